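# Peak-to-gene assignment: nearest TSS within 50 kb, proximal/distal split
# at 5 kb, and lineage labelling against Epi/PrE gene sets.

#' Assign each peak to its nearest TSS within a maximum distance
#'
#' Distance is measured from the peak midpoint to the TSS; a peak is
#' assigned to the single gene with minimum distance on the same chromosome
#' when that distance is at most `max_dist` (default 50 kb), otherwise to no
#' gene. Equidistant ties break to the lexicographically smaller gene id.
#'
#' @param peaks peak data.frame (see [peak_table()]).
#' @param genes gene data.frame with `gene_id`, `chrom`, `tss` (see
#'   [read_genes()]).
#' @param max_dist maximum assignment distance in bp (inclusive).
#' @return data.frame: peak columns plus `gene_id` (`NA` if unassigned) and
#'   `distance_bp`.
#' @export
assign_nearest_tss <- function(peaks, genes, max_dist = 50000) {
  n <- nrow(peaks)
  gene_id <- rep(NA_character_, n)
  distance <- rep(NA_real_, n)
  mid <- floor((peaks$start + peaks$end) / 2)
  genes <- genes[order(genes$gene_id), , drop = FALSE]  # lexicographic tie-break
  by_chrom <- split(seq_len(nrow(genes)), genes$chrom)
  for (i in seq_len(n)) {
    gi <- by_chrom[[peaks$chrom[i]]]
    if (is.null(gi)) next
    d <- abs(mid[i] - genes$tss[gi])
    j <- which.min(d)   # first minimum = smallest gene_id on ties
    if (d[j] <= max_dist) {
      gene_id[i] <- genes$gene_id[gi[j]]
      distance[i] <- d[j]
    }
  }
  out <- peaks
  out$gene_id <- gene_id
  out$distance_bp <- distance
  out
}

#' Proximal/distal classification of assigned peaks
#'
#' Proximal iff distance to the assigned TSS is strictly less than
#' `prox_dist` (default 5 kb).
#'
#' @param assignment output of [assign_nearest_tss()].
#' @param prox_dist proximal cutoff in bp (strict `<`).
#' @return character vector `"proximal"`/`"distal"`; errors on unassigned
#'   peaks.
#' @export
classify_locality <- function(assignment, prox_dist = 5000) {
  if (any(is.na(assignment$gene_id)))
    stop("classify_locality requires all peaks to be assigned to a gene")
  ifelse(assignment$distance_bp < prox_dist, "proximal", "distal")
}

#' Lineage labelling of assigned peaks
#'
#' A peak inherits the lineage of its assigned gene: `Epi` if the gene is in
#' `epi_genes`, `PrE` if in `pre_genes`, otherwise `none` (also for
#' unassigned peaks).
#'
#' @param assignment output of [assign_nearest_tss()].
#' @param epi_genes,pre_genes disjoint character vectors of gene ids.
#' @return character vector in `{"Epi", "PrE", "none"}`.
#' @export
label_lineage <- function(assignment, epi_genes, pre_genes) {
  if (length(intersect(epi_genes, pre_genes)))
    stop("epi_genes and pre_genes must be disjoint")
  ifelse(is.na(assignment$gene_id), "none",
         ifelse(assignment$gene_id %in% epi_genes, "Epi",
                ifelse(assignment$gene_id %in% pre_genes, "PrE", "none")))
}

#' One-call CRE annotation
#'
#' Runs [assign_nearest_tss()], [classify_locality()] (for assigned peaks)
#' and [label_lineage()] and returns the combined table.
#'
#' @inheritParams assign_nearest_tss
#' @inheritParams classify_locality
#' @param epi_genes,pre_genes lineage gene-id sets.
#' @return annotated peak data.frame with `gene_id`, `distance_bp`,
#'   `locality`, `lineage`.
#' @export
annotate_cres <- function(peaks, genes, epi_genes = character(),
                          pre_genes = character(), max_dist = 50000,
                          prox_dist = 5000) {
  asn <- assign_nearest_tss(peaks, genes, max_dist)
  loc <- rep(NA_character_, nrow(asn))
  ok <- !is.na(asn$gene_id)
  if (any(ok)) loc[ok] <- ifelse(asn$distance_bp[ok] < prox_dist, "proximal", "distal")
  asn$locality <- loc
  asn$lineage <- label_lineage(asn, epi_genes, pre_genes)
  asn
}
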