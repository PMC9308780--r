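# Transcriptome analyses: transgene-vs-endogenous quantification from
# CDS/3'UTR coverage, lineage gene-list intersection of two differential
# tables, first-change time-course classification, and staging of bulk
# samples on single-cell cluster centroids via residual PCA.

#' Transgene expression relative to the endogenous locus (T/E)
#'
#' The transgene encodes only the CDS, so reads over the last-exon CDS come
#' from transgene plus endogenous transcripts while 3'UTR reads are
#' endogenous only. Counts are normalized to library size (per million) and
#' segment length (per kb); per sample, `T = CDS_norm - UTR_norm`, `E` is
#' the mean normalized 3'UTR expression over the designated endogenous
#' reference samples, and the relative transgene expression is `T/E`.
#'
#' @param seg_counts numeric matrix, rows `"CDS_last_exon"` and `"UTR3"`,
#'   columns samples.
#' @param library_sizes named per-sample totals.
#' @param segment_lengths named lengths in bp for the two segments.
#' @param reference_samples sample names defining `E`.
#' @return list with `cds_norm`, `utr_norm`, `T` (per sample), `E`,
#'   `ratio` (per sample T/E) and `negative_T` flags.
#' @export
transgene_ratio <- function(seg_counts, library_sizes, segment_lengths,
                            reference_samples) {
  need <- c("CDS_last_exon", "UTR3")
  if (!all(need %in% rownames(seg_counts)))
    stop("seg_counts must contain rows CDS_last_exon and UTR3")
  if (length(reference_samples) == 0) stop("reference_samples must be non-empty")
  if (!all(reference_samples %in% colnames(seg_counts)))
    stop("unknown reference sample(s)")
  norm <- function(seg) {
    seg_counts[seg, ] / (library_sizes[colnames(seg_counts)] / 1e6) /
      (segment_lengths[[seg]] / 1000)
  }
  cds <- norm("CDS_last_exon")
  utr <- norm("UTR3")
  Tt <- cds - utr
  E <- mean(utr[reference_samples])
  if (E == 0) stop("endogenous reference expression E is zero; T/E undefined")
  neg <- Tt < 0
  if (any(neg)) warning("negative transgene expression T in ",
                        sum(neg), " sample(s); reported as-is")
  list(cds_norm = cds, utr_norm = utr, T = Tt, E = E, ratio = Tt / E,
       negative_T = neg)
}

#' Lineage gene lists from the intersection of two differential tables
#'
#' Both tables compare PrE vs Epi on a shared gene space. The PrE list
#' contains genes up in both tables at the thresholds; the Epi list genes
#' down in both. Genes changing in only one table, or in opposite
#' directions, are excluded.
#'
#' @param deA,deB data.frames with `feature`, `log2fc`, `padj`.
#' @param lfc_min,fdr_max thresholds (defaults 2 and 0.1, the published
#'   RNA setting).
#' @return list with `epi` and `pre` gene-id vectors (disjoint).
#' @export
intersect_lineage_genes <- function(deA, deB, lfc_min = 2, fdr_max = 0.1) {
  cls <- function(de) {
    k <- classify_features(de, lfc_min, fdr_max)
    stats::setNames(k, de$feature)
  }
  a <- cls(deA); b <- cls(deB)
  shared <- intersect(names(a), names(b))
  pre <- shared[a[shared] == "up" & b[shared] == "up"]
  epi <- shared[a[shared] == "down" & b[shared] == "down"]
  list(epi = epi, pre = pre)
}

#' First-change timepoint over a differential time course
#'
#' Each timepoint is compared to 0 h and to the previous timepoint; a gene
#' is flagged at the earliest timepoint where either contrast passes
#' [classify_features()], with the direction taken from that contrast's
#' fold change (vs-0h wins if both pass).
#'
#' @param vs0 named list (by timepoint, ascending) of differential tables
#'   vs 0 h.
#' @param vsprev named list of tables vs the previous timepoint (same
#'   names).
#' @param lfc_min,padj_max thresholds (defaults 2, 0.1).
#' @return data.frame `gene`, `first_change` (NA if never), `direction`.
#' @export
de_timecourse <- function(vs0, vsprev, lfc_min = 2, padj_max = 0.1) {
  stopifnot(identical(names(vs0), names(vsprev)))
  genes <- unique(unlist(lapply(vs0, function(d) d$feature)))
  first <- rep(NA_character_, length(genes))
  dirn <- rep(NA_character_, length(genes))
  names(first) <- names(dirn) <- genes
  for (tp in names(vs0)) {
    for (tab in list(vs0[[tp]], vsprev[[tp]])) {
      k <- classify_features(tab, lfc_min, padj_max)
      hit <- tab$feature[k != "stable"]
      newly <- hit[is.na(first[hit])]
      first[newly] <- tp
      dirn[newly] <- k[match(newly, tab$feature)]
    }
  }
  data.frame(gene = genes, first_change = unname(first),
             direction = unname(dirn), stringsAsFactors = FALSE)
}

#' Stage bulk samples on single-cell cluster centroids by residual PCA
#'
#' Single-cell counts are CPM-normalized per cell, log1p-transformed, and
#' averaged within (optionally merged) clusters; bulk counts are
#' median-of-ratios normalized and log2(x+1)-transformed. On the shared
#' gene space, each gene is regressed on the platform indicator
#' (`expression ~ group`, group = bulk vs single-cell), i.e. group-centered;
#' PCA of the residual matrix (samples x genes) places bulk samples and
#' cluster centroids in one space, and each bulk sample is assigned to the
#' nearest cluster centroid in the first two PCs (Euclidean distance).
#'
#' @param bulk counts matrix genes x samples.
#' @param sc counts matrix genes x cells.
#' @param cell_clusters named character vector: cluster label per cell.
#' @param cluster_merge optional named character vector mapping raw cluster
#'   labels to merged labels (e.g. `c("E3.5:0" = "E3.5_PrE",
#'   "E3.5:4" = "E3.5_PrE")`).
#' @param n_pcs PCs retained in the output (mapping always uses 2).
#' @return list: `pcs` (scores, rows = bulk samples then cluster
#'   centroids), `residuals`, `mapping` (data.frame sample, cluster,
#'   distance), `group`.
#' @export
stage_bulk_on_sc <- function(bulk, sc, cell_clusters, cluster_merge = NULL,
                             n_pcs = 5) {
  stopifnot(!is.null(rownames(bulk)), !is.null(rownames(sc)))
  cl <- as.character(cell_clusters[colnames(sc)])
  if (anyNA(cl)) stop("every cell needs a cluster label")
  if (!is.null(cluster_merge)) {
    m <- cl %in% names(cluster_merge)
    cl[m] <- cluster_merge[cl[m]]
  }
  genes <- intersect(rownames(bulk), rownames(sc))
  if (length(genes) == 0) stop("empty gene intersection between bulk and sc")
  # single-cell side: CPM -> log1p -> cluster means
  cpm <- sweep(sc[genes, , drop = FALSE], 2, colSums(sc), "/") * 1e6
  lg <- log1p(cpm)
  cent <- vapply(unique(cl), function(k)
    rowMeans(lg[, cl == k, drop = FALSE]), numeric(length(genes)))
  # bulk side: median-of-ratios normalize -> log1p. The same log base is
  # used on both platforms deliberately: a base mismatch is a per-gene
  # slope (not an offset), which the group-centering step cannot remove
  # and which stretches bulk trajectories relative to the cluster
  # centroids.
  sf <- size_factors_median_of_ratios(bulk[genes, , drop = FALSE])
  bl <- log1p(sweep(bulk[genes, , drop = FALSE], 2, sf, "/"))
  X <- t(cbind(bl, cent))                       # samples x genes
  group <- rep(c("bulk", "sc"), c(ncol(bl), ncol(cent)))
  # expression ~ group least squares == group centering per gene
  R <- X
  for (g in unique(group)) {
    i <- group == g
    R[i, ] <- sweep(X[i, , drop = FALSE], 2, colMeans(X[i, , drop = FALSE]))
  }
  if (all(abs(R) < 1e-12))
    stop("degenerate input: residual matrix is zero, PCA undefined")
  pc <- stats::prcomp(R, center = TRUE, scale. = FALSE)
  k <- min(n_pcs, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  bidx <- which(group == "bulk")
  cidx <- which(group == "sc")
  map <- do.call(rbind, lapply(bidx, function(i) {
    d <- sqrt(colSums((t(scores[cidx, 1:2, drop = FALSE]) - scores[i, 1:2])^2))
    j <- which.min(d)
    data.frame(sample = rownames(scores)[i], cluster = rownames(scores)[cidx][j],
               distance = d[j], stringsAsFactors = FALSE)
  }))
  list(pcs = scores, residuals = R, mapping = map, group = group,
       var_explained = pc$sdev^2 / sum(pc$sdev^2))
}
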