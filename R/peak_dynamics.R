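# Peak taxonomies across a differentiation time course: q-value ranking,
# GATA6 early/late x open/closed classification, and the NANOG 2 h
# redistribution clusters.

#' Top-N peaks by q-value
#'
#' Returns the `n` peaks with smallest q-value; ties break by score
#' (descending), then chromosome, then start. If fewer than `n` peaks are
#' supplied, all are returned.
#'
#' @param peaks peak data.frame with a `qvalue` column.
#' @param n number of peaks to keep.
#' @return the ranked subset.
#' @export
top_n_by_q <- function(peaks, n) {
  if (any(is.na(peaks$qvalue))) stop("top_n_by_q requires q-values on all peaks")
  ord <- order(peaks$qvalue, -peaks$score, peaks$chrom, peaks$start)
  peaks[ord[seq_len(min(n, nrow(peaks)))], , drop = FALSE]
}

# internal: union-merge peak sets into a consensus universe (GRanges reduce)
merge_universe <- function(peak_sets) {
  all <- do.call(rbind, lapply(peak_sets, function(p)
    p[, c("chrom", "start", "end")]))
  gr <- GenomicRanges::reduce(peaks_gr(peak_table(all$chrom, all$start, all$end)))
  peak_table(as.character(GenomicRanges::seqnames(gr)),
             GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr))
}

#' GATA6 peak taxonomy: early/late split by 0 h accessibility
#'
#' Peaks ranked per timepoint (top N by MACS q-value; see [top_n_by_q()])
#' are merged into a union universe by 1 bp overlap. A universe peak is
#' `early` if it overlaps the ranked set of any timepoint between 2 and 8 h,
#' `late` if it overlaps only the 48 h ranked set, and `unclassified`
#' otherwise. Early peaks overlapping an ATAC peak at 0 h are
#' `early_open_0h`; the remaining early peaks are `early_closed_0h`.
#'
#' @param ranked named list of peak data.frames; names are timepoints in
#'   hours, must include `"2"`, `"4"`, `"8"`, `"48"`.
#' @param atac0 ATAC peak data.frame at 0 h.
#' @param n rank cut applied per timepoint (default 10000, the published
#'   GATA6 choice).
#' @return data.frame: universe peaks plus a `category` column in
#'   `{early_open_0h, early_closed_0h, late, unclassified}`.
#' @export
classify_gata6_peaks <- function(ranked, atac0, n = 10000) {
  need <- c("2", "4", "8", "48")
  miss <- setdiff(need, names(ranked))
  if (length(miss))
    stop("missing required timepoint(s): ", paste(miss, collapse = ", "), " h")
  topsets <- lapply(ranked[need], top_n_by_q, n = n)
  uni <- merge_universe(topsets)
  in_set <- function(set) overlap_any(uni, set)
  early <- in_set(topsets[["2"]]) | in_set(topsets[["4"]]) | in_set(topsets[["8"]])
  late48 <- in_set(topsets[["48"]])
  open0 <- overlap_any(uni, atac0)
  uni$category <- ifelse(early & open0, "early_open_0h",
                         ifelse(early, "early_closed_0h",
                                ifelse(late48, "late", "unclassified")))
  uni
}

#' NANOG 2 h redistribution clusters
#'
#' Each NANOG 2 h peak is assigned to: `c1_preexisting` if it overlaps a
#' NANOG 0 h peak; otherwise `c2_denovo_open` if it overlaps an ATAC 0 h
#' peak (de novo binding over open chromatin); otherwise `c3_denovo_closed`
#' (de novo binding at sites closed at 0 h).
#'
#' @param n0 NANOG peaks at 0 h.
#' @param n2 NANOG peaks at 2 h.
#' @param atac0 ATAC peaks at 0 h.
#' @return `n2` with an added `cluster` column.
#' @export
classify_nanog_2h <- function(n0, n2, atac0) {
  pre <- overlap_any(n2, n0)
  open0 <- overlap_any(n2, atac0)
  n2$cluster <- ifelse(pre, "c1_preexisting",
                       ifelse(open0, "c2_denovo_open", "c3_denovo_closed"))
  n2
}
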