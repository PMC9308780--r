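# Signal quantification over peak classes: per-peak windowed signal
# matrices, the eviction-and-redirection (redistribution) score, and
# center-anchored meta-profiles.

#' Per-peak signal matrix across assays and timepoints
#'
#' One row per peak, one column per track; entry = mean signal over
#' `[midpoint - flank, midpoint + flank)` (see [track_stat()]).
#'
#' @param peaks peak data.frame; extra columns (e.g. `cluster`) are carried
#'   through as row metadata.
#' @param tracks named list of `signal_track`s; names become column names
#'   (conventionally `"assay.timepoint"`).
#' @param flank half-window in bp (default 500).
#' @return list with `signal` (numeric matrix) and `peaks` (the input rows).
#' @export
signal_matrix <- function(peaks, tracks, flank = 500) {
  stopifnot(length(tracks) > 0, !is.null(names(tracks)))
  mid <- floor((peaks$start + peaks$end) / 2)
  m <- matrix(NA_real_, nrow = nrow(peaks), ncol = length(tracks),
              dimnames = list(NULL, names(tracks)))
  for (j in seq_along(tracks)) {
    tr <- tracks[[j]]
    for (i in seq_len(nrow(peaks))) {
      m[i, j] <- track_stat(tr, peaks$chrom[i], mid[i] - flank, mid[i] + flank,
                            "mean")
    }
  }
  list(signal = m, peaks = peaks)
}

#' Redistribution score between two timepoints
#'
#' For each cluster, `R = median over peaks of log2((s(t1)+1)/(s(t0)+1))`.
#' Redistribution is `detected` when the pre-existing cluster loses signal
#' (`R_c1 <= -delta`) while the de-novo-closed cluster gains it
#' (`R_c3 >= +delta`).
#'
#' @param mat output of [signal_matrix()].
#' @param cluster_col name of the cluster column in `mat$peaks`.
#' @param assay assay name used in the track column labels.
#' @param t0,t1 timepoint labels; columns `paste(assay, t, sep=".")` must
#'   exist.
#' @param delta detection threshold on the median log-ratio (default 0.5).
#' @param c1,c3 cluster labels playing the losing / gaining role.
#' @return list with per-cluster medians `R`, per-peak log-ratios, and
#'   `detected`.
#' @export
redistribution_score <- function(mat, cluster_col = "cluster", assay = "NANOG",
                                 t0 = "0", t1 = "2", delta = 0.5,
                                 c1 = "c1_preexisting", c3 = "c3_denovo_closed") {
  col0 <- paste(assay, t0, sep = ".")
  col1 <- paste(assay, t1, sep = ".")
  for (cc in c(col0, col1)) if (!cc %in% colnames(mat$signal))
    stop("timepoint column missing from signal matrix: ", cc)
  cl <- mat$peaks[[cluster_col]]
  if (is.null(cl)) stop("no cluster column '", cluster_col, "' in peaks")
  lr <- log2((mat$signal[, col1] + 1) / (mat$signal[, col0] + 1))
  R <- c(tapply(lr, cl, stats::median))   # plain named vector
  for (cc in c(c1, c3)) if (!cc %in% names(R) || !sum(cl == cc))
    stop("empty cluster: ", cc)
  list(R = R, log_ratios = split(lr, cl), delta = delta,
       detected = unname(R[c1] <= -delta && R[c3] >= delta))
}

#' Center-anchored meta-profile
#'
#' Mean signal across centers, in `n_bins` equal bins spanning
#' `[-flank, +flank)` around each center.
#'
#' @param track a `signal_track`.
#' @param centers data.frame with `chrom` and `pos` (bp).
#' @param flank half-window in bp.
#' @param n_bins number of profile bins.
#' @return numeric vector of length `n_bins`.
#' @export
meta_profile <- function(track, centers, flank = 500, n_bins = 20) {
  if (nrow(centers) == 0) stop("meta_profile requires at least one center")
  w <- 2 * flank / n_bins
  prof <- matrix(NA_real_, nrow(centers), n_bins)
  for (i in seq_len(nrow(centers))) {
    lo <- centers$pos[i] - flank
    for (b in seq_len(n_bins)) {
      prof[i, b] <- track_stat(track, centers$chrom[i], lo + (b - 1) * w,
                               lo + b * w, "mean")
    }
  }
  colMeans(prof)
}
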