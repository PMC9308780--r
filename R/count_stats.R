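# Negative-binomial differential count engine: median-of-ratios size
# factors, moderated method-of-moments dispersion, Wald test, BH-FDR, and
# the up/stable/down classifier shared by the ATAC, RNA and Capture-C
# comparisons.

#' Median-of-ratios size factors
#'
#' `s_j = median_f count(f,j) / geomean_j' count(f,j')`, restricted to
#' features with all-positive counts (the DESeq normalization).
#'
#' @param counts numeric matrix, features x samples.
#' @return positive numeric vector, one size factor per sample.
#' @export
size_factors_median_of_ratios <- function(counts) {
  if (ncol(counts) < 1) stop("need at least one sample")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop("no feature has all-positive counts; consider a pseudo-reference ",
         "fallback (e.g. add a pseudocount or use positive-count geomeans)")
  lg <- log(counts[pos, , drop = FALSE])
  ref <- rowMeans(lg)                      # log geometric mean per feature
  sf <- apply(lg, 2, function(x) exp(stats::median(x - ref)))
  names(sf) <- colnames(counts)
  sf
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up BH with monotonicity enforcement, capped at 1. `NA`
#' entries are passed through untouched and do not count toward `m`.
#'
#' @param p numeric vector of p-values in \[0,1\].
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- p
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Negative-binomial Wald test between two conditions
#'
#' Per feature: normalized means with pseudocount 0.5 give the log2 fold
#' change `test` vs `ref`; the NB dispersion is estimated by method of
#' moments from within-condition variances, moderated across features
#' (median), and floored at 1e-8; the Wald statistic uses a delta-method
#' standard error and a two-sided normal p-value. Features with zero counts
#' in every sample get `log2fc = 0`, `p = 1`, and are excluded from the BH
#' universe.
#'
#' @param counts numeric matrix, features x samples.
#' @param condition character/factor vector, one condition per sample.
#' @param contrast `c(test, ref)`; positive `log2fc` means higher in `test`.
#' @param size_factors optional per-sample size factors; computed by
#'   [size_factors_median_of_ratios()] when `NULL`.
#' @param dispersion_method `"pooled"` (one moderated dispersion shared by
#'   all features; robust for few replicates) or `"per_feature"` (raw
#'   method-of-moments per feature).
#' @param dispersion optional externally supplied dispersion (scalar or
#'   per-feature vector), e.g. derived from finer-grained units than the
#'   tested features; overrides internal estimation.
#' @return data.frame with columns `feature`, `baseMean`, `log2fc`, `p`,
#'   `padj`, `dispersion`.
#' @export
nb_wald_test <- function(counts, condition, contrast,
                         size_factors = NULL,
                         dispersion_method = c("pooled", "per_feature"),
                         dispersion = NULL) {
  dispersion_method <- match.arg(dispersion_method)
  condition <- as.character(condition)
  if (length(condition) != ncol(counts))
    stop("condition must have one entry per sample")
  if (length(contrast) != 2) stop("contrast must be c(test, ref)")
  for (cc in contrast) if (!cc %in% condition)
    stop("condition absent from metadata: ", cc)
  if (is.null(size_factors)) size_factors <- size_factors_median_of_ratios(counts)
  norm <- sweep(counts, 2, size_factors, "/")

  ia <- which(condition == contrast[2])   # ref
  ib <- which(condition == contrast[1])   # test
  na <- length(ia); nb <- length(ib)
  ma <- rowMeans(norm[, ia, drop = FALSE])
  mb <- rowMeans(norm[, ib, drop = FALSE])
  va <- if (na >= 2) apply(norm[, ia, drop = FALSE], 1, stats::var) else rep(NA_real_, nrow(norm))
  vb <- if (nb >= 2) apply(norm[, ib, drop = FALSE], 1, stats::var) else rep(NA_real_, nrow(norm))

  # method-of-moments dispersion pooled across the two conditions
  dfa <- max(na - 1, 0); dfb <- max(nb - 1, 0)
  pool_var <- (ifelse(is.na(va), 0, va) * dfa + ifelse(is.na(vb), 0, vb) * dfb) /
    max(dfa + dfb, 1)
  pool_mean <- (ma * na + mb * nb) / (na + nb)
  raw_disp <- ifelse(pool_mean > 0, (pool_var - pool_mean) / pool_mean^2, NA_real_)
  disp <- if (!is.null(dispersion)) {
    pmax(rep(dispersion, length.out = nrow(norm)), 1e-8)
  } else if (dispersion_method == "pooled") {
    # mean, not median: the per-feature moment estimator at 2 df is
    # median-biased low (chi-square), which would inflate Wald tails.
    # Negative estimates enter the mean unfloored; flooring first would
    # bias the pooled value upward in the Poisson limit.
    common <- mean(raw_disp, na.rm = TRUE)
    if (!is.finite(common)) common <- 1e-8
    rep(max(common, 1e-8), nrow(norm))
  } else {
    pmax(ifelse(is.na(raw_disp), 1e-8, raw_disp), 1e-8)
  }

  log2fc <- log2((mb + 0.5) / (ma + 0.5))
  var_ma <- (ma + disp * ma^2) / na
  var_mb <- (mb + disp * mb^2) / nb
  se <- sqrt(var_ma / (ma + 0.5)^2 + var_mb / (mb + 0.5)^2) / log(2)
  z <- ifelse(se > 0, log2fc / se, 0)
  p <- 2 * stats::pnorm(-abs(z))

  all_zero <- rowSums(counts) == 0
  log2fc[all_zero] <- 0
  p[all_zero] <- 1
  padj <- rep(NA_real_, length(p))
  padj[!all_zero] <- bh_adjust(p[!all_zero])
  padj[all_zero] <- 1

  data.frame(
    feature = if (is.null(rownames(counts))) as.character(seq_len(nrow(counts))) else rownames(counts),
    baseMean = rowMeans(norm), log2fc = log2fc, p = p, padj = padj,
    dispersion = disp, stringsAsFactors = FALSE
  )
}

#' Classify differential features as up / stable / down
#'
#' `up` iff `log2fc >= lfc_min` and `padj < padj_max`; `down` iff
#' `log2fc <= -lfc_min` and `padj < padj_max`; otherwise `stable`. The ATAC
#' comparisons use `lfc_min = 2, padj_max = 1e-4`; the RNA comparisons use
#' `lfc_min = 2, padj_max = 0.1`.
#'
#' @param result a data.frame with `log2fc` and `padj` (see [nb_wald_test()]).
#' @param lfc_min positive log2 fold-change threshold.
#' @param padj_max adjusted-p threshold (strict `<`).
#' @return character vector in `{"up", "stable", "down"}`.
#' @export
classify_features <- function(result, lfc_min, padj_max) {
  if (lfc_min <= 0 || padj_max <= 0) stop("thresholds must be positive")
  sig <- !is.na(result$padj) & result$padj < padj_max
  ifelse(sig & result$log2fc >= lfc_min, "up",
         ifelse(sig & result$log2fc <= -lfc_min, "down", "stable"))
}
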