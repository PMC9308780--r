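# 3D genome analyses: Capture-C sliding-window differential interactions
# (reusing the NB engine) and Hi-C A/B compartment eigenvectors at 250 kb
# with correlation-based switch calling.

#' Sliding-window grid
#'
#' Windows `[start + step*i, start + step*i + win)` for
#' `i = 0..floor((L - win)/step)`.
#'
#' @param L region length in bp.
#' @param win window size in bp.
#' @param step slide in bp.
#' @return data.frame `start`, `end` (relative to the region start).
#' @export
sliding_windows <- function(L, win = 5000, step = 500) {
  if (L < win) stop("region shorter than window")
  i <- 0:((L - win) %/% step)
  data.frame(start = i * step, end = i * step + win)
}

#' Viewpoint profile container
#'
#' @param id viewpoint identifier.
#' @param chrom,start,end profiled region (0-based half-open).
#' @param signal matrix of binned signal, bins x samples (bin grid aligned
#'   to `start`).
#' @param condition per-sample condition labels.
#' @param bin_size bin width in bp (default 1000, the published setting).
#' @return object of class `viewpoint_profile`.
#' @export
viewpoint_profile <- function(id, chrom, start, end, signal, condition,
                              bin_size = 1000) {
  stopifnot(nrow(signal) == (end - start) / bin_size,
            ncol(signal) == length(condition))
  if (any(signal < 0)) stop("viewpoint signal must be >= 0")
  structure(list(id = id, chrom = chrom, start = start, end = end,
                 signal = signal, condition = as.character(condition),
                 bin_size = bin_size),
            class = "viewpoint_profile")
}

#' Capture-C differential interactions over overlapping windows
#'
#' Bin signal is summed within overlapping windows (default 5 kb windows
#' slid by 500 bp), rounded to integer counts, and tested between the two
#' conditions with the NB Wald engine; BH is applied over windows.
#' Significant windows (`padj < padj_max`, default 0.01) are merged into
#' maximal runs.
#'
#' The NB dispersion is estimated from the 1 kb bins (which are close to
#' independent) and propagated to the window sums as
#' `alpha_w = alpha_bin * sum(mu_b^2) / sum(mu_b)^2`; estimating it from
#' the overlapping windows themselves is unstable (few effective degrees
#' of freedom) and intermittently anti-conservative.
#'
#' @param profile a `viewpoint_profile` with >= 2 replicates per condition.
#' @param contrast `c(test, ref)` condition labels.
#' @param win,step window geometry in bp.
#' @param padj_max significance threshold (strict `<`).
#' @return list: `windows` (per-window results in genomic coordinates),
#'   `significant` (merged runs as data.frame chrom/start/end).
#' @export
window_differential <- function(profile, contrast, win = 5000, step = 500,
                                padj_max = 0.01) {
  L <- profile$end - profile$start
  wins <- sliding_windows(L, win, step)
  bs <- profile$bin_size
  counts <- t(vapply(seq_len(nrow(wins)), function(i) {
    b0 <- wins$start[i] %/% bs + 1L
    b1 <- (wins$end[i] - 1L) %/% bs + 1L
    colSums(profile$signal[b0:b1, , drop = FALSE])
  }, numeric(ncol(profile$signal))))
  counts <- round(counts)
  rownames(counts) <- sprintf("w%04d", seq_len(nrow(wins)))
  # bin-level dispersion, propagated to window sums
  bins <- round(profile$signal)
  rownames(bins) <- sprintf("b%04d", seq_len(nrow(bins)))
  sf <- size_factors_median_of_ratios(bins)
  bnorm <- sweep(bins, 2, sf, "/")
  disp_bin <- local({
    va <- vb <- ma <- mb <- NULL
    for (cc in unique(profile$condition)) {
      i <- profile$condition == cc
      va <- cbind(va, apply(bnorm[, i, drop = FALSE], 1, stats::var))
      ma <- cbind(ma, rowMeans(bnorm[, i, drop = FALSE]))
    }
    pv <- rowMeans(va); pm <- rowMeans(ma)
    max(mean((pv - pm) / pm^2, na.rm = TRUE), 1e-8)
  })
  mu_bin <- rowMeans(bnorm)
  disp_win <- vapply(seq_len(nrow(wins)), function(i) {
    b0 <- wins$start[i] %/% bs + 1L
    b1 <- (wins$end[i] - 1L) %/% bs + 1L
    mu <- mu_bin[b0:b1]
    disp_bin * sum(mu^2) / max(sum(mu)^2, 1e-8)
  }, numeric(1))
  res <- nb_wald_test(counts, profile$condition, contrast,
                      size_factors = sf, dispersion = disp_win)
  res$start <- profile$start + wins$start
  res$end <- profile$start + wins$end
  res$chrom <- profile$chrom
  sig <- which(!is.na(res$padj) & res$padj < padj_max)
  runs <- if (length(sig)) {
    gr <- GenomicRanges::reduce(peaks_gr(
      peak_table(res$chrom[sig], res$start[sig], res$end[sig])))
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr) - 1L,
               end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
  } else {
    data.frame(chrom = character(), start = integer(), end = integer())
  }
  list(windows = res, significant = runs)
}

#' A/B compartment eigenvector of a contact matrix
#'
#' Standard pipeline: coverage normalization (entry ij divided by the
#' product of row sums), observed/expected by distance-diagonal means,
#' Pearson correlation matrix, and the leading eigenvector by power
#' iteration (all-ones start, deterministic first-basis fallback when the
#' start is orthogonal to the leading direction; tolerance 1e-10). The sign
#' is oriented so that the eigenvector correlates positively with a
#' reference activity score (e.g. H3K27ac per bin); positive = A
#' compartment. All-zero rows are masked and reported.
#'
#' @param mat square symmetric non-negative contact matrix (one
#'   chromosome at fixed bin size, conventionally 250 kb).
#' @param reference numeric per-bin activity score used to orient the sign.
#' @param tol power-iteration convergence tolerance.
#' @return list: `eigen` (per-bin score, NA for masked), `cor` (Pearson
#'   correlation matrix, masked bins NA), `masked` (indices), `lambda`.
#' @export
compartment_eigen <- function(mat, reference, tol = 1e-10) {
  stopifnot(nrow(mat) == ncol(mat))
  if (max(abs(mat - t(mat))) > 1e-8 * max(abs(mat), 1))
    stop("contact matrix must be symmetric")
  if (any(mat < 0)) stop("contact matrix must be non-negative")
  n <- nrow(mat)
  rs <- rowSums(mat)
  masked <- as.integer(which(rs == 0))
  keep <- setdiff(seq_len(n), masked)
  m <- mat[keep, keep, drop = FALSE]
  rk <- rowSums(m)
  cov <- m / outer(rk, rk) * mean(rk)^2        # coverage normalization
  d <- abs(outer(seq_along(keep), seq_along(keep), "-"))
  expd <- tapply(cov, d, mean)                 # expected per diagonal
  oe <- cov / matrix(expd[as.character(d)], nrow(cov), ncol(cov))
  oe[!is.finite(oe)] <- 0
  C <- suppressWarnings(stats::cor(oe))
  C[!is.finite(C)] <- 0
  v <- power_iteration(C, tol)
  # orient: positive correlation with the reference activity score
  r <- suppressWarnings(stats::cor(v$vector, reference[keep]))
  if (!is.na(r) && r < 0) v$vector <- -v$vector
  ev <- rep(NA_real_, n)
  ev[keep] <- v$vector
  Cf <- matrix(NA_real_, n, n)
  Cf[keep, keep] <- C
  list(eigen = ev, cor = Cf, masked = masked, lambda = v$lambda)
}

# internal: leading eigenvector by power iteration; correlation matrices
# are PSD so the largest-magnitude eigenvalue is the leading one. Both
# deterministic starts are iterated and the larger Rayleigh quotient wins:
# the all-ones start can be exactly orthogonal to the leading eigenvector
# on balanced two-block matrices, where it converges to the runner-up.
power_iteration <- function(C, tol = 1e-10, max_iter = 50000) {
  n <- nrow(C)
  starts <- list(rep(1, n) / sqrt(n), c(1, rep(0, n - 1)))
  best <- NULL
  for (v0 in starts) {
    v <- v0
    for (it in seq_len(max_iter)) {
      w <- C %*% v
      nw <- sqrt(sum(w^2))
      if (nw < 1e-14) break                   # start orthogonal to range
      w <- as.numeric(w / nw)
      done <- sqrt(sum((w - v)^2)) < tol || sqrt(sum((w + v)^2)) < tol
      v <- w
      if (done) break
    }
    lambda <- as.numeric(crossprod(v, C %*% v))
    if (is.null(best) || lambda > best$lambda)
      best <- list(vector = v, lambda = lambda)
  }
  best
}

#' Compartment switches between two conditions
#'
#' For each bin, `r` is the Pearson correlation between the bin's row of
#' the Hi-C correlation matrix in the two conditions (masked bins
#' excluded); a bin switches compartment iff `r < r_max` (strict; default
#' 0.4, the published rule). Direction comes from the eigenvector signs
#' (`A->B` when positive in `a` and negative in `b`, etc.).
#'
#' @param a,b outputs of [compartment_eigen()] on the same bin grid.
#' @param r_max switch threshold on the correlation.
#' @return data.frame per bin: `bin`, `r`, `switch`, `direction`.
#' @export
compartment_switches <- function(a, b, r_max = 0.4) {
  n <- nrow(a$cor)
  if (n != nrow(b$cor)) stop("bin grids differ between conditions")
  masked <- union(a$masked, b$masked)
  keep <- setdiff(seq_len(n), masked)
  r <- rep(NA_real_, n)
  for (i in keep) {
    cols <- setdiff(keep, integer(0))
    r[i] <- suppressWarnings(stats::cor(a$cor[i, cols], b$cor[i, cols]))
  }
  sw <- !is.na(r) & r < r_max
  dir <- rep(NA_character_, n)
  pa <- a$eigen > 0; pb <- b$eigen > 0
  dir[sw & pa & !pb] <- "A->B"
  dir[sw & !pa & pb] <- "B->A"
  dir[sw & pa == pb] <- "none"
  data.frame(bin = seq_len(n), r = r, switch = sw, direction = dir,
             stringsAsFactors = FALSE)
}

#' Read / write a dense contact matrix (TSV with bin header)
#'
#' @param path TSV path; first row and column are bin labels.
#' @return numeric matrix.
#' @export
read_contact_matrix <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  m <- as.matrix(dt[, -1, drop = FALSE])
  rownames(m) <- as.character(dt[[1]])
  m
}

#' @rdname read_contact_matrix
#' @param mat square numeric matrix with dimnames.
#' @export
write_contact_matrix <- function(mat, path) {
  dt <- data.table::data.table(bin = rownames(mat))
  for (j in seq_len(ncol(mat))) dt[[colnames(mat)[j]]] <- mat[, j]
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
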