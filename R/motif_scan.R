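# FIMO-style PWM scanning: log-odds scores at integer resolution, exact
# null p-values by dynamic programming over positions, BH q-values over the
# scanned-window universe, and the motif density / strength comparisons
# between peak classes.

BASES <- c("A", "C", "G", "T")

#' Construct a motif model
#'
#' Wraps a position probability matrix with a background composition and a
#' pseudocount. Scores are `sum_i log2((W[b_i, i] + eps) / q[b_i])`, scaled
#' to integers at `1/scale` resolution so that the exact null score
#' distribution is computable by dynamic programming.
#'
#' @param x a JASPAR PFM list from [read_pwm_jaspar()], or a 4 x k numeric
#'   matrix of counts or probabilities with rownames A,C,G,T.
#' @param background length-4 base composition (A,C,G,T), summing to 1;
#'   default uniform.
#' @param pseudocount added to each probability before the log-odds
#'   (default 0.25/4 per base, i.e. 0.25 spread over a position).
#' @param scale integer score resolution (default 1000, i.e. 1e-3).
#' @param id motif identifier.
#' @return object of class `motif_model`.
#' @export
motif_model <- function(x, background = rep(0.25, 4), pseudocount = 0.0625,
                        scale = 1000, id = NULL) {
  if (is.list(x) && !is.null(x$counts)) {
    if (is.null(id)) id <- x$id
    x <- x$counts
  }
  stopifnot(is.matrix(x), nrow(x) == 4)
  if (is.null(rownames(x))) rownames(x) <- BASES
  x <- x[BASES, , drop = FALSE]
  cs <- colSums(x)
  if (any(cs <= 0)) stop("invalid PWM: empty column")
  W <- sweep(x, 2, cs, "/")
  k <- ncol(W)
  if (k < 4) stop("motif width must be >= 4")
  if (any(abs(colSums(W) - 1) > 1e-9)) stop("PPM columns must sum to 1")
  background <- background / sum(background)
  lo <- log2((W + pseudocount) / background)      # 4 x k log-odds
  iscore <- round(lo * scale)
  structure(list(id = if (is.null(id)) "motif" else id, ppm = W,
                 background = background, pseudocount = pseudocount,
                 scale = scale, iscore = iscore, width = k),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cons <- paste(BASES[apply(x$ppm, 2, which.max)], collapse = "")
  cat(sprintf("motif_model '%s': width %d, consensus %s\n", x$id, x$width, cons))
  invisible(x)
}

#' Exact null score distribution of a motif
#'
#' Dynamic programming over positions under the 0-order background model:
#' the exact probability mass function of the integer-scaled score of a
#' random k-mer.
#'
#' @param motif a `motif_model`.
#' @return list with `min` (smallest achievable integer score), `pmf`, and
#'   `tail` where `tail[s - min + 1] = P(score >= s)`.
#' @export
score_distribution <- function(motif) {
  is <- motif$iscore
  q <- motif$background
  lo_min <- sum(apply(is, 2, min))
  lo_max <- sum(apply(is, 2, max))
  pmf <- numeric(lo_max - lo_min + 1)
  # running support [cur_min, cur_min + length - 1]
  cur <- 1
  cur_min <- 0
  for (i in seq_len(motif$width)) {
    col <- is[, i]
    new_min <- cur_min + min(col)
    new_len <- (cur_min + max(col) + length(cur) - 1) - new_min + 1
    new <- numeric(new_len)
    for (b in 1:4) {
      off <- cur_min + col[b] - new_min
      idx <- (off + 1):(off + length(cur))
      new[idx] <- new[idx] + cur * q[b]
    }
    cur <- new
    cur_min <- new_min
  }
  stopifnot(cur_min == lo_min, length(cur) == lo_max - lo_min + 1)
  tail <- rev(cumsum(rev(cur)))
  list(min = lo_min, max = lo_max, pmf = cur, tail = tail)
}

#' Exact p-value for an integer-scaled motif score
#'
#' @param motif a `motif_model`.
#' @param iscore integer score(s) on the scaled grid.
#' @param dist optional precomputed [score_distribution()].
#' @return `P(score >= iscore)` under the background model.
#' @export
motif_pvalue <- function(motif, iscore, dist = score_distribution(motif)) {
  idx <- pmin(pmax(iscore - dist$min + 1, 1), length(dist$tail))
  p <- dist$tail[idx]
  p[iscore > dist$max] <- 0
  p[iscore <= dist$min] <- 1
  p
}

# internal: DNA string -> integer codes (A=1..T=4, else NA)
dna_codes <- function(s) {
  v <- utf8ToInt(toupper(s))
  code <- rep(NA_integer_, 128)
  code[utf8ToInt("A")] <- 1L; code[utf8ToInt("C")] <- 2L
  code[utf8ToInt("G")] <- 3L; code[utf8ToInt("T")] <- 4L
  code[v]
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# internal: integer window scores on one coded strand; NA where window has N
window_iscores <- function(codes, iscore) {
  k <- ncol(iscore)
  n <- length(codes) - k + 1
  if (n < 1) return(integer(0))
  s <- numeric(n)
  na <- rep(FALSE, n)
  idx <- seq_len(n)
  for (i in seq_len(k)) {
    ci <- codes[idx + i - 1L]
    na <- na | is.na(ci)
    s <- s + ifelse(is.na(ci), 0, iscore[ci, i])
  }
  s[na] <- NA
  s
}

#' Scan sequences for motif occurrences with exact p-values
#'
#' Both strands are scanned; windows containing `N` are skipped. Hits with
#' `p <= p_max` are reported with BH q-values computed over the total number
#' of scanned windows (both strands), the FIMO-like multiple-testing
#' universe.
#'
#' @param seqs named character vector of DNA sequences, or a
#'   `Biostrings::DNAStringSet`.
#' @param motif a `motif_model`.
#' @param p_max p-value threshold (default 1e-3, the published setting).
#' @param background `"seq"` to estimate the 0-order composition from the
#'   scanned sequences (default, with uniform fallback), `"uniform"`, or a
#'   length-4 numeric vector.
#' @return data.frame: `seqname`, `start`, `end` (0-based half-open within
#'   the sequence), `strand`, `score` (log2 odds), `p`, `q`,
#'   `matched_seq`, `motif_id`.
#' @export
scan_motifs <- function(seqs, motif, p_max = 1e-3, background = "seq") {
  if (methods::is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  if (is.null(names(seqs))) names(seqs) <- as.character(seq_along(seqs))
  if (identical(background, "seq")) {
    tab <- table(factor(strsplit(toupper(paste(seqs, collapse = "")), "")[[1]],
                        levels = BASES))
    bg <- as.numeric(tab)
    if (sum(bg) == 0 || any(bg == 0)) bg <- rep(0.25, 4) else bg <- bg / sum(bg)
  } else if (identical(background, "uniform")) {
    bg <- rep(0.25, 4)
  } else bg <- background / sum(background)
  motif <- motif_model(motif$ppm, background = bg,
                       pseudocount = motif$pseudocount, scale = motif$scale,
                       id = motif$id)
  dist <- score_distribution(motif)
  k <- motif$width
  out <- list()
  n_windows <- 0
  for (nm in names(seqs)) {
    s <- toupper(seqs[[nm]])
    L <- nchar(s)
    if (L < k) next
    for (strand in c("+", "-")) {
      str <- if (strand == "+") s else revcomp_chr(s)
      isc <- window_iscores(dna_codes(str), motif$iscore)
      ok <- !is.na(isc)
      n_windows <- n_windows + sum(ok)
      p <- rep(NA_real_, length(isc))
      p[ok] <- motif_pvalue(motif, isc[ok], dist)
      hit <- which(ok & p <= p_max)
      if (!length(hit)) next
      # map - strand windows back to forward coordinates
      start0 <- if (strand == "+") hit - 1L else L - (hit - 1L) - k
      out[[length(out) + 1]] <- data.frame(
        seqname = nm, start = start0, end = start0 + k, strand = strand,
        score = isc[hit] / motif$scale, p = p[hit],
        matched_seq = substring(str, hit, hit + k - 1),
        motif_id = motif$id, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(seqname = character(), start = integer(), end = integer(),
                      strand = character(), score = numeric(), p = numeric(),
                      q = numeric(), matched_seq = character(),
                      motif_id = character(), stringsAsFactors = FALSE))
  }
  hits <- do.call(rbind, out)
  ord <- order(hits$p)
  hits <- hits[ord, , drop = FALSE]
  h <- nrow(hits)
  q <- pmin(hits$p * n_windows / seq_len(h), 1)
  hits$q <- rev(cummin(rev(q)))
  hits <- hits[, c("seqname", "start", "end", "strand", "score", "p", "q",
                   "matched_seq", "motif_id")]
  rownames(hits) <- NULL
  hits
}

#' Scan motif occurrences inside peaks of a genome
#'
#' Extracts each peak's sequence from the genome, scans it with
#' [scan_motifs()], and lifts hit coordinates back to the genome.
#'
#' @param genome named character vector (or `DNAStringSet`) of chromosome
#'   sequences.
#' @param peaks peak data.frame.
#' @inheritParams scan_motifs
#' @return genomic hit data.frame (`chrom`, `start`, `end`, `strand`,
#'   `score`, `p`, `q`, `matched_seq`, `motif_id`, `peak_index`).
#' @export
scan_peaks_motifs <- function(genome, peaks, motif, p_max = 1e-3,
                              background = "seq") {
  if (methods::is(genome, "DNAStringSet")) genome <- as.character(genome)
  seqs <- character(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    seqs[i] <- substring(genome[[peaks$chrom[i]]], peaks$start[i] + 1, peaks$end[i])
  }
  names(seqs) <- as.character(seq_len(nrow(peaks)))
  hits <- scan_motifs(seqs, motif, p_max, background)
  i <- as.integer(hits$seqname)
  data.frame(chrom = peaks$chrom[i],
             start = peaks$start[i] + hits$start,
             end = peaks$start[i] + hits$end,
             strand = hits$strand, score = hits$score, p = hits$p, q = hits$q,
             matched_seq = hits$matched_seq, motif_id = hits$motif_id,
             peak_index = i, stringsAsFactors = FALSE)
}

#' Per-peak motif density
#'
#' Counts hits whose interval lies fully within each peak (containment;
#' hits straddling a peak edge are not counted). Both strands count.
#'
#' @param peaks peak data.frame (optionally with a class label column).
#' @param hits genomic hit data.frame (see [scan_peaks_motifs()]).
#' @return integer vector, one count per peak.
#' @export
motif_density <- function(peaks, hits) {
  if (nrow(hits) == 0) return(integer(nrow(peaks)))
  hg <- peaks_gr(peak_table(hits$chrom, hits$start, hits$end))
  pg <- peaks_gr(peaks)
  ov <- GenomicRanges::findOverlaps(hg, pg, type = "within")
  as.integer(tabulate(S4Vectors::subjectHits(ov), nbins = nrow(peaks)))
}

#' Motif strength comparison between peak classes
#'
#' Motif strength is the FIMO-style q-value of each hit (smaller = closer
#' to consensus). Returns the per-class q-value distributions and a
#' two-sided Mann-Whitney (Wilcoxon rank-sum) comparison between two named
#' classes; classes with fewer than 2 hits are excluded with a warning.
#'
#' @param hits genomic hit data.frame with a `q` column.
#' @param classes per-hit class label vector.
#' @param compare length-2 character: which classes to test (default the
#'   first two classes with enough hits).
#' @return list: `q_by_class`, `medians`, `compare`, `p` (rank-sum p, or NA
#'   if degenerate).
#' @export
motif_strength <- function(hits, classes, compare = NULL) {
  stopifnot(nrow(hits) == length(classes))
  q_by_class <- split(hits$q, classes)
  ok <- names(q_by_class)[lengths(q_by_class) >= 2]
  if (is.null(compare)) compare <- utils::head(ok, 2)
  p <- NA_real_
  if (length(compare) == 2 && all(compare %in% ok)) {
    p <- stats::wilcox.test(q_by_class[[compare[1]]], q_by_class[[compare[2]]],
                            exact = FALSE)$p.value
  } else {
    warning("motif_strength: not enough hits per class; rank-sum test skipped")
  }
  list(q_by_class = q_by_class,
       medians = vapply(q_by_class, stats::median, numeric(1)),
       compare = compare, p = p)
}
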