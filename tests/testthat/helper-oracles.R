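# Independent oracles used by the tests. These must stay independent of the
# implementation paths they check.

# brute-force exact motif p-values: enumerate all 4^k words, score each with
# the motif's integer-scaled log-odds, and sum background probabilities of
# words scoring at least s. Independent of the DP in score_distribution().
enumerate_motif_tail <- function(motif) {
  k <- motif$width
  stopifnot(k <= 8)
  is <- motif$iscore
  q <- motif$background
  words <- as.matrix(expand.grid(rep(list(1:4), k)))
  scores <- integer(nrow(words))
  probs <- rep(1, nrow(words))
  for (i in seq_len(k)) {
    scores <- scores + is[words[, i], i]
    probs <- probs * q[words[, i]]
  }
  o <- order(scores)
  s <- scores[o]
  p <- probs[o]
  # tail(sc) = sum of probs with score >= sc
  list(scores = s, tail = rev(cumsum(rev(p))))
}

oracle_pvalue <- function(enum, iscore) {
  vapply(iscore, function(s) {
    i <- match(TRUE, enum$scores >= s)
    if (is.na(i)) 0 else enum$tail[i]
  }, numeric(1))
}

# random position probability matrix of width k
random_ppm <- function(k, concentration = 1) {
  m <- matrix(stats::rgamma(4 * k, concentration), 4, k,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  sweep(m, 2, colSums(m), "/")
}

# brute-force median-of-ratios on a tiny table (independent arithmetic)
oracle_size_factors <- function(counts) {
  keep <- apply(counts > 0, 1, all)
  gm <- exp(rowMeans(log(counts[keep, , drop = FALSE])))
  apply(counts[keep, , drop = FALSE], 2, function(col) median(col / gm))
}

# two-proportion z-test oracle for the Poisson limit of the NB Wald test
oracle_two_prop_p <- function(ka, kb, na, nb) {
  # rates lambda_a, lambda_b; H0 equal. Unpooled normal approx on log rates.
  la <- ka / na; lb <- kb / nb
  se <- sqrt(1 / pmax(ka, 1) + 1 / pmax(kb, 1))
  z <- (log(lb) - log(la)) / se
  2 * stats::pnorm(-abs(z))
}

rc <- function(s) chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
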