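test_that("scan p-values equal brute-force enumeration for k <= 8", {
  set.seed(41)
  motifs <- c(list(gata6_synthetic_motif()),
              lapply(4:8, function(k)
                motif_model(random_ppm(k), id = paste0("rnd", k))))
  for (m in motifs) {
    enum <- enumerate_motif_tail(m)
    d <- score_distribution(m)
    # every achievable integer score agrees to >= 10 significant digits
    sc <- unique(enum$scores)
    expect_equal(motif_pvalue(m, sc, d), oracle_pvalue(enum, sc),
                 tolerance = 1e-12)
    # smallest achievable score has p = 1
    expect_equal(motif_pvalue(m, d$min, d), 1)
  }
})

test_that("consensus hit p equals the product of per-position max mass", {
  m <- gata6_synthetic_motif()   # uniform background by default
  d <- score_distribution(m)
  max_mass <- prod(apply(m$ppm, 2, function(col) 0.25 * sum(col == max(col))))
  expect_equal(motif_pvalue(m, d$max, d), max_mass, tolerance = 1e-12)
  hits <- scan_motifs(c(s = "AGATAAGA"), m, p_max = 1, background = "uniform")
  expect_equal(min(hits$p), max_mass, tolerance = 1e-12)
})

test_that("scanning is strand-symmetric and skips N windows", {
  set.seed(42)
  m <- gata6_synthetic_motif()
  seq <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
  seq <- paste0(substr(seq, 1, 200), "AGATAAGA", substr(seq, 209, 500))
  h1 <- scan_motifs(c(x = seq), m, p_max = 1e-3, background = "uniform")
  h2 <- scan_motifs(c(x = rc(seq)), m, p_max = 1e-3, background = "uniform")
  expect_equal(nrow(h1), nrow(h2))
  # coordinates mirror: start' = L - end
  L <- nchar(seq)
  expect_setequal(L - h2$end, h1$start)
  expect_setequal(paste(h1$start, h1$strand),
                  paste(L - h2$end, chartr("+-", "-+", h2$strand)))
  # N windows are skipped entirely
  nn <- scan_motifs(c(x = paste0("AGAT", "N", "AGA")), m, p_max = 1)
  expect_equal(nrow(nn), 0)
  # specificity: no planted motif, tiny threshold, ~0 hits
  rnd <- paste(sample(c("A", "C", "G", "T"), 5000, TRUE), collapse = "")
  expect_lte(nrow(scan_motifs(c(x = rnd), m, p_max = 1e-6,
                              background = "uniform")), 1)
})

test_that("motif density counts contained hits only", {
  peaks <- peak_table("chr1", c(100, 500), c(200, 600))
  hits <- data.frame(chrom = "chr1",
                     start = c(110, 150, 180, 195, 510),
                     end = c(118, 158, 188, 203, 518))
  # 195-203 straddles the first peak's edge -> not counted
  expect_equal(motif_density(peaks, hits), c(3L, 1L))
  expect_equal(motif_density(peaks, hits[0, ]), c(0L, 0L))
})

test_that("density and strength are invariant under genome translation", {
  set.seed(44)
  sim <- cached_sim(c("genome", "peaks_tracks"))
  genome <- Biostrings::readDNAStringSet(sim$paths$genome)
  m <- gata6_synthetic_motif()
  cres <- sim$truth$cres
  sel <- which(cres$class %in% c("Epi", "PrE_early_open"))[1:40]
  pk <- peak_table(cres$chrom[sel], cres$start[sel], cres$end[sel])
  h1 <- scan_peaks_motifs(genome, pk, m)
  # translate: prepend 1 kb of A to chr1 and shift chr1 peaks
  g2 <- as.character(genome)
  g2[["chr1"]] <- paste0(strrep("A", 1000), g2[["chr1"]])
  pk2 <- pk
  pk2$start <- pk2$start + ifelse(pk2$chrom == "chr1", 1000, 0)
  pk2$end <- pk2$end + ifelse(pk2$chrom == "chr1", 1000, 0)
  h2 <- scan_peaks_motifs(g2, pk2, m)
  expect_equal(motif_density(pk, h1), motif_density(pk2, h2))
  expect_equal(sort(h1$q), sort(h2$q), tolerance = 1e-12)
})

test_that("planted PrE motifs are denser and stronger than Epi motifs", {
  sim <- cached_sim(c("genome", "peaks_tracks"))
  genome <- Biostrings::readDNAStringSet(sim$paths$genome)
  m <- motif_model(read_pwm_jaspar(sim$paths$pfm))
  cres <- sim$truth$cres
  sel <- cres$class %in% c("Epi", "PrE_early_open", "PrE_early_closed")
  pk <- peak_table(cres$chrom[sel], cres$start[sel], cres$end[sel])
  cls <- ifelse(cres$class[sel] == "Epi", "Epi", "PrE")
  hits <- scan_peaks_motifs(genome, pk, m, p_max = 1e-3)
  dens <- motif_density(pk, hits)
  expect_gt(mean(dens[cls == "PrE"]), mean(dens[cls == "Epi"]))
  st <- motif_strength(hits, cls[hits$peak_index], compare = c("Epi", "PrE"))
  expect_lt(st$medians[["PrE"]], st$medians[["Epi"]])
  expect_lt(st$p, 0.01)
})

test_that("degenerate strength comparisons warn and skip the test", {
  hits <- data.frame(chrom = "chr1", start = c(1, 10), end = c(9, 18),
                     q = c(0.1, 0.2))
  expect_warning(st <- motif_strength(hits, c("A", "B")), "skipped")
  expect_true(is.na(st$p))
})

test_that("invalid PWMs are rejected", {
  bad <- matrix(c(0.5, 0.5, 0.2, 0.2), 4, 2)   # columns do not sum to 1
  rownames(bad) <- c("A", "C", "G", "T")
  expect_error(motif_model(rbind(bad, bad)[1:4, 1:2, drop = FALSE]))
  expect_error(motif_model(random_ppm(3)), "width")
})
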