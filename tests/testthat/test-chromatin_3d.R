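test_that("sliding window count matches floor((L-win)/step)+1", {
  w <- sliding_windows(10000, 5000, 500)
  expect_equal(nrow(w), 11)
  expect_equal(w$start[1], 0)
  expect_equal(w$end[11], 10000)
  for (L in c(5000, 7300, 50000)) for (win in c(2000, 5000))
    for (step in c(250, 500, 1000)) {
      if (L < win) next
      expect_equal(nrow(sliding_windows(L, win, step)),
                   (L - win) %/% step + 1)
    }
  expect_error(sliding_windows(4000, 5000, 500), "shorter")
})

test_that("window differential finds planted gains and respects the null", {
  vs <- simulate_viewpoints(seed = 21)
  gain <- window_differential(vs$profiles$vp_gain, c("48h", "0h"))
  seg <- vs$truth[vs$truth$id == "vp_gain", ]
  hit <- any(gain$significant$start < seg$seg_end &
             gain$significant$end > seg$seg_start)
  expect_true(hit)
  null <- window_differential(vs$profiles$vp_null, c("48h", "0h"))
  expect_lte(nrow(null$significant), 1)
  # loss detected with negative fold change
  loss <- window_differential(vs$profiles$vp_loss, c("48h", "0h"))
  sigw <- loss$windows[!is.na(loss$windows$padj) & loss$windows$padj < 0.01, ]
  expect_true(all(sigw$log2fc < 0))
})

test_that("compartment eigenvector splits the two blocks exactly", {
  cm <- simulate_contacts(seed = 1, noise = FALSE)
  ref <- cm$reference[cm$reference$chrom == "chr1", "score"]
  a <- compartment_eigen(cm$matrices$chr1_0h, ref)
  expect_true(all(a$eigen[1:20] > 0))
  expect_true(all(a$eigen[21:40] < 0))
  # matches dense eigendecomposition to 1e-8
  e <- eigen(a$cor)
  v <- e$vectors[, 1]
  if (sum(v * a$eigen) < 0) v <- -v
  expect_lt(max(abs(v - a$eigen)), 1e-8)
  # negating the reference flips every sign
  b <- compartment_eigen(cm$matrices$chr1_0h, -ref)
  expect_equal(b$eigen, -a$eigen)
})

test_that("bin permutation preserves the compartment assignment", {
  # the observed/expected step is distance-aware, so exact value-level
  # equivariance does not hold; the compartment calls (signs) do
  cm <- simulate_contacts(seed = 2)
  ref <- cm$reference[cm$reference$chrom == "chr1", "score"]
  a <- compartment_eigen(cm$matrices$chr1_0h, ref)
  set.seed(5)
  perm <- sample(40)
  ap <- compartment_eigen(cm$matrices$chr1_0h[perm, perm], ref[perm])
  expect_identical(sign(ap$eigen), sign(a$eigen[perm]))
  expect_gt(cor(ap$eigen, a$eigen[perm]), 0.99)
})

test_that("switch calls recover planted flips with correct direction", {
  cm <- simulate_contacts(seed = 3)
  ref <- cm$reference[cm$reference$chrom == "chr1", "score"]
  a <- compartment_eigen(cm$matrices$chr1_0h, ref)
  b <- compartment_eigen(cm$matrices$chr1_48h, ref)
  sw <- compartment_switches(a, b)
  expect_equal(which(sw$switch), c(5, 25))
  expect_equal(sw$direction[5], "A->B")     # bin 5 is A in the ref condition
  expect_equal(sw$direction[25], "B->A")
  # identical conditions: r = 1 everywhere, no switches
  sw0 <- compartment_switches(a, a)
  expect_true(all(abs(sw0$r - 1) < 1e-12))
  expect_false(any(sw0$switch))
  expect_error(compartment_switches(a, list(cor = matrix(0, 3, 3),
                                            eigen = 1:3, masked = integer())),
               "grids")
})

test_that("the switch rule is strict: r equal to the threshold is kept", {
  # inject synthetic profiles with a known near-0.4 row correlation, then
  # set the threshold to the computed r itself: strict '<' must not fire
  n <- 12
  x <- scale(seq(-1, 1, length.out = n))[, 1]
  y <- 0.4 * x + sqrt(1 - 0.16) * scale(x^2)[, 1]
  A <- list(cor = outer(rep(1, n), x), eigen = rep(1, n), masked = integer())
  Bc <- A$cor
  Bc[1, ] <- y
  B <- list(cor = Bc, eigen = rep(1, n), masked = integer())
  sw <- compartment_switches(A, B, r_max = 0.4)
  expect_equal(sw$r[1], 0.4, tolerance = 1e-9)
  r_obs <- sw$r[1]
  expect_false(compartment_switches(A, B, r_max = r_obs)$switch[1])
  expect_true(compartment_switches(A, B, r_max = r_obs + 1e-9)$switch[1])
})

test_that("all-zero rows are masked and excluded", {
  cm <- simulate_contacts(seed = 4, noise = FALSE)
  m <- cm$matrices$chr1_0h
  m[7, ] <- 0; m[, 7] <- 0
  ref <- cm$reference[cm$reference$chrom == "chr1", "score"]
  a <- compartment_eigen(m, ref)
  expect_equal(a$masked, 7)
  expect_true(is.na(a$eigen[7]))
  expect_equal(sum(is.na(a$eigen)), 1)
})

test_that("null contact matrices rarely switch", {
  n_sw <- vapply(1:10, function(s) {
    cm <- simulate_contacts(seed = 100 + s, switch_bins = integer())
    ref <- cm$reference[cm$reference$chrom == "chr1", "score"]
    a <- compartment_eigen(cm$matrices$chr1_0h, ref)
    b <- compartment_eigen(cm$matrices$chr1_48h, ref)
    sum(compartment_switches(a, b)$switch, na.rm = TRUE)
  }, numeric(1))
  expect_lte(mean(n_sw) / 40, 0.02)
})
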