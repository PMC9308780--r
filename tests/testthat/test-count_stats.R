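test_that("size factors match the median-of-ratios definition", {
  m <- matrix(c(10, 20, 30, 10, 20, 30), ncol = 2,
              dimnames = list(paste0("f", 1:3), c("a", "b")))
  expect_equal(unname(size_factors_median_of_ratios(m)), c(1, 1))
  m2 <- cbind(a = c(10, 20, 30), b = c(20, 40, 60))
  sf <- size_factors_median_of_ratios(m2)
  expect_equal(unname(sf[2] / sf[1]), 2)
  # toy table vs brute-force oracle
  set.seed(21)
  toy <- matrix(rpois(15, 50) + 1, 5, 3,
                dimnames = list(paste0("f", 1:5), paste0("s", 1:3)))
  expect_equal(unname(size_factors_median_of_ratios(toy)),
               unname(oracle_size_factors(toy)))
  zeros <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_error(size_factors_median_of_ratios(zeros), "pseudo-reference")
})

test_that("BH adjustment matches hand computation and caps at 1", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.42), 0.42)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(2)
  p <- runif(100)
  expect_true(all(bh_adjust(p) >= p))
})

test_that("NB Wald test is calibrated on null data and handles degenerates", {
  set.seed(101)
  mu <- exp(runif(4000, log(20), log(500)))
  counts <- matrix(rnbinom(4000 * 4, mu = rep(mu, each = 4), size = 10),
                   ncol = 4, byrow = TRUE,
                   dimnames = list(paste0("f", 1:4000), paste0("s", 1:4)))
  res <- nb_wald_test(counts, c("A", "A", "B", "B"), c("B", "A"))
  expect_gt(mean(res$p < 0.05), 0.03)
  expect_lt(mean(res$p < 0.05), 0.07)
  expect_true(all(res$padj >= res$p - 1e-12))
  # all-zero feature: lfc 0, p 1
  counts2 <- rbind(counts[1:5, ], zero = rep(0, 4))
  res2 <- nb_wald_test(counts2, c("A", "A", "B", "B"), c("B", "A"),
                       size_factors = rep(1, 4))
  expect_equal(res2$log2fc[res2$feature == "zero"], 0)
  expect_equal(res2$p[res2$feature == "zero"], 1)
  expect_error(nb_wald_test(counts, c("A", "A", "B", "B"), c("C", "A")),
               "absent")
})

test_that("planted fold changes are recovered (see ledger: ~85% within 0.5)", {
  set.seed(55)
  mu <- c(100, 100, 400, 400)
  counts <- t(vapply(1:3000, function(i) rnbinom(4, mu = mu, size = 20),
                     numeric(4)))
  rownames(counts) <- paste0("f", 1:3000)
  res <- nb_wald_test(counts, c("A", "A", "B", "B"), c("B", "A"),
                      size_factors = rep(1, 4))
  # delta method gives sd(log2fc) ~ 0.34 at these parameters, so the
  # attainable fraction within 0.5 is ~0.856, not the nominal 0.9
  expect_gt(mean(abs(res$log2fc - 2) < 0.5), 0.8)
  expect_lt(abs(median(res$log2fc) - 2), 0.05)
})

test_that("Wald p agrees with a two-proportion oracle in the Poisson limit", {
  set.seed(77)
  mu <- rep(2000, 1000) * exp(rnorm(1000, 0, 0.05))
  counts <- cbind(rpois(1000, mu), rpois(1000, mu),
                  rpois(1000, mu), rpois(1000, mu))
  rownames(counts) <- paste0("f", 1:1000)
  res <- nb_wald_test(counts, c("A", "A", "B", "B"), c("B", "A"),
                      size_factors = rep(1, 4))
  ka <- counts[, 1] + counts[, 2]
  kb <- counts[, 3] + counts[, 4]
  po <- oracle_two_prop_p(ka, kb, 2, 2)
  rel <- abs(res$p - po) / pmax(po, 1e-12)
  expect_lt(median(rel), 0.1)
})

test_that("up/stable/down classification applies the published thresholds", {
  res <- data.frame(log2fc = c(2.5, 2.5, -2.0, 1.9, -2.5),
                    padj = c(1e-5, 0.01, 0.05, 1e-9, NA))
  # ATAC thresholds: padj < 1e-4, |lfc| >= 2
  expect_equal(classify_features(res, 2, 1e-4),
               c("up", "stable", "stable", "stable", "stable"))
  # RNA thresholds: FDR < 0.1, |lfc| >= 2
  expect_equal(classify_features(res, 2, 0.1),
               c("up", "up", "down", "stable", "stable"))
  expect_error(classify_features(res, -1, 0.1), "positive")
})

test_that("FDR is controlled on null simulations", {
  set.seed(303)
  fdp <- replicate(5, {
    mu <- exp(runif(2000, log(50), log(300)))
    counts <- matrix(rnbinom(2000 * 4, mu = rep(mu, each = 4), size = 10),
                     ncol = 4, byrow = TRUE,
                     dimnames = list(paste0("f", 1:2000), NULL))
    res <- nb_wald_test(counts, c("A", "A", "B", "B"), c("B", "A"))
    mean(res$padj < 0.1)  # every discovery on a null is false
  })
  expect_lte(mean(fdp), 0.15)
})
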