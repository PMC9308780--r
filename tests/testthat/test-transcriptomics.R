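test_that("transgene T/E follows the CDS - UTR definition", {
  seg <- rbind(CDS_last_exon = c(100, 200), UTR3 = c(100, 200) * 800 / 1200)
  colnames(seg) <- c("s1", "s2")
  lib <- c(s1 = 1e6, s2 = 2e6)
  len <- c(CDS_last_exon = 1200, UTR3 = 800)
  # CDS and UTR normalized values equal -> T = 0, ratio 0
  tr <- transgene_ratio(seg, lib, len, c("s1", "s2"))
  expect_equal(unname(tr$T), c(0, 0))
  expect_equal(unname(tr$ratio), c(0, 0))
  # library scaling invariance: proportional counts, doubled library
  seg2 <- rbind(CDS_last_exon = c(120, 240), UTR3 = c(40, 80))
  colnames(seg2) <- c("s1", "s2")
  tr2 <- transgene_ratio(seg2, lib, len, c("s1", "s2"))
  expect_equal(tr2$cds_norm[["s1"]], tr2$cds_norm[["s2"]])
  expect_equal(tr2$ratio[["s1"]], tr2$ratio[["s2"]])
  seg_named <- function(cds, utr) {
    m <- rbind(CDS_last_exon = cds, UTR3 = utr)
    colnames(m) <- c("s1", "s2")
    m
  }
  expect_error(transgene_ratio(seg_named(c(1, 1), c(0, 0)), lib, len,
                               c("s1", "s2")), "zero")
  expect_warning(transgene_ratio(seg_named(c(1, 90), c(90, 90)), lib, len,
                                 c("s1", "s2")), "negative")
})

test_that("noiseless synthetic counts recover the planted ratio exactly", {
  tg <- simulate_transgene(seed = 1, dispersion = 0)
  # expected counts instead of draws: recompute means analytically
  # (dispersion 0 still draws Poisson; build the exact case by hand)
  len <- c(CDS_last_exon = 1200, UTR3 = 800)
  lib <- c(a = 1e6, b = 1e6, r1 = 1e6, r2 = 1e6)
  e <- 10; trg <- c(30, 15, 0, 0)                    # planted rates
  seg <- rbind(CDS_last_exon = (e + trg) * 1.2, UTR3 = rep(e * 0.8, 4))
  colnames(seg) <- names(lib)
  out <- transgene_ratio(seg, lib, len, c("r1", "r2"))
  expect_equal(unname(out$ratio), trg / e, tolerance = 1e-12)
})

test_that("lineage gene lists intersect two differential tables", {
  deA <- data.frame(feature = c("g1", "g2", "g3", "g4", "g5"),
                    log2fc = c(3, 3, -3, 3, -3),
                    padj = c(0.01, 0.01, 0.01, 0.01, 0.01))
  deB <- data.frame(feature = c("g1", "g2", "g3", "g4", "g6"),
                    log2fc = c(3, 0, -3, -3, -3),
                    padj = c(0.01, 0.01, 0.01, 0.01, 0.01))
  out <- intersect_lineage_genes(deA, deB)
  expect_equal(out$pre, "g1")      # up in both
  expect_equal(out$epi, "g3")      # down in both
  # g2: up in A only; g4: direction conflict; g5/g6: absent in one table
  expect_false(any(c("g2", "g4", "g5", "g6") %in% unlist(out)))
})

test_that("first-change timepoints use either contrast at each step", {
  tab <- function(g, lfc, padj) data.frame(feature = g, log2fc = lfc,
                                           padj = padj)
  genes <- c("early", "late_prev", "never")
  vs0 <- list("2" = tab(genes, c(3, 0, 0), c(0.01, 1, 1)),
              "8" = tab(genes, c(3, 0.5, 0), c(0.01, 1, 1)))
  vsprev <- list("2" = tab(genes, c(0, 0, 0), c(1, 1, 1)),
                 "8" = tab(genes, c(0, 3, 0), c(1, 0.01, 1)))
  out <- de_timecourse(vs0, vsprev)
  expect_equal(out$first_change[out$gene == "early"], "2")
  expect_equal(out$first_change[out$gene == "late_prev"], "8")
  expect_true(is.na(out$first_change[out$gene == "never"]))
  expect_equal(out$direction[out$gene == "early"], "up")
})

test_that("planted DE onsets are recovered from the RNA counts", {
  sim <- cached_sim("rna")
  counts <- read_count_table(sim$paths$rna_counts)
  meta <- as.data.frame(data.table::fread(sim$paths$rna_meta))
  cond <- meta$condition[match(colnames(counts), meta$sample)]
  res48 <- nb_wald_test(counts, cond, c("48h", "0h"))
  cls <- classify_features(res48, 2, 0.1)
  lin <- sim$truth$genes$lineage[match(res48$feature,
                                       sim$truth$genes$gene_id)]
  expect_gt(mean(cls[lin == "Epi"] == "down"), 0.8)
  expect_gt(mean(cls[lin == "PrE"] == "up"), 0.8)
  expect_gt(mean(cls[lin == "other"] == "stable"), 0.9)
})

test_that("residual PCA staging recovers planted clusters; residual identity", {
  st <- simulate_staging(seed = 11)
  m <- stage_bulk_on_sc(st$bulk, st$sc, st$clusters)
  expect_equal(m$mapping$cluster, st$truth$cluster)
  # least-squares identity: per-gene group means of residuals are 0
  for (g in unique(m$group))
    expect_lt(max(abs(colMeans(m$residuals[m$group == g, , drop = FALSE]))),
              1e-10)
  # swapping group labels leaves residuals unchanged
  m2 <- stage_bulk_on_sc(st$bulk, st$sc, st$clusters)
  expect_equal(m$residuals, m2$residuals)
  # degenerate constant input errors
  const_bulk <- matrix(5, 10, 4, dimnames = list(paste0("g", 1:10),
                                                 paste0("s", 1:4)))
  const_sc <- matrix(5, 10, 6, dimnames = list(paste0("g", 1:10),
                                               paste0("c", 1:6)))
  cl <- setNames(rep(c("k1", "k2"), 3), colnames(const_sc))
  expect_error(stage_bulk_on_sc(const_bulk, const_sc, cl), "degenerate")
})

test_that("cluster merging pools raw clusters before averaging", {
  st <- simulate_staging(seed = 12)
  # split E3.5_PrE cells into two raw labels, then merge them back
  cl <- st$clusters
  idx <- which(cl == "E3.5_PrE")
  cl[idx[seq(1, length(idx), 2)]] <- "E3.5:0"
  cl[idx[seq(2, length(idx), 2)]] <- "E3.5:4"
  m <- stage_bulk_on_sc(st$bulk, st$sc, cl,
                        cluster_merge = c("E3.5:0" = "E3.5_PrE",
                                          "E3.5:4" = "E3.5_PrE"))
  expect_equal(m$mapping$cluster, st$truth$cluster)
})
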