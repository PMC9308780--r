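test_that("peak reading parses BED and narrowPeak, converting -log10 q", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200", "chr2\t0\t50"), bed)
  p <- read_peaks(bed, "bed")
  expect_equal(p$chrom, c("chr1", "chr2"))
  expect_equal(p$start, c(100, 0))
  expect_equal(p$end, c(200, 50))

  np <- tempfile(fileext = ".narrowPeak")
  writeLines("chr1\t100\t200\tpk1\t50\t.\t8.5\t4\t2.0\t30", np)
  q <- read_peaks(np, "narrowPeak")
  expect_equal(q$qvalue, 0.01)          # 10^-2
  expect_equal(q$signal, 8.5)

  empty <- tempfile()
  file.create(empty)
  expect_equal(nrow(read_peaks(empty, "bed")), 0)
})

test_that("malformed peak lines raise errors naming the line", {
  bad <- tempfile()
  writeLines(c("chr1\t1\t2", "chr1\tnope"), bad)
  expect_error(read_peaks(bad, "bed"), "line 2")
  expect_error(read_peaks(tempfile(), "bed"), "no such file")
})

test_that("peak write/read round-trips coordinates and scores exactly", {
  set.seed(11)
  p <- peak_table(sample(c("chr1", "chr2"), 30, TRUE),
                  s <- sample.int(1e6, 30), s + sample.int(500, 30),
                  name = sprintf("p%02d", 1:30),
                  score = runif(30) * 1000,
                  signal = rexp(30), qvalue = runif(30))
  for (fmt in c("bed", "narrowPeak")) {
    f <- tempfile()
    write_peaks(p, f, fmt)
    q <- read_peaks(f, fmt)
    expect_identical(q$chrom, p$chrom)
    expect_equal(q$start, p$start)
    expect_equal(q$end, p$end)
    expect_equal(q$score, p$score)
    if (fmt == "narrowPeak") expect_equal(q$qvalue, p$qvalue, tolerance = 1e-12)
  }
})

test_that("overlaps follows half-open semantics and is symmetric", {
  a <- list(chrom = "chr1", start = 100, end = 200)
  expect_true(overlaps(a, list(chrom = "chr1", start = 199, end = 300)))
  expect_false(overlaps(a, list(chrom = "chr1", start = 200, end = 300)))
  expect_false(overlaps(a, list(chrom = "chr2", start = 100, end = 200)))
  # property: symmetric; disjoint intervals never overlap
  set.seed(3)
  for (i in 1:50) {
    x <- list(chrom = "chr1", start = s1 <- sample.int(1000, 1),
              end = s1 + sample.int(100, 1))
    y <- list(chrom = "chr1", start = s2 <- sample.int(1000, 1),
              end = s2 + sample.int(100, 1))
    expect_identical(overlaps(x, y), overlaps(y, x))
    if (x$end <= y$start || y$end <= x$start) expect_false(overlaps(x, y))
  }
})

test_that("track_stat weights partial bins by bp overlap", {
  tr <- signal_track(list(chr1 = rep(2, 100)), 10)
  expect_equal(track_stat(tr, "chr1", 3, 977, "mean"), 2)
  tr2 <- signal_track(list(chr1 = c(1, 3)), 10)
  expect_equal(track_stat(tr2, "chr1", 0, 20, "sum"), 40)  # 1*10 + 3*10
  # partial bins: [5,15) covers half of each bin
  expect_equal(track_stat(tr2, "chr1", 5, 15, "sum"), 1 * 5 + 3 * 5)
  expect_equal(track_stat(tr2, "chr1", 5, 15, "mean"), 2)
  expect_equal(track_stat(signal_track(list(chr1 = numeric(10)), 10),
                          "chr1", 0, 100, "mean"), 0)
  expect_error(track_stat(tr2, "chr1", 10, 30), "outside")
  expect_error(signal_track(list(chr1 = c(1, -1)), 10), "finite")
})

test_that("bedGraph round-trips a binned track (zeros omitted, runs merged)", {
  set.seed(4)
  v <- numeric(200)
  v[30:60] <- round(rexp(31) * 10, 3)
  tr <- signal_track(list(chr1 = v, chr2 = numeric(50)), 25)
  f <- tempfile(fileext = ".bedGraph")
  write_bedgraph(tr, f)
  back <- read_bedgraph(f, 25, chrom_lengths = c(chr1 = 5000, chr2 = 1250))
  expect_equal(back$values$chr1, v, tolerance = 1e-9)
  expect_equal(back$values$chr2, numeric(50))
})

test_that("fragment filters apply the published strict cuts", {
  fr <- data.frame(chrom = "chr1", start = 0,
                   end = c(119, 120, 150, 151, 180, 181))
  expect_equal(filter_fragments(fr, "tf")$end, 119)            # < 120 kept
  expect_equal(filter_fragments(fr, "histone")$end, c(151, 180, 181)) # > 150
  expect_equal(filter_fragments(fr, "nucleosomal_atac")$end, 181)     # > 180
  expect_error(filter_fragments(fr, "nope"))
  # property: tf and histone sets are disjoint for any input
  set.seed(9)
  rnd <- data.frame(chrom = "chr1", start = 0, end = sample(20:400, 200, TRUE))
  tf <- filter_fragments(rnd, "tf")
  hist <- filter_fragments(rnd, "histone")
  expect_length(intersect(rownames(tf), rownames(hist)), 0)
})

test_that("gene tables convert 1-based GTF-like input and derive the TSS", {
  f <- tempfile()
  writeLines(c("gene_id\tchrom\tstart\tend\tstrand\tlineage",
               "g1\tchr1\t1001\t2000\t+\tEpi",
               "g2\tchr1\t5001\t6000\t-\tPrE"), f)
  g <- read_genes(f)
  expect_equal(g$start, c(1000, 5000))   # 0-based
  expect_equal(g$tss, c(1000, 5999))     # strand-aware
})

test_that("JASPAR PFM parsing recovers the count matrix", {
  f <- tempfile(fileext = ".pfm")
  writeLines(c(">M1 test", "A [ 10 0 3 ]", "C [ 0 10 3 ]",
               "G [ 0 0 3 ]", "T [ 0 0 1 ]"), f)
  p <- read_pwm_jaspar(f)
  expect_equal(p$id, "M1 test")
  expect_equal(unname(p$counts["A", ]), c(10, 0, 3))
  expect_equal(unname(p$counts["T", ]), c(0, 0, 1))
})
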