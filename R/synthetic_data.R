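# Synthetic multi-omic time course with planted ground truth.
#
# The generator emulates the statistical structure of a doxycycline-induced
# GATA6 differentiation experiment: a 9-timepoint course (0-48 h) with
# planted Epi CREs (high NANOG/SOX2 at 0 h, transient GATA6 at 2-8 h,
# decaying accessibility/H3K27ac), PrE CREs bound early (from 2 h, split by
# 0 h accessibility) or only late (48 h), NANOG redistribution at 2 h onto
# GATA6-opened sites, negative-binomial replicate counts, bimodal fragment
# lengths, matched bulk/single-cell RNA trajectories, viewpoint interaction
# gains/losses and two-compartment toy contact matrices with a minority of
# switching bins. Planted mean trajectories are deterministic (they stand
# for replicate-pooled normalized coverage); stochastic noise lives in the
# count tables.

ASSAYS <- c("GATA6", "NANOG", "SOX2", "ATAC", "H3K27ac")

#' Simulation configuration
#'
#' Defaults define the package's stated synthetic world; see the methods
#' vignette for the rationale of each value.
#'
#' @param seed root seed; all randomness derives from it via named
#'   substreams, so adding one assay never perturbs the others.
#' @param n_chroms,chrom_length_bp genome geometry (2 x 10 Mb: large enough
#'   for 40 bins at 250 kb, small enough for seconds-scale runs).
#' @param n_epi_cres,n_pre_cres_early,n_pre_cres_late,n_background_peaks
#'   planted feature counts; early PrE CREs are split evenly into
#'   open-at-0h and closed-at-0h.
#' @param timepoints hours; default `c(0,2,4,8,16,24,32,40,48)`.
#' @param n_replicates replicates per timepoint for count tables.
#' @param nb_dispersion NB dispersion of replicate counts.
#' @param depth mean counts per feature at full signal.
#' @param motif_density_epi,motif_density_pre mean planted GATA6 motifs per
#'   CRE (Poisson).
#' @param motif_strength_epi,motif_strength_pre per-base mutation rate
#'   applied to the consensus when planting (higher = weaker motifs).
#' @param nanog_relocation strength of the 2 h NANOG redistribution onto
#'   GATA6-opened sites (0 disables it).
#' @param bin_size signal-track bin width in bp.
#' @param peak_width planted CRE width in bp.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_chroms = 2, chrom_length_bp = 1e7,
                       n_epi_cres = 120, n_pre_cres_early = 120,
                       n_pre_cres_late = 60, n_background_peaks = 100,
                       timepoints = c(0, 2, 4, 8, 16, 24, 32, 40, 48),
                       n_replicates = 2, nb_dispersion = 0.05, depth = 200,
                       motif_density_epi = 1, motif_density_pre = 3,
                       motif_strength_epi = 0.15, motif_strength_pre = 0.02,
                       nanog_relocation = 1, bin_size = 50, peak_width = 600) {
  cfg <- as.list(environment())
  stopifnot(all(diff(timepoints) > 0),
            n_chroms >= 1, chrom_length_bp >= 1e6,
            n_replicates >= 1, nb_dispersion >= 0, depth > 0)
  class(cfg) <- "sim_config"
  cfg
}

# deterministic substream seed from root seed and stream name
subseed <- function(seed, name) {
  h <- 0
  for (c in utf8ToInt(name)) h <- (h * 131 + c) %% 1000003
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

#' Negative-binomial replicate counts
#'
#' Draws with `variance = mean + dispersion * mean^2`; `dispersion = 0`
#' degenerates to Poisson.
#'
#' @param mean mean (scalar or vector, recycled over `n` draws each).
#' @param dispersion NB dispersion (>= 0).
#' @param n draws per mean value.
#' @param seed optional seed applied before drawing.
#' @return integer vector of length `n * length(mean)` (mean-major).
#' @export
planted_counts <- function(mean, dispersion, n, seed = NULL) {
  stopifnot(all(mean > 0), dispersion >= 0, n >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (n == 0) return(integer(0))
  mu <- rep(mean, each = n)
  if (dispersion == 0) stats::rpois(length(mu), mu)
  else stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
}

# --- planted mean trajectories -------------------------------------------

logistic_rise <- function(t, t0, tau) 1 / (1 + exp(-(t - t0) / tau))
transient_pulse <- function(t) ifelse(t <= 0, 0, (t / 2) * exp(1 - t / 2))

# mean signal amplitude for one CRE class / assay at times t; `a` is the
# per-CRE accessibility-gain factor coupling ATAC opening and NANOG
# relocation on closed early PrE CREs.
planted_trajectory <- function(class, assay, t, relocation = 1, a = 1) {
  switch(paste(class, assay, sep = "."),
    # eviction couples to relocation: the signal gained at GATA6-opened
    # sites is lost from the pre-existing Epi sites at the same time
    "Epi.NANOG"              = 30 * exp(-t / 6) *
                               (1 - 0.5 * relocation * transient_pulse(t)),
    "Epi.SOX2"               = 24 * exp(-t / 6) *
                               (1 - 0.5 * relocation * transient_pulse(t)),
    "Epi.GATA6"              = 25 * transient_pulse(t),
    "Epi.ATAC"               = 30 * (0.05 + 0.95 * exp(-t / 8)),
    "Epi.H3K27ac"            = 25 * (0.1 + 0.9 * exp(-t / 10)),
    "PrE_early_open.GATA6"   = 30 * logistic_rise(t, 2, 0.8),
    "PrE_early_open.ATAC"    = 25 * (1 + 0.3 * logistic_rise(t, 8, 4)),
    "PrE_early_open.NANOG"   = relocation * 20 * transient_pulse(t),
    "PrE_early_open.SOX2"    = relocation * 16 * transient_pulse(t),
    "PrE_early_open.H3K27ac" = 25 * logistic_rise(t, 16, 5),
    "PrE_early_closed.GATA6" = 30 * logistic_rise(t, 2, 0.8),
    "PrE_early_closed.ATAC"  = a * 25 * logistic_rise(t, 4, 1.5),
    "PrE_early_closed.NANOG" = relocation * a * 20 * transient_pulse(t),
    "PrE_early_closed.SOX2"  = relocation * a * 16 * transient_pulse(t),
    "PrE_early_closed.H3K27ac" = 25 * logistic_rise(t, 20, 5),
    "PrE_late.GATA6"         = 30 * logistic_rise(t, 40, 3),
    "PrE_late.ATAC"          = 20 * logistic_rise(t, 36, 4),
    "PrE_late.H3K27ac"       = 20 * logistic_rise(t, 44, 3),
    "background.ATAC"        = rep(15, length(t)),
    "background.H3K27ac"     = rep(12, length(t)),
    rep(0, length(t)))
}

PEAK_MIN_SIGNAL <- 5   # a CRE emits a peak when its planted mean exceeds this

# GATA6 taxonomy implied by the planted class
truth_gata6_category <- function(class) {
  switch(class,
         Epi = "early_open_0h",
         PrE_early_open = "early_open_0h",
         PrE_early_closed = "early_closed_0h",
         PrE_late = "late",
         NA_character_)
}

# NANOG 2 h cluster implied by the planted class
truth_nanog_cluster <- function(class) {
  switch(class,
         Epi = "c1_preexisting",
         PrE_early_open = "c2_denovo_open",
         PrE_early_closed = "c3_denovo_closed",
         NA_character_)
}

# --- synthetic GATA6 motif ------------------------------------------------

GATA6_CONSENSUS <- "AGATAAGA"

synthetic_gata6_pfm <- function() {
  k <- nchar(GATA6_CONSENSUS)
  counts <- matrix(1, 4, k, dimnames = list(BASES, NULL))
  idx <- match(strsplit(GATA6_CONSENSUS, "")[[1]], BASES)
  for (i in seq_len(k)) counts[idx[i], i] <- 97
  counts
}

#' The synthetic GATA6-family motif used by the generator
#'
#' A width-8 GATA-site consensus (`AGATAAGA`) with a sharply peaked PFM.
#' This is a synthetic stand-in, not a database matrix.
#'
#' @return a `motif_model`.
#' @export
gata6_synthetic_motif <- function() {
  motif_model(synthetic_gata6_pfm(), id = "GATA6_synthetic")
}

mutate_consensus <- function(consensus, rate) {
  b <- strsplit(consensus, "")[[1]]
  mut <- stats::runif(length(b)) < rate
  if (any(mut)) {
    for (i in which(mut)) b[i] <- sample(setdiff(BASES, b[i]), 1)
  }
  paste(b, collapse = "")
}

# --- main generator -------------------------------------------------------

#' Generate the synthetic multi-omic time course
#'
#' Writes all on-disk inputs the pipeline consumes (FASTA genome with
#' planted motifs, narrowPeak peak sets and bedGraph tracks per assay and
#' timepoint, NB count tables, fragment tables, transgene segment counts,
#' single-cell and bulk staging matrices, viewpoint profiles, contact
#' matrices) plus ground-truth TSVs, and returns the ground truth as R
#' objects. Identical configs produce byte-identical outputs.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if needed).
#' @param components subset of
#'   `c("genome","peaks_tracks","atac_counts","fragments","rna",
#'   "transgene","sc","viewpoints","contacts")`; the CRE layout and truth
#'   tables are always produced.
#' @return invisible list: `config`, `dir`, `truth` (list of data.frames),
#'   `paths`.
#' @export
simulate_multiomics <- function(config, outdir,
                                components = c("genome", "peaks_tracks",
                                               "atac_counts", "fragments",
                                               "rna", "transgene", "sc",
                                               "viewpoints", "contacts")) {
  stopifnot(inherits(config, "sim_config"))
  ok <- dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  cfg <- config
  paths <- list()
  truth <- list()
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  chrom_len <- stats::setNames(rep(cfg$chrom_length_bp, cfg$n_chroms), chroms)

  ## -- CRE layout (always) ------------------------------------------------
  set.seed(subseed(cfg$seed, "layout"))
  n_eo <- cfg$n_pre_cres_early %/% 2
  n_ec <- cfg$n_pre_cres_early - n_eo
  classes <- c(rep("Epi", cfg$n_epi_cres),
               rep("PrE_early_open", n_eo),
               rep("PrE_early_closed", n_ec),
               rep("PrE_late", cfg$n_pre_cres_late),
               rep("background", cfg$n_background_peaks))
  n_cre <- length(classes)
  spacing <- 45000
  margin <- 150000
  slots_per_chrom <- (cfg$chrom_length_bp - 2 * margin) %/% spacing
  if (slots_per_chrom * cfg$n_chroms < n_cre)
    stop("genome too small for the requested number of CREs")
  slot_chrom <- rep(chroms, each = slots_per_chrom)
  slot_pos <- margin + (rep(seq_len(slots_per_chrom), cfg$n_chroms) - 1) * spacing
  pick <- sort(sample(length(slot_chrom), n_cre))
  classes <- sample(classes)               # shuffle classes over slots
  cre <- data.frame(
    cre_id = sprintf("CRE%04d", seq_len(n_cre)),
    chrom = slot_chrom[pick],
    start = slot_pos[pick] + sample(-2000:2000, n_cre, replace = TRUE),
    stringsAsFactors = FALSE)
  cre$end <- cre$start + cfg$peak_width
  cre$class <- classes
  cre$access_factor <- stats::runif(n_cre, 0.8, 1.2)
  cre$gata6_category <- vapply(cre$class, truth_gata6_category, "")
  cre$nanog_cluster <- vapply(cre$class, truth_nanog_cluster, "")

  ## genes: one target gene per non-background CRE + decoys
  is_gene <- cre$class != "background"
  off <- sample(2000:18000, sum(is_gene), replace = TRUE) *
    sample(c(-1, 1), sum(is_gene), replace = TRUE)
  gstrand <- sample(c("+", "-"), sum(is_gene), replace = TRUE)
  mid <- floor((cre$start + cre$end) / 2)
  tss <- pmax(mid[is_gene] + off, 1000)
  glin <- ifelse(cre$class[is_gene] == "Epi", "Epi",
                 ifelse(grepl("^PrE", cre$class[is_gene]), "PrE", "other"))
  genes <- data.frame(
    gene_id = sprintf("G%04d", seq_len(sum(is_gene))),
    chrom = cre$chrom[is_gene],
    start = ifelse(gstrand == "+", tss, tss - 5000),
    end = ifelse(gstrand == "+", tss + 5000, tss + 1),
    strand = gstrand, lineage = glin, stringsAsFactors = FALSE)
  # decoy/housekeeping genes far from every CRE (inside the CRE-free
  # margin), lineage "other". They outnumber the lineage genes so that the
  # transcriptome is majority-stable, as median-of-ratios normalization
  # assumes.
  n_decoy <- sum(is_gene) + 30
  dch <- sample(chroms, n_decoy, replace = TRUE)
  dpos <- sapply(seq_len(n_decoy), function(i)
    margin %/% 2 + sample.int(1000, 1) * 40)
  decoys <- data.frame(gene_id = sprintf("DEC%04d", seq_len(n_decoy)),
                       chrom = dch, start = dpos, end = dpos + 5000,
                       strand = "+", lineage = "other",
                       stringsAsFactors = FALSE)
  genes_all <- rbind(genes, decoys)
  cre$gene_id <- NA_character_
  cre$gene_id[is_gene] <- genes$gene_id
  cre$tss <- NA_real_
  cre$tss[is_gene] <- tss

  ## planted motifs
  set.seed(subseed(cfg$seed, "motifs"))
  k <- nchar(GATA6_CONSENSUS)
  motif_tab <- list()
  dens_of <- function(cls) switch(cls,
    Epi = cfg$motif_density_epi,
    PrE_early_open = , PrE_early_closed = , PrE_late = cfg$motif_density_pre,
    0)
  mut_of <- function(cls) switch(cls,
    Epi = cfg$motif_strength_epi,
    PrE_early_open = , PrE_early_closed = , PrE_late = cfg$motif_strength_pre,
    0)
  cre$n_motifs <- 0L
  for (i in seq_len(n_cre)) {
    d <- dens_of(cre$class[i])
    if (d <= 0) next
    nm <- stats::rpois(1, d)
    if (nm == 0) next
    nm <- min(nm, 8)
    # non-overlapping slots in the central +/-200 bp of the CRE
    mid_i <- floor((cre$start[i] + cre$end[i]) / 2)
    slots <- sample(seq(-200, 200 - k, by = k + 4), nm)
    for (s in slots) {
      seqs <- mutate_consensus(GATA6_CONSENSUS, mut_of(cre$class[i]))
      strand <- sample(c("+", "-"), 1)
      motif_tab[[length(motif_tab) + 1]] <- data.frame(
        cre_id = cre$cre_id[i], chrom = cre$chrom[i], start = mid_i + s,
        end = mid_i + s + k, strand = strand, planted_seq = seqs,
        stringsAsFactors = FALSE)
    }
    cre$n_motifs[i] <- nm
  }
  motifs <- if (length(motif_tab)) do.call(rbind, motif_tab) else
    data.frame(cre_id = character(), chrom = character(), start = integer(),
               end = integer(), strand = character(), planted_seq = character())

  truth$cres <- cre
  truth$genes <- genes_all
  truth$motifs <- motifs

  tps <- cfg$timepoints
  traj <- function(i, assay) planted_trajectory(cre$class[i], assay, tps,
                                                cfg$nanog_relocation,
                                                cre$access_factor[i])

  ## -- genome with planted motif instances --------------------------------
  if ("genome" %in% components) {
    set.seed(subseed(cfg$seed, "genome"))
    seqs <- character(cfg$n_chroms)
    names(seqs) <- chroms
    for (ch in chroms) {
      letters <- sample(BASES, cfg$chrom_length_bp, replace = TRUE)
      mi <- which(motifs$chrom == ch)
      for (j in mi) {
        s <- motifs$planted_seq[j]
        if (motifs$strand[j] == "-") s <- revcomp_chr(s)
        letters[(motifs$start[j] + 1):(motifs$end[j])] <- strsplit(s, "")[[1]]
      }
      seqs[ch] <- paste(letters, collapse = "")
    }
    fa <- Biostrings::DNAStringSet(seqs)
    paths$genome <- file.path(outdir, "genome.fa")
    Biostrings::writeXStringSet(fa, paths$genome, width = 80)
    # ship the synthetic motif next to the genome
    pfm <- synthetic_gata6_pfm()
    paths$pfm <- file.path(outdir, "gata6_synthetic.pfm")
    writeLines(c(">GATA6_synthetic synthetic GATA-family motif",
                 vapply(BASES, function(b) sprintf("%s [ %s ]", b,
                   paste(pfm[b, ], collapse = " ")), "")), paths$pfm)
  }

  ## -- peak sets and signal tracks ----------------------------------------
  if ("peaks_tracks" %in% components) {
    set.seed(subseed(cfg$seed, "peaks"))
    dir.create(file.path(outdir, "peaks"), showWarnings = FALSE)
    dir.create(file.path(outdir, "tracks"), showWarnings = FALSE)
    jitter <- matrix(sample(-30:30, n_cre * length(tps), replace = TRUE),
                     n_cre, length(tps))
    qjit <- matrix(stats::runif(n_cre * length(tps), 0, 0.3),
                   n_cre, length(tps))
    n_bins <- cfg$chrom_length_bp %/% cfg$bin_size
    sigma <- 150
    for (assay in ASSAYS) {
      amp <- t(vapply(seq_len(n_cre), function(i) traj(i, assay),
                      numeric(length(tps))))
      for (ti in seq_along(tps)) {
        tp <- tps[ti]
        called <- which(amp[, ti] >= PEAK_MIN_SIGNAL)
        pk <- peak_table(cre$chrom[called],
                         cre$start[called] + jitter[called, ti],
                         cre$end[called] + jitter[called, ti],
                         name = cre$cre_id[called],
                         score = round(amp[called, ti] * 10),
                         signal = amp[called, ti],
                         qvalue = 10^-(amp[called, ti] / 3 + qjit[called, ti]))
        paths[[sprintf("peaks_%s_%s", assay, tp)]] <-
          file.path(outdir, "peaks", sprintf("%s_%sh.narrowPeak", assay, tp))
        write_peaks(pk, paths[[sprintf("peaks_%s_%s", assay, tp)]],
                    "narrowPeak")
        # replicate-pooled track: gaussian bump at each CRE center
        vals <- lapply(chroms, function(ch) numeric(n_bins))
        names(vals) <- chroms
        for (i in which(amp[, ti] > 0)) {
          c_bin <- mid[i] %/% cfg$bin_size
          span <- 12                      # +/- 600 bp at 50 bp bins
          b <- (c_bin - span):(c_bin + span)
          b <- b[b >= 0 & b < n_bins]
          d <- (b + 0.5) * cfg$bin_size - mid[i]
          vals[[cre$chrom[i]]][b + 1] <- vals[[cre$chrom[i]]][b + 1] +
            amp[i, ti] * exp(-d^2 / (2 * sigma^2))
        }
        tr <- signal_track(vals, cfg$bin_size, "CPM")
        paths[[sprintf("track_%s_%s", assay, tp)]] <-
          file.path(outdir, "tracks", sprintf("%s_%sh.bedGraph", assay, tp))
        write_bedgraph(tr, paths[[sprintf("track_%s_%s", assay, tp)]])
      }
    }
  }

  ## -- ATAC replicate counts over CREs ------------------------------------
  if ("atac_counts" %in% components) {
    set.seed(subseed(cfg$seed, "atac_counts"))
    samples <- as.vector(outer(seq_len(cfg$n_replicates), tps,
                               function(r, t) sprintf("t%g_rep%d", t, r)))
    cond <- rep(sprintf("%gh", tps), each = cfg$n_replicates)
    counts <- matrix(0, n_cre, length(samples),
                     dimnames = list(cre$cre_id, samples))
    for (i in seq_len(n_cre)) {
      mu <- pmax(traj(i, "ATAC"), 0.5) / 30 * cfg$depth
      counts[i, ] <- planted_counts(rep(mu, each = cfg$n_replicates),
                                    cfg$nb_dispersion, 1)
    }
    paths$atac_counts <- file.path(outdir, "atac_counts.tsv")
    write_count_table(counts, paths$atac_counts)
    meta <- data.frame(sample = samples, condition = cond,
                       replicate = rep(seq_len(cfg$n_replicates), length(tps)))
    paths$atac_meta <- file.path(outdir, "atac_meta.tsv")
    data.table::fwrite(meta, paths$atac_meta, sep = "\t")
  }

  ## -- fragment tables (bimodal length mixtures) --------------------------
  if ("fragments" %in% components) {
    set.seed(subseed(cfg$seed, "fragments"))
    frag_file <- function(name, n, p_short) {
      short <- stats::rbinom(n, 1, p_short) == 1
      len <- ifelse(short, pmax(round(stats::rnorm(n, 80, 15)), 20),
                    pmax(round(stats::rnorm(n, 200, 25)), 150))
      ch <- sample(chroms, n, replace = TRUE)
      st <- sample.int(cfg$chrom_length_bp - 400, n)
      p <- file.path(outdir, name)
      data.table::fwrite(data.table::data.table(ch, st, st + len), p,
                         sep = "\t", col.names = FALSE)
      p
    }
    paths$fragments_tf <- frag_file("fragments_tf.tsv", 20000, 0.8)
    paths$fragments_histone <- frag_file("fragments_histone.tsv", 20000, 0.2)
    paths$fragments_atac <- frag_file("fragments_atac.tsv", 20000, 0.6)
  }

  ## -- bulk RNA counts over genes -----------------------------------------
  if ("rna" %in% components) {
    set.seed(subseed(cfg$seed, "rna"))
    ng <- nrow(genes_all)
    base <- cfg$depth * exp(stats::rnorm(ng, 0, 0.4))
    onset <- sample(c(2, 4, 8, 16), ng, replace = TRUE)
    mu_of <- function(g, t) {
      lin <- genes_all$lineage[g]
      # switch normalized to exactly 0 at t = 0 and ~1 at the course end,
      # so lineage genes are fully off (or on) at the start
      r0 <- logistic_rise(0, onset[g], 2)
      s <- (logistic_rise(t, onset[g], 2) - r0) / (1 - r0)
      if (lin == "Epi") base[g] * (0.05 + 0.95 * (1 - s))
      else if (lin == "PrE") base[g] * (0.05 + 0.95 * s)
      else rep(base[g], length(t))
    }
    samples <- as.vector(outer(seq_len(cfg$n_replicates), tps,
                               function(r, t) sprintf("t%g_rep%d", t, r)))
    counts <- matrix(0, ng, length(samples),
                     dimnames = list(genes_all$gene_id, samples))
    onset_truth <- rep(NA_real_, ng)
    for (g in seq_len(ng)) {
      mu <- pmax(mu_of(g, tps), 0.5)
      counts[g, ] <- planted_counts(rep(mu, each = cfg$n_replicates),
                                    cfg$nb_dispersion, 1)
      if (genes_all$lineage[g] != "other") onset_truth[g] <- onset[g]
    }
    paths$rna_counts <- file.path(outdir, "rna_counts.tsv")
    write_count_table(counts, paths$rna_counts)
    meta <- data.frame(sample = samples,
                       condition = rep(sprintf("%gh", tps),
                                       each = cfg$n_replicates),
                       replicate = rep(seq_len(cfg$n_replicates), length(tps)))
    paths$rna_meta <- file.path(outdir, "rna_meta.tsv")
    data.table::fwrite(meta, paths$rna_meta, sep = "\t")
    genes_out <- genes_all
    genes_out$onset <- onset_truth
    truth$genes <- genes_out
    # gene annotation table (1-based GTF-like, see read_genes)
    ann <- genes_all
    ann$start <- ann$start + 1L
    paths$genes <- file.path(outdir, "genes.tsv")
    data.table::fwrite(ann, paths$genes, sep = "\t")
  }

  ## -- transgene segment counts -------------------------------------------
  if ("transgene" %in% components) {
    tg <- simulate_transgene(seed = subseed(cfg$seed, "transgene"),
                             timepoints = tps,
                             n_replicates = cfg$n_replicates,
                             dispersion = 0)
    paths$transgene_counts <- file.path(outdir, "transgene_counts.tsv")
    write_count_table(tg$seg_counts, paths$transgene_counts)
    paths$transgene_meta <- file.path(outdir, "transgene_meta.tsv")
    data.table::fwrite(data.frame(sample = names(tg$library_sizes),
                                  library_size = tg$library_sizes,
                                  reference = names(tg$library_sizes) %in%
                                    tg$reference_samples),
                       paths$transgene_meta, sep = "\t")
    truth$transgene <- tg$truth
  }

  ## -- single-cell clusters + matched bulk --------------------------------
  if ("sc" %in% components) {
    st <- simulate_staging(seed = subseed(cfg$seed, "sc"), timepoints = tps,
                           n_replicates = cfg$n_replicates)
    paths$sc_counts <- file.path(outdir, "sc_counts.tsv")
    write_count_table(st$sc, paths$sc_counts)
    paths$sc_cells <- file.path(outdir, "sc_cells.tsv")
    data.table::fwrite(data.frame(cell = names(st$clusters),
                                  cluster = st$clusters),
                       paths$sc_cells, sep = "\t")
    paths$stage_bulk <- file.path(outdir, "stage_bulk_counts.tsv")
    write_count_table(st$bulk, paths$stage_bulk)
    truth$stage <- st$truth
  }

  ## -- viewpoint profiles --------------------------------------------------
  if ("viewpoints" %in% components) {
    vps <- simulate_viewpoints(seed = subseed(cfg$seed, "viewpoints"),
                               chrom = chroms[1],
                               dispersion = cfg$nb_dispersion)
    dir.create(file.path(outdir, "viewpoints"), showWarnings = FALSE)
    manifest <- list()
    for (vp in vps$profiles) {
      for (j in seq_len(ncol(vp$signal))) {
        nmj <- colnames(vp$signal)[j]
        tr <- signal_track(stats::setNames(list(c(
          numeric(vp$start %/% vp$bin_size), vp$signal[, j])), vp$chrom),
          vp$bin_size, "capC")
        pth <- file.path(outdir, "viewpoints",
                         sprintf("%s_%s.bedGraph", vp$id, nmj))
        write_bedgraph(tr, pth)
      }
      manifest[[vp$id]] <- data.frame(id = vp$id, chrom = vp$chrom,
                                      start = vp$start, end = vp$end,
                                      bin_size = vp$bin_size,
                                      samples = paste(colnames(vp$signal),
                                                      collapse = ","),
                                      conditions = paste(vp$condition,
                                                         collapse = ","))
    }
    paths$viewpoints <- file.path(outdir, "viewpoints", "manifest.tsv")
    data.table::fwrite(do.call(rbind, manifest), paths$viewpoints, sep = "\t")
    truth$viewpoints <- vps$truth
    attr(truth$viewpoints, "profiles") <- vps$profiles
  }

  ## -- contact matrices -----------------------------------------------------
  if ("contacts" %in% components) {
    cm <- simulate_contacts(seed = subseed(cfg$seed, "contacts"),
                            chroms = chroms,
                            n_bins = as.integer(cfg$chrom_length_bp %/% 250000))
    dir.create(file.path(outdir, "contacts"), showWarnings = FALSE)
    for (nm in names(cm$matrices)) {
      paths[[paste0("contacts_", nm)]] <-
        file.path(outdir, "contacts", paste0(nm, ".tsv"))
      write_contact_matrix(cm$matrices[[nm]], paths[[paste0("contacts_", nm)]])
    }
    paths$compartment_reference <- file.path(outdir, "contacts",
                                             "reference.tsv")
    data.table::fwrite(cm$reference, paths$compartment_reference, sep = "\t")
    truth$compartments <- cm$truth
  }

  ## -- ground truth TSVs ----------------------------------------------------
  for (nm in names(truth)) {
    p <- file.path(outdir, sprintf("truth_%s.tsv", nm))
    data.table::fwrite(truth[[nm]], p, sep = "\t")
    paths[[paste0("truth_", nm)]] <- p
  }

  invisible(list(config = cfg, dir = outdir, truth = truth, paths = paths))
}

# --- component generators (callable directly in tests) --------------------

#' Synthetic transgene segment counts
#'
#' Endogenous expression rises as the PrE program engages; the transgene
#' (CDS only) is high right after induction and decays. Counts are NB (or
#' Poisson at `dispersion = 0`) over CDS-last-exon and 3'UTR segments.
#' `truth$ratio` holds the planted per-sample T/E against the mean
#' endogenous level of the reference (final-timepoint) samples.
#'
#' @param seed seed.
#' @param timepoints hours.
#' @param n_replicates samples per timepoint.
#' @param dispersion NB dispersion (0 = Poisson).
#' @param utr_depth mean 3'UTR counts at the reference endogenous level.
#' @param ratio0 planted transgene/endogenous ratio at induction (t = 0).
#' @return list: `seg_counts`, `library_sizes`, `segment_lengths`,
#'   `reference_samples`, `truth`.
#' @export
simulate_transgene <- function(seed = 1, timepoints = c(0, 2, 4, 8, 16, 24, 32, 40, 48),
                               n_replicates = 4, dispersion = 0,
                               utr_depth = 10000, ratio0 = 3) {
  set.seed(seed)
  len <- c(CDS_last_exon = 1200, UTR3 = 800)
  tps <- timepoints
  samples <- as.vector(outer(seq_len(n_replicates), tps,
                             function(r, t) sprintf("t%g_rep%d", t, r)))
  tvec <- rep(tps, each = n_replicates)
  e_rate <- 2 + 8 * logistic_rise(tvec, 8, 4)        # endogenous, rises
  e_ref <- 2 + 8 * logistic_rise(max(tps), 8, 4)     # reference level
  tr_rate <- ratio0 * e_ref * exp(-tvec / 24)        # transgene, decays
  lib <- round(stats::runif(length(samples), 18e6, 22e6))
  names(lib) <- samples
  # scale so the reference-sample UTR mean count is utr_depth
  scl <- utr_depth / (e_ref * (len[["UTR3"]] / 1000) * (mean(lib) / 1e6))
  mu_utr <- e_rate * scl * (len[["UTR3"]] / 1000) * (lib / 1e6)
  mu_cds <- (e_rate + tr_rate) * scl * (len[["CDS_last_exon"]] / 1000) * (lib / 1e6)
  draw <- function(mu) planted_counts(mu, dispersion, 1)
  seg <- rbind(CDS_last_exon = draw(mu_cds), UTR3 = draw(mu_utr))
  colnames(seg) <- samples
  ref <- samples[tvec == max(tps)]
  list(seg_counts = seg, library_sizes = lib, segment_lengths = len,
       reference_samples = ref,
       truth = data.frame(sample = samples, timepoint = tvec,
                          ratio = tr_rate / e_ref, stringsAsFactors = FALSE))
}

#' Synthetic single-cell clusters and matched bulk trajectory
#'
#' Four blastocyst-stage clusters (E3.5_EPI, E3.5_ICM, E3.5_PrE, E4.5_PrE)
#' at fixed positions in a 2-D latent space; cells are Poisson draws around
#' their cluster's profile, bulk samples NB draws around their planted
#' stage's profile. `truth` records the planted bulk-to-cluster map
#' (0-4 h -> E3.5_EPI, 8 h -> E3.5_ICM, 16 h -> E3.5_PrE,
#' 24-48 h -> E4.5_PrE).
#'
#' @param seed seed.
#' @param timepoints,n_replicates bulk design.
#' @param n_genes,cells_per_cluster panel size.
#' @param dispersion bulk NB dispersion.
#' @return list: `sc` (genes x cells), `clusters`, `bulk`
#'   (genes x samples), `truth`.
#' @export
simulate_staging <- function(seed = 1,
                             timepoints = c(0, 2, 4, 8, 16, 24, 32, 40, 48),
                             n_replicates = 2, n_genes = 600,
                             cells_per_cluster = 40, dispersion = 0.05,
                             sc_library = 50000, bulk_library = 2e6) {
  set.seed(seed)
  lat <- rbind(E3.5_EPI = c(0, 1), E3.5_ICM = c(1, 0.5),
               E3.5_PrE = c(2, 0), E4.5_PrE = c(3, -0.5))
  stage_of <- function(t) {
    if (t <= 4) "E3.5_EPI" else if (t <= 8) "E3.5_ICM"
    else if (t <= 16) "E3.5_PrE" else "E4.5_PrE"
  }
  genes <- sprintf("SG%04d", seq_len(n_genes))
  gsd <- 0.35
  G <- matrix(stats::rnorm(n_genes * 2, 0, gsd), n_genes, 2)
  loaded <- stats::runif(n_genes) <= 0.5     # half the panel is stage-neutral
  G[!loaded, ] <- 0
  b <- stats::runif(n_genes, 3, 5.5)
  # balance up- and down-markers: divide loaded rates by the expected
  # marker growth so total marker mass is stage-independent (CPM and
  # median-of-ratios then agree on the stage-neutral genes)
  rate_at <- function(z) {
    r <- exp(b + as.numeric(G %*% z))
    r[loaded] <- r[loaded] / exp(gsd^2 * sum(z^2) / 2)
    r
  }
  # single cells: Poisson draws, library ~ 5000
  cl <- rep(rownames(lat), each = cells_per_cluster)
  cells <- sprintf("cell%04d", seq_along(cl))
  sc <- matrix(0, n_genes, length(cells), dimnames = list(genes, cells))
  for (j in seq_along(cl)) {
    r <- rate_at(lat[cl[j], ])
    sc[, j] <- stats::rpois(n_genes, r / sum(r) * sc_library)
  }
  names(cl) <- cells
  samples <- as.vector(outer(seq_len(n_replicates), timepoints,
                             function(r, t) sprintf("t%g_rep%d", t, r)))
  tvec <- rep(timepoints, each = n_replicates)
  bulk <- matrix(0, n_genes, length(samples), dimnames = list(genes, samples))
  planted <- vapply(tvec, stage_of, "")
  for (j in seq_along(samples)) {
    r <- rate_at(lat[planted[j], ])
    mu <- r / sum(r) * bulk_library
    bulk[, j] <- planted_counts(pmax(mu, 0.1), dispersion, 1)
  }
  list(sc = sc, clusters = cl, bulk = bulk,
       truth = data.frame(sample = samples, timepoint = tvec,
                          cluster = planted, stringsAsFactors = FALSE))
}

#' Synthetic Capture-C viewpoint profiles
#'
#' Three 100 kb viewpoints binned at 1 kb with two conditions x two
#' replicates: one with a planted 3-fold gain over a 6 kb segment in the
#' test condition, one with a 3-fold loss, one null. Baseline signal decays
#' with distance from the viewpoint.
#'
#' @param seed seed.
#' @param chrom chromosome name.
#' @param region_start genomic start of the first profile.
#' @param depth counts at the viewpoint-proximal bins.
#' @param fold planted effect size.
#' @param dispersion NB dispersion of bin counts.
#' @param conditions length-2 condition labels `c(ref, test)`.
#' @return list: `profiles` (list of `viewpoint_profile`), `truth`
#'   (planted segment per viewpoint).
#' @export
simulate_viewpoints <- function(seed = 1, chrom = "chr1",
                                region_start = 1e6, depth = 400, fold = 3,
                                dispersion = 0.05,
                                conditions = c("0h", "48h")) {
  set.seed(seed)
  L <- 100000; bs <- 1000; nb <- L %/% bs
  effects <- c(vp_gain = fold, vp_loss = 1 / fold, vp_null = 1)
  seg_rel <- c(20000, 26000)      # planted segment, relative to region start
  profiles <- list()
  truth <- list()
  for (vi in seq_along(effects)) {
    id <- names(effects)[vi]
    start <- region_start + (vi - 1) * 2e5
    center <- nb / 2
    base <- depth / (1 + abs(seq_len(nb) - 0.5 - center) / 8)
    segbins <- (seg_rel[1] %/% bs + 1):(seg_rel[2] %/% bs)
    samples <- as.vector(outer(1:2, conditions, function(r, cc)
      sprintf("%s_rep%d", cc, r)))
    cond <- rep(conditions, each = 2)
    sig <- matrix(0, nb, length(samples), dimnames = list(NULL, samples))
    for (j in seq_along(samples)) {
      mu <- base
      if (cond[j] == conditions[2]) mu[segbins] <- mu[segbins] * effects[vi]
      sig[, j] <- planted_counts(mu, dispersion, 1)
    }
    profiles[[id]] <- viewpoint_profile(id, chrom, start, start + L, sig,
                                        cond, bs)
    truth[[id]] <- data.frame(id = id, chrom = chrom,
                              seg_start = start + seg_rel[1],
                              seg_end = start + seg_rel[2],
                              fold = unname(effects[vi]),
                              stringsAsFactors = FALSE)
  }
  list(profiles = profiles, truth = do.call(rbind, truth))
}

#' Synthetic two-compartment contact matrices with planted switches
#'
#' Per chromosome and condition, a two-block checkerboard contact matrix
#' (`mean contact = depth * (1 + rho * v_i * v_j)` with `v` = +/-1 per
#' block, Poisson noise, symmetrized). In the test condition two bins of
#' chromosome 1 flip compartment. The reference activity score is the
#' reference-condition compartment sign plus noise (A = positive).
#'
#' @param seed seed.
#' @param chroms chromosome names.
#' @param n_bins bins per chromosome (default 40 = 10 Mb at 250 kb).
#' @param depth mean contact count.
#' @param rho checkerboard contrast in (0,1).
#' @param switch_bins bins of `chroms[1]` flipped in the test condition;
#'   defaults to bins at 12% and 62% of the chromosome (5 and 25 of 40).
#' @param noise if `FALSE`, matrices are the exact expected values.
#' @param conditions length-2 labels `c(ref, test)`.
#' @return list: `matrices` (named `chrN_cond`), `reference` (data.frame),
#'   `truth` (per chrom/bin compartments and switch flags).
#' @export
simulate_contacts <- function(seed = 1, chroms = c("chr1", "chr2"),
                              n_bins = 40, depth = 60, rho = 0.6,
                              switch_bins = NULL, noise = TRUE,
                              conditions = c("0h", "48h")) {
  set.seed(seed)
  if (is.null(switch_bins))
    switch_bins <- unique(pmax(1, round(n_bins * c(0.12, 0.62))))
  mats <- list()
  truth <- list()
  refs <- list()
  for (ch in chroms) {
    v <- rep(c(1, -1), c(ceiling(n_bins / 2), floor(n_bins / 2)))
    v2 <- v
    if (ch == chroms[1]) v2[switch_bins] <- -v2[switch_bins]
    for (cc in conditions) {
      vv <- if (cc == conditions[1]) v else v2
      mu <- depth * (1 + rho * outer(vv, vv))
      m <- if (noise) {
        r <- matrix(stats::rpois(n_bins^2, mu), n_bins)
        round((r + t(r)) / 2)
      } else mu
      dimnames(m) <- list(sprintf("%s_bin%02d", ch, seq_len(n_bins)),
                          sprintf("%s_bin%02d", ch, seq_len(n_bins)))
      mats[[sprintf("%s_%s", ch, cc)]] <- m
    }
    refs[[ch]] <- data.frame(chrom = ch, bin = seq_len(n_bins),
                             score = v + stats::rnorm(n_bins, 0, 0.2))
    truth[[ch]] <- data.frame(chrom = ch, bin = seq_len(n_bins),
                              comp_ref = ifelse(v > 0, "A", "B"),
                              comp_test = ifelse(v2 > 0, "A", "B"),
                              switch = v != v2, stringsAsFactors = FALSE)
  }
  list(matrices = mats, reference = do.call(rbind, refs),
       truth = do.call(rbind, truth))
}
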