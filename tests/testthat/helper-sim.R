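# Shared synthetic fixtures, generated once per test session.

.sim_cache <- new.env(parent = emptyenv())

# default-world simulation (seed 1), restricted to the components a test
# needs; cached by component set
cached_sim <- function(components, seed = 1) {
  key <- paste(c(seed, sort(components)), collapse = "|")
  if (is.null(.sim_cache[[key]])) {
    dir <- file.path(tempdir(), paste0("sim_", abs(sum(utf8ToInt(key)))))
    .sim_cache[[key]] <- simulate_multiomics(sim_config(seed = seed), dir,
                                             components = components)
  }
  .sim_cache[[key]]
}

# small fast world for multi-seed properties: 4 timepoints, 5 Mb chroms
small_sim_config <- function(seed, ...) {
  args <- utils::modifyList(
    list(seed = seed, chrom_length_bp = 5e6, n_epi_cres = 60,
         n_pre_cres_early = 60, n_pre_cres_late = 30,
         n_background_peaks = 40, timepoints = c(0, 2, 4, 8)),
    list(...))
  do.call(sim_config, args)
}

read_sim_peaks <- function(sim, assay, tp) {
  read_peaks(file.path(sim$dir, "peaks",
                       sprintf("%s_%sh.narrowPeak", assay, tp)))
}

read_sim_track <- function(sim, assay, tp) {
  cl <- stats::setNames(rep(sim$config$chrom_length_bp, sim$config$n_chroms),
                        paste0("chr", seq_len(sim$config$n_chroms)))
  read_bedgraph(file.path(sim$dir, "tracks",
                          sprintf("%s_%sh.bedGraph", assay, tp)),
                sim$config$bin_size, cl)
}

# for each planted CRE (first arg), the index of the overlapping called
# peak (second arg), or NA
match_to_truth <- function(truth_cres, called) {
  pk <- peak_table(truth_cres$chrom, truth_cres$start, truth_cres$end)
  ov <- GenomicRanges::findOverlaps(credyn:::peaks_gr(pk),
                                    credyn:::peaks_gr(called))
  idx <- match(seq_len(nrow(pk)), S4Vectors::queryHits(ov))
  S4Vectors::subjectHits(ov)[idx]
}
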