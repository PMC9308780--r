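# End-to-end pipeline and command-line entry point. Every published
# threshold is a defaulted, overridable field of the run configuration.

#' Default run configuration
#'
#' All thresholds default to the published analysis settings: 50 kb
#' assignment / 5 kb proximal, fragment cuts 120/150/180 bp, top
#' 10,000/15,000 peak ranks, motif p/q 1e-3, ATAC padj 1e-4 with |lfc| >= 2,
#' RNA FDR 0.1 with |lfc| >= 2, 5 kb / 500 bp Capture-C windows at
#' padj < 0.01, 250 kb compartment bins with switch correlation < 0.4.
#'
#' @param seed integer seed for the simulation stage.
#' @param ... overrides for any default field.
#' @return named list of run parameters.
#' @export
run_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    max_dist = 50000, prox_dist = 5000,
    frag_tf = 120, frag_histone = 150, frag_nucleosomal = 180,
    top_n_gata6 = 10000, top_n_nanog = 15000,
    motif_p = 1e-3, motif_q = 1e-3,
    atac_lfc = 2, atac_padj = 1e-4,
    rna_lfc = 2, rna_padj = 0.1,
    flank = 500, delta = 0.5,
    capc_win = 5000, capc_step = 500, capc_padj = 0.01,
    compartment_bin = 250000, switch_r = 0.4
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Load viewpoint profiles written by the simulator
#'
#' @param manifest_path path to `viewpoints/manifest.tsv`.
#' @return named list of `viewpoint_profile` objects.
#' @export
read_viewpoints <- function(manifest_path) {
  man <- as.data.frame(data.table::fread(manifest_path, sep = "\t"))
  dirn <- dirname(manifest_path)
  out <- list()
  for (i in seq_len(nrow(man))) {
    samples <- strsplit(man$samples[i], ",")[[1]]
    conds <- strsplit(man$conditions[i], ",")[[1]]
    nb <- (man$end[i] - man$start[i]) %/% man$bin_size[i]
    sig <- matrix(0, nb, length(samples), dimnames = list(NULL, samples))
    for (j in seq_along(samples)) {
      tr <- read_bedgraph(file.path(dirn, sprintf("%s_%s.bedGraph",
                                                  man$id[i], samples[j])),
                          man$bin_size[i],
                          stats::setNames(man$end[i], man$chrom[i]))
      b0 <- man$start[i] %/% man$bin_size[i]
      sig[, j] <- tr$values[[man$chrom[i]]][(b0 + 1):(b0 + nb)]
    }
    out[[man$id[i]]] <- viewpoint_profile(man$id[i], man$chrom[i],
                                          man$start[i], man$end[i], sig,
                                          conds, man$bin_size[i])
  }
  out
}

#' Run the full analysis pipeline on a synthetic dataset
#'
#' Simulates a dataset (unless `sim_dir` points at an existing simulation),
#' then runs every stage — CRE annotation, ATAC differential
#' classification, GATA6/NANOG taxonomies, NANOG redistribution scoring,
#' motif density/strength, transgene T/E, bulk-on-single-cell staging,
#' Capture-C window differentials and compartment switch calling — writing
#' per-stage TSVs, a machine-readable `summary.json` and `run_log.txt`
#' into `outdir`.
#'
#' @param config a [run_config()].
#' @param outdir output directory.
#' @param sim a [sim_config()]; defaults to `sim_config(seed = config$seed)`.
#' @return invisible list with all stage results and the summary.
#' @export
run_full_pipeline <- function(config = run_config(), outdir,
                              sim = sim_config(seed = config$seed)) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log <- file.path(outdir, "run_log.txt")
  logln <- function(...) cat(sprintf(...), "\n", file = log, append = TRUE)
  cat("", file = log)
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  cfg_path <- file.path(outdir, "run_config.json")
  writeLines(cfg_json, cfg_path)
  logln("package credyn %s", as.character(utils::packageVersion("credyn")))
  logln("R %s", R.version.string)
  logln("seed %d", config$seed)
  logln("config md5 %s", unname(tools::md5sum(cfg_path)))

  stage <- function(name, expr) {
    logln("stage %s: start", name)
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    logln("stage %s: done", name)
    res
  }
  summary <- list(seed = config$seed)

  simres <- stage("simulate",
                  simulate_multiomics(sim, file.path(outdir, "sim")))
  sdir <- simres$dir
  truth <- simres$truth

  ## annotation of ATAC 48 h peaks
  ann <- stage("annotate", {
    peaks <- read_peaks(file.path(sdir, "peaks", "ATAC_48h.narrowPeak"))
    genes <- read_genes(file.path(sdir, "genes.tsv"))
    out <- annotate_cres(peaks, genes,
                         epi_genes = genes$gene_id[genes$lineage == "Epi"],
                         pre_genes = genes$gene_id[genes$lineage == "PrE"],
                         max_dist = config$max_dist,
                         prox_dist = config$prox_dist)
    data.table::fwrite(out, file.path(outdir, "annotation.tsv"), sep = "\t")
    out
  })
  summary$annotation <- as.list(table(ann$lineage))

  ## ATAC differential 48 h vs 0 h
  atac <- stage("atac_diff", {
    counts <- read_count_table(file.path(sdir, "atac_counts.tsv"))
    meta <- as.data.frame(data.table::fread(file.path(sdir, "atac_meta.tsv")))
    res <- nb_wald_test(counts, meta$condition[match(colnames(counts),
                                                     meta$sample)],
                        contrast = c("48h", "0h"))
    res$class <- classify_features(res, config$atac_lfc, config$atac_padj)
    data.table::fwrite(res, file.path(outdir, "atac_diff.tsv"), sep = "\t")
    res
  })
  summary$atac_classes <- as.list(table(atac$class))

  ## peak taxonomies
  tax <- stage("taxonomy", {
    rp <- function(assay, tp) read_peaks(file.path(
      sdir, "peaks", sprintf("%s_%sh.narrowPeak", assay, tp)))
    atac0 <- rp("ATAC", 0)
    g <- classify_gata6_peaks(list("2" = rp("GATA6", 2), "4" = rp("GATA6", 4),
                                   "8" = rp("GATA6", 8),
                                   "48" = rp("GATA6", 48)),
                              atac0, n = config$top_n_gata6)
    nano <- classify_nanog_2h(top_n_by_q(rp("NANOG", 0), config$top_n_nanog),
                              top_n_by_q(rp("NANOG", 2), config$top_n_nanog),
                              atac0)
    data.table::fwrite(g, file.path(outdir, "gata6_taxonomy.tsv"), sep = "\t")
    data.table::fwrite(nano, file.path(outdir, "nanog_clusters.tsv"), sep = "\t")
    list(gata6 = g, nanog = nano)
  })
  summary$gata6_taxonomy <- as.list(table(tax$gata6$category))
  summary$nanog_clusters <- as.list(table(tax$nanog$cluster))

  ## NANOG redistribution 0 -> 2 h
  redis <- stage("redistribution", {
    tracks <- list(
      "NANOG.0" = read_bedgraph(file.path(sdir, "tracks", "NANOG_0h.bedGraph"),
                                sim$bin_size,
                                stats::setNames(rep(sim$chrom_length_bp,
                                                    sim$n_chroms),
                                                paste0("chr", seq_len(sim$n_chroms)))),
      "NANOG.2" = read_bedgraph(file.path(sdir, "tracks", "NANOG_2h.bedGraph"),
                                sim$bin_size,
                                stats::setNames(rep(sim$chrom_length_bp,
                                                    sim$n_chroms),
                                                paste0("chr", seq_len(sim$n_chroms)))))
    m <- signal_matrix(tax$nanog, tracks, flank = config$flank)
    redistribution_score(m, "cluster", "NANOG", "0", "2", config$delta)
  })
  summary$redistribution <- list(R = as.list(redis$R),
                                 detected = redis$detected)

  ## motif density & strength, early (Epi) vs PrE classes
  mot <- stage("motif", {
    genome <- Biostrings::readDNAStringSet(file.path(sdir, "genome.fa"))
    motif <- motif_model(read_pwm_jaspar(file.path(sdir, "gata6_synthetic.pfm")))
    cres <- truth$cres
    sel <- cres$class %in% c("Epi", "PrE_early_open", "PrE_early_closed")
    pk <- peak_table(cres$chrom[sel], cres$start[sel], cres$end[sel],
                     name = cres$cre_id[sel])
    hits <- scan_peaks_motifs(genome, pk, motif, p_max = config$motif_p)
    dens <- motif_density(pk, hits)
    cls <- ifelse(cres$class[sel] == "Epi", "Epi", "PrE")
    strength <- motif_strength(hits, cls[hits$peak_index])
    data.table::fwrite(hits, file.path(outdir, "motif_hits.tsv"), sep = "\t")
    list(density_by_class = tapply(dens, cls, mean), strength = strength)
  })
  summary$motif <- list(density = as.list(mot$density_by_class),
                        strength_medians = as.list(mot$strength$medians),
                        strength_p = mot$strength$p)

  ## transgene T/E
  tg <- stage("transgene", {
    seg <- read_count_table(file.path(sdir, "transgene_counts.tsv"))
    meta <- as.data.frame(data.table::fread(file.path(sdir, "transgene_meta.tsv")))
    transgene_ratio(seg, stats::setNames(meta$library_size, meta$sample),
                    c(CDS_last_exon = 1200, UTR3 = 800),
                    meta$sample[meta$reference])
  })
  summary$transgene <- list(mean_ratio = mean(tg$ratio), E = tg$E)

  ## staging bulk on single-cell clusters
  stg <- stage("staging", {
    bulk <- read_count_table(file.path(sdir, "stage_bulk_counts.tsv"))
    sc <- read_count_table(file.path(sdir, "sc_counts.tsv"))
    cells <- as.data.frame(data.table::fread(file.path(sdir, "sc_cells.tsv")))
    st <- stage_bulk_on_sc(bulk, sc, stats::setNames(cells$cluster, cells$cell))
    data.table::fwrite(st$mapping, file.path(outdir, "staging.tsv"), sep = "\t")
    st
  })
  summary$staging <- stats::setNames(as.list(stg$mapping$cluster),
                                     stg$mapping$sample)

  ## Capture-C windows
  capc <- stage("capture_c", {
    vps <- read_viewpoints(file.path(sdir, "viewpoints", "manifest.tsv"))
    lapply(vps, function(vp)
      window_differential(vp, contrast = c("48h", "0h"), win = config$capc_win,
                          step = config$capc_step,
                          padj_max = config$capc_padj))
  })
  summary$capture_c <- lapply(capc, function(x) nrow(x$significant))

  ## compartments
  comp <- stage("compartments", {
    ref <- as.data.frame(data.table::fread(file.path(sdir, "contacts",
                                                     "reference.tsv")))
    chroms <- unique(ref$chrom)
    out <- list()
    for (ch in chroms) {
      a <- compartment_eigen(read_contact_matrix(
        file.path(sdir, "contacts", sprintf("%s_0h.tsv", ch))),
        ref$score[ref$chrom == ch])
      b <- compartment_eigen(read_contact_matrix(
        file.path(sdir, "contacts", sprintf("%s_48h.tsv", ch))),
        ref$score[ref$chrom == ch])
      out[[ch]] <- compartment_switches(a, b, r_max = config$switch_r)
    }
    sw <- do.call(rbind, Map(function(ch, d) cbind(chrom = ch, d),
                             names(out), out))
    data.table::fwrite(sw, file.path(outdir, "compartment_switches.tsv"),
                       sep = "\t")
    out
  })
  summary$compartments <- list(
    n_switch = sum(vapply(comp, function(d) sum(d$switch, na.rm = TRUE), 0)),
    n_bins = sum(vapply(comp, nrow, 0)))

  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logln("pipeline complete")
  invisible(list(summary = summary, annotation = ann, atac = atac,
                 taxonomy = tax, redistribution = redis, motif = mot,
                 transgene = tg, staging = stg, capture_c = capc,
                 compartments = comp))
}

#' Command-line interface
#'
#' Entry point behind the `cre` script (`inst/cli/cre`). Subcommands:
#' `simulate`, `diff`, `annotate`, `validate`, `run`, `version`.
#' Arguments are `--key value` pairs.
#'
#' @param argv character vector of command-line arguments.
#' @return invisibly, the subcommand's result.
#' @export
cre_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) == 0 || argv[1] %in% c("-h", "--help")) {
    cat("usage: cre <simulate|diff|annotate|validate|run|version> [--key value ...]\n")
    return(invisible(NULL))
  }
  cmd <- argv[1]
  kv <- list()
  rest <- argv[-1]
  i <- 1
  while (i <= length(rest)) {
    if (startsWith(rest[i], "--")) {
      kv[[substring(rest[i], 3)]] <- rest[i + 1]
      i <- i + 2
    } else i <- i + 1
  }
  need <- function(k) {
    if (is.null(kv[[k]])) stop("missing required argument --", k)
    kv[[k]]
  }
  num <- function(k, d) if (is.null(kv[[k]])) d else as.numeric(kv[[k]])
  res <- switch(cmd,
    version = {
      cat("credyn", as.character(utils::packageVersion("credyn")), "\n")
    },
    simulate = {
      cfg <- sim_config(seed = as.integer(num("seed", 1)))
      simulate_multiomics(cfg, need("out"))
    },
    validate = validate_file(need("path"),
                             if (is.null(kv$format)) "auto" else kv$format),
    diff = {
      counts <- read_count_table(need("counts"))
      meta <- as.data.frame(data.table::fread(need("meta")))
      contrast <- strsplit(need("contrast"), ",")[[1]]
      res <- nb_wald_test(counts,
                          meta$condition[match(colnames(counts), meta$sample)],
                          contrast)
      res$class <- classify_features(res, num("lfc", 2), num("padj", 1e-4))
      data.table::fwrite(res, need("out"), sep = "\t")
      res
    },
    annotate = {
      peaks <- read_peaks(need("peaks"))
      genes <- read_genes(need("genes"))
      out <- annotate_cres(peaks, genes,
                           epi_genes = genes$gene_id[genes$lineage == "Epi"],
                           pre_genes = genes$gene_id[genes$lineage == "PrE"],
                           max_dist = num("max-dist", 50000),
                           prox_dist = num("prox-dist", 5000))
      data.table::fwrite(out, need("out"), sep = "\t")
      out
    },
    run = {
      cfg <- run_config(seed = as.integer(num("seed", 1)))
      run_full_pipeline(cfg, need("out"))
    },
    stop("unknown subcommand: ", cmd)
  )
  invisible(res)
}
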