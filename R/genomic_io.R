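# Readers/writers for the plain-text genomic formats the pipeline consumes,
# plus the interval / binned-signal primitives every other module uses.
# All coordinates are 0-based half-open (BED convention); GTF-like gene
# tables are converted on read.

#' Construct a peak table
#'
#' Peaks are plain data.frames with columns `chrom`, `start`, `end` (0-based
#' half-open), `name`, `score`, `strand`, `signal`, `qvalue` and optional
#' label columns. `qvalue` is on the raw \[0,1\] scale (not -log10).
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open.
#' @param name,score,strand,signal,qvalue optional per-peak annotation.
#' @return a `data.frame` of peaks.
#' @export
peak_table <- function(chrom, start, end, name = NULL, score = NULL,
                       strand = NULL, signal = NULL, qvalue = NULL) {
  n <- length(start)
  stopifnot(length(end) == n)
  if (length(chrom) != n) chrom <- rep(as.character(chrom), length.out = n)
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start < 0)) stop("peak coordinates must be non-negative")
  if (any(end <= start)) stop("peak intervals require start < end")
  if (!is.null(qvalue)) {
    bad <- !is.na(qvalue) & (qvalue < 0 | qvalue > 1)
    if (any(bad)) stop("qvalue must lie in [0, 1]")
  }
  data.frame(
    chrom = as.character(chrom), start = start, end = end,
    name = if (is.null(name)) rep(".", n) else as.character(name),
    score = if (is.null(score)) rep(0, n) else as.numeric(score),
    strand = if (is.null(strand)) rep(".", n) else as.character(strand),
    signal = if (is.null(signal)) rep(NA_real_, n) else as.numeric(signal),
    qvalue = if (is.null(qvalue)) rep(NA_real_, n) else as.numeric(qvalue),
    stringsAsFactors = FALSE
  )
}

#' Read peak calls from BED or narrowPeak
#'
#' narrowPeak column 9 carries -log10(q); it is converted to a raw q-value
#' (`10^-col9`); a sentinel of -1 becomes `NA`.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"bed"` or `"narrowPeak"`.
#' @return a peak `data.frame` (see [peak_table()]).
#' @export
read_peaks <- function(path, format = c("auto", "bed", "narrowPeak")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    format <- if (grepl("narrowPeak$", path, ignore.case = TRUE)) "narrowPeak" else "bed"
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(peak_table(character(), integer(), integer()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  need <- if (format == "narrowPeak") 10L else 3L
  bad <- which(nf < need)
  if (length(bad))
    stop(sprintf("malformed %s line %d in %s: expected >= %d fields, got %d",
                 format, bad[1], path, need, nf[bad[1]]))
  get <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else NA_character_, "")
  chrom <- get(1)
  start <- suppressWarnings(as.numeric(get(2)))
  end <- suppressWarnings(as.numeric(get(3)))
  if (anyNA(start) || anyNA(end)) {
    bad <- which(is.na(start) | is.na(end))[1]
    stop(sprintf("malformed %s line %d in %s: non-numeric coordinates", format, bad, path))
  }
  name <- if (all(nf >= 4)) get(4) else NULL
  score <- if (all(nf >= 5)) suppressWarnings(as.numeric(get(5))) else NULL
  strand <- if (all(nf >= 6)) get(6) else NULL
  signal <- qvalue <- NULL
  if (format == "narrowPeak") {
    signal <- suppressWarnings(as.numeric(get(7)))
    mlogq <- suppressWarnings(as.numeric(get(9)))
    qvalue <- ifelse(is.na(mlogq) | mlogq < 0, NA_real_, 10^(-mlogq))
  }
  peak_table(chrom, start, end, name, score, strand, signal, qvalue)
}

#' Write peaks to BED or narrowPeak
#'
#' Round-trips coordinates and scores exactly through [read_peaks()].
#'
#' @param peaks a peak `data.frame`.
#' @param path output path.
#' @param format `"bed"` (6 columns) or `"narrowPeak"` (10 columns).
#' @export
write_peaks <- function(peaks, path, format = c("bed", "narrowPeak")) {
  format <- match.arg(format)
  num <- function(x) ifelse(is.na(x), "-1", format(x, digits = 17, trim = TRUE, scientific = FALSE))
  base <- paste(peaks$chrom, format(peaks$start, scientific = FALSE, trim = TRUE),
                format(peaks$end, scientific = FALSE, trim = TRUE),
                peaks$name, num(peaks$score), peaks$strand, sep = "\t")
  if (format == "narrowPeak") {
    mlogq <- ifelse(is.na(peaks$qvalue), -1, -log10(pmax(peaks$qvalue, 1e-300)))
    base <- paste(base, num(peaks$signal), "-1", num(mlogq), "-1", sep = "\t")
  }
  writeLines(base, path)
  invisible(path)
}

# internal: peaks as GRanges (1-based closed, as IRanges expects)
peaks_gr <- function(peaks) {
  GenomicRanges::GRanges(peaks$chrom,
                         IRanges::IRanges(start = peaks$start + 1L, end = peaks$end))
}

#' Interval overlap under half-open semantics
#'
#' `overlaps()` tests two single intervals; `overlap_any()` is the vectorized
#' form reporting, per row of `query`, whether any `subject` row shares at
#' least 1 bp on the same chromosome.
#'
#' @param a,b single-row peak data.frames (or lists with `chrom`, `start`,
#'   `end`).
#' @return logical.
#' @export
overlaps <- function(a, b) {
  a$chrom == b$chrom && a$start < b$end && b$start < a$end
}

#' @rdname overlaps
#' @param query,subject peak data.frames.
#' @export
overlap_any <- function(query, subject) {
  if (nrow(subject) == 0) return(rep(FALSE, nrow(query)))
  IRanges::overlapsAny(peaks_gr(query), peaks_gr(subject))
}

#' Construct a binned signal track
#'
#' A signal track stores fixed-bin coverage per chromosome. Bin `i` (1-based)
#' covers bp `[(i-1)*bin_size, i*bin_size)`.
#'
#' @param values named list of non-negative numeric vectors, one per
#'   chromosome.
#' @param bin_size bin width in bp.
#' @param normalization_tag free-text provenance tag (e.g. "CPM").
#' @return an object of class `signal_track`.
#' @export
signal_track <- function(values, bin_size, normalization_tag = "raw") {
  stopifnot(is.list(values), !is.null(names(values)), bin_size >= 1)
  for (v in values) {
    if (any(!is.finite(v)) || any(v < 0))
      stop("signal track values must be finite and >= 0")
  }
  structure(list(values = values, bin_size = as.integer(bin_size),
                 normalization_tag = normalization_tag),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("signal_track: %d chromosome(s), bin %d bp, norm '%s'\n",
              length(x$values), x$bin_size, x$normalization_tag))
  for (ch in names(x$values))
    cat(sprintf("  %s: %d bins (%.0f bp)\n", ch, length(x$values[[ch]]),
                length(x$values[[ch]]) * as.numeric(x$bin_size)))
  invisible(x)
}

#' Read a bedGraph file into a signal track
#'
#' Records must be aligned to a regular `bin_size` grid; runs spanning
#' several bins (as written by [write_bedgraph()]) are expanded. Gaps are 0.
#'
#' @param path bedGraph path (4 columns, no track line).
#' @param bin_size grid width in bp.
#' @param chrom_lengths optional named vector of chromosome lengths in bp;
#'   defaults to the last covered position per chromosome.
#' @inheritParams signal_track
#' @return a `signal_track`.
#' @export
read_bedgraph <- function(path, bin_size, chrom_lengths = NULL,
                          normalization_tag = "raw") {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "value"))
  if (nrow(dt) && any(dt$start %% bin_size != 0 | dt$end %% bin_size != 0))
    stop("bedGraph records not aligned to a ", bin_size, " bp grid")
  chroms <- unique(c(dt$chrom, names(chrom_lengths)))
  values <- list()
  for (ch in chroms) {
    sub <- dt[dt$chrom == ch, ]
    len <- if (!is.null(chrom_lengths) && ch %in% names(chrom_lengths))
      chrom_lengths[[ch]] else if (nrow(sub)) max(sub$end) else bin_size
    v <- numeric(ceiling(len / bin_size))
    if (nrow(sub)) {
      b0 <- sub$start %/% bin_size
      b1 <- sub$end %/% bin_size
      for (i in seq_len(nrow(sub))) v[(b0[i] + 1L):b1[i]] <- sub$value[i]
    }
    values[[ch]] <- v
  }
  signal_track(values, bin_size, normalization_tag)
}

#' Write a signal track as bedGraph
#'
#' Adjacent equal-valued bins are merged into runs; zero runs are omitted.
#'
#' @param track a `signal_track`.
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  bs <- as.numeric(track$bin_size)
  for (ch in names(track$values)) {
    v <- track$values[[ch]]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (any(keep)) {
      lines <- sprintf("%s\t%.0f\t%.0f\t%s", ch, starts[keep] * bs,
                       ends[keep] * bs,
                       format(r$values[keep], digits = 10, trim = TRUE,
                              scientific = FALSE))
      writeLines(lines, con)
    }
  }
  invisible(path)
}

#' Windowed statistic over a signal track
#'
#' Computes a statistic over the bins overlapping `[start, end)`, weighting
#' partial bins by their overlap in bp. `"mean"` is the per-bp average;
#' `"sum"` is the integral in value x bp.
#'
#' @param track a `signal_track`.
#' @param chrom chromosome name.
#' @param start,end interval, 0-based half-open bp.
#' @param stat `"mean"` or `"sum"`.
#' @return a single number.
#' @export
track_stat <- function(track, chrom, start, end, stat = c("mean", "sum")) {
  stat <- match.arg(stat)
  v <- track$values[[chrom]]
  if (is.null(v)) stop("chromosome not in track: ", chrom)
  bs <- as.numeric(track$bin_size)
  if (start < 0 || end > length(v) * bs || start >= end)
    stop(sprintf("interval %s:%.0f-%.0f outside track extent", chrom, start, end))
  b0 <- floor(start / bs) + 1
  b1 <- ceiling(end / bs)
  idx <- b0:b1
  bin_lo <- (idx - 1) * bs
  bin_hi <- idx * bs
  w <- pmin(bin_hi, end) - pmax(bin_lo, start)
  if (stat == "sum") sum(v[idx] * w) else sum(v[idx] * w) / sum(w)
}

#' Read a 3-column fragment table
#'
#' @param path TSV with columns chrom, start, end (0-based half-open).
#' @return data.frame with an added `length` column (`end - start`).
#' @export
read_fragments <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end"))
  df <- as.data.frame(dt)
  if (nrow(df) && any(df$end <= df$start)) stop("fragments require end > start")
  df$length <- df$end - df$start
  df
}

#' Fragment-size selection
#'
#' Reproduces the assay-specific fragment-length cuts used throughout the
#' analysis: transcription-factor CUT&RUN keeps subnucleosomal fragments
#' (< 120 bp), histone-modification CUT&RUN keeps fragments > 150 bp, and
#' nucleosomal ATAC signal keeps fragments > 180 bp. All cuts are strict.
#'
#' @param frags a fragment data.frame (see [read_fragments()]).
#' @param mode one of `"tf"`, `"histone"`, `"nucleosomal_atac"`.
#' @return the filtered fragment data.frame.
#' @export
filter_fragments <- function(frags, mode = c("tf", "histone", "nucleosomal_atac")) {
  mode <- match.arg(mode)
  len <- frags$end - frags$start
  keep <- switch(mode,
                 tf = len < 120,
                 histone = len > 150,
                 nucleosomal_atac = len > 180)
  frags[keep, , drop = FALSE]
}

#' Read a gene/TSS annotation table
#'
#' The table is GTF-like with 1-based inclusive coordinates, converted on
#' read to 0-based half-open. Expected columns: `gene_id`, `chrom`, `start`,
#' `end`, `strand`, `lineage` (`Epi`, `PrE` or `other`). The TSS is derived
#' from the strand: first transcribed bp (0-based).
#'
#' @param path TSV path with a header row.
#' @return data.frame with columns gene_id, chrom, start, end, strand,
#'   lineage, tss.
#' @export
read_genes <- function(path) {
  df <- as.data.frame(data.table::fread(path, header = TRUE, sep = "\t"))
  need <- c("gene_id", "chrom", "start", "end", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("gene table missing columns: ", paste(miss, collapse = ", "))
  if (!"lineage" %in% names(df)) df$lineage <- "other"
  df$start <- df$start - 1L  # to 0-based half-open
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1L)
  df
}

#' Read / write a counts table (features x samples)
#'
#' TSV with feature ids in the first column and sample ids as the header.
#'
#' @param path TSV path.
#' @return integer matrix with feature rownames and sample colnames.
#' @export
read_count_table <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  m <- as.matrix(dt[, -1, drop = FALSE])
  rownames(m) <- as.character(dt[[1]])
  storage.mode(m) <- "double"
  if (any(m < 0)) stop("counts must be non-negative")
  m
}

#' @rdname read_count_table
#' @param counts matrix with rownames/colnames.
#' @export
write_count_table <- function(counts, path) {
  dt <- data.table::data.table(feature = rownames(counts))
  for (j in colnames(counts)) dt[[j]] <- counts[, j]
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read a JASPAR-style position frequency matrix
#'
#' Format: a `>` header line (id and optional name), then four rows
#' `A [ ... ]`, `C [ ... ]`, `G [ ... ]`, `T [ ... ]`.
#'
#' @param path PFM text path.
#' @return list with `id` and `counts` (4 x k matrix, rows A,C,G,T).
#' @export
read_pwm_jaspar <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (!startsWith(lines[1], ">")) stop("JASPAR PFM must start with a '>' header")
  id <- sub("^>\\s*", "", lines[1])
  rows <- lines[2:5]
  parse_row <- function(l) {
    l <- gsub("[][]", " ", sub("^[ACGT]", "", l))
    as.numeric(strsplit(trimws(l), "[[:space:]]+")[[1]])
  }
  bases <- substr(rows, 1, 1)
  if (!identical(sort(bases), c("A", "C", "G", "T")))
    stop("PFM must contain one row each for A, C, G, T")
  vals <- lapply(rows, parse_row)
  k <- unique(lengths(vals))
  if (length(k) != 1) stop("PFM rows have unequal lengths")
  counts <- do.call(rbind, vals)
  rownames(counts) <- bases
  counts <- counts[c("A", "C", "G", "T"), , drop = FALSE]
  list(id = id, counts = counts)
}

#' Validate a pipeline input file
#'
#' Light-weight format check used by the `cre io validate` CLI entry.
#'
#' @param path file path.
#' @param format one of `"bed"`, `"narrowPeak"`, `"bedGraph"`, `"fasta"`,
#'   `"counts"`, `"pfm"`; `"auto"` guesses from the extension.
#' @return invisibly `TRUE`; errors describe the first problem found.
#' @export
validate_file <- function(path, format = "auto") {
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
                     bed = "bed", narrowpeak = "narrowPeak",
                     bedgraph = "bedGraph", bg = "bedGraph",
                     fa = "fasta", fasta = "fasta",
                     tsv = "counts", pfm = "pfm",
                     stop("cannot guess format for ", path))
  }
  switch(format,
         bed = read_peaks(path, "bed"),
         narrowPeak = read_peaks(path, "narrowPeak"),
         bedGraph = data.table::fread(path, header = FALSE, sep = "\t"),
         fasta = Biostrings::readDNAStringSet(path),
         counts = read_count_table(path),
         pfm = read_pwm_jaspar(path),
         stop("unknown format: ", format))
  invisible(TRUE)
}
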