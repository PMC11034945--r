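## File formats: sample sheet CSV, BED3/6, ENCODE narrowPeak, BEDPE-style
## loop tables, TSV count matrices, MEME-like PWM text, run manifests.
## All genomic coordinates are 0-based half-open internally and on disk.

SHEET_COLS <- c("sample_id", "subject_id", "pair_id", "group", "cohort",
                "fraction", "assay", "replicate", "sex", "age", "pmd")

#' Read and validate a sample sheet
#'
#' The sheet is a CSV with one row per sequencing library and columns
#' `sample_id, subject_id, pair_id, group, cohort, fraction, assay,
#' replicate, sex, age, pmd`. Validation enforces the matched-pair design:
#' every pair has exactly one case and one control subject, cohort
#' (AF = antipsychotic-free, AT = antipsychotic-treated) is constant within
#' a pair, and `(subject_id, fraction, assay, replicate)` is unique.
#'
#' @param path CSV file path
#' @return a data.frame of validated sample records
#' @export
read_sample_sheet <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(SHEET_COLS, names(df))
  if (length(missing))
    stop_fmt("sample sheet missing column(s): %s", paste(missing, collapse = ", "))
  df <- df[, SHEET_COLS]
  validate_sample_sheet(df)
  df
}

validate_sample_sheet <- function(df) {
  chk_enum <- function(col, allowed) {
    bad <- setdiff(unique(df[[col]]), allowed)
    if (length(bad))
      stop_fmt("unknown %s value(s): %s", col, paste(bad, collapse = ", "))
  }
  chk_enum("group", c("case", "control"))
  chk_enum("cohort", c("AF", "AT"))
  chk_enum("fraction", c("NeuNpos", "NeuNneg"))
  chk_enum("assay", c("H3K27ac", "H3K4me3", "RNA"))
  chk_enum("sex", c("M", "F"))
  if (any(!is.finite(df$age) | df$age < 0)) stop_fmt("age must be a real >= 0")
  if (any(!is.finite(df$pmd) | df$pmd < 0)) stop_fmt("pmd must be a real >= 0")
  if (any(df$replicate < 1)) stop_fmt("replicate must be >= 1")
  for (p in unique(df$pair_id)) {
    sub <- unique(df[df$pair_id == p, c("subject_id", "group", "cohort")])
    if (length(unique(sub$cohort)) != 1)
      stop_fmt("pair %s mixes cohorts", p)
    n_case <- length(unique(sub$subject_id[sub$group == "case"]))
    n_ctrl <- length(unique(sub$subject_id[sub$group == "control"]))
    if (n_case != 1 || n_ctrl != 1)
      stop_fmt("pair %s must have exactly one case and one control subject (got %d/%d)",
               p, n_case, n_ctrl)
  }
  key <- do.call(paste, c(df[c("subject_id", "fraction", "assay", "replicate")], sep = "\r"))
  if (anyDuplicated(key))
    stop_fmt("duplicate (subject_id, fraction, assay, replicate) combination")
  invisible(df)
}

#' Write a sample sheet CSV
#' @param df sample sheet data.frame
#' @param path output file
#' @return `path`, invisibly
#' @export
write_sample_sheet <- function(df, path) {
  write.csv(df[, SHEET_COLS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read genomic intervals from BED, narrowPeak or a BEDPE-style loop table
#'
#' All formats are whitespace-delimited text with 0-based half-open
#' coordinates. For narrowPeak (ENCODE 10-column), column 10 is the summit
#' offset from `start`; an offset of -1 (summit not determined) is mapped
#' to the interval midpoint. The returned `summit` column is an absolute
#' genomic position.
#'
#' @param path input file
#' @param format one of `"bed"`, `"narrowPeak"`, `"bedpe_tsv"`
#' @return a data.frame of intervals; narrowPeak adds `name, score, strand,
#'   signal, p, q, summit`; bedpe_tsv returns paired anchor coordinates
#' @export
read_intervals <- function(path, format = c("bed", "narrowPeak", "bedpe_tsv")) {
  format <- match.arg(format)
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   sep = "", comment.char = "#")
  if (nrow(df) == 0) return(empty_intervals(format))
  chk_coords <- function(s, e, what = "interval") {
    if (!is.numeric(s) || !is.numeric(e) || any(s != floor(s)) || any(e != floor(e)))
      stop_fmt("non-integer coordinate in %s", path)
    if (any(s >= e)) stop_fmt("start >= end in %s (%s)", path, what)
  }
  if (format == "bed") {
    chk_coords(df[[2]], df[[3]])
    out <- data.frame(chrom = as.character(df[[1]]), start = as.integer(df[[2]]),
                      end = as.integer(df[[3]]), stringsAsFactors = FALSE)
    if (ncol(df) >= 4) out$name <- as.character(df[[4]])
    if (ncol(df) >= 5) out$score <- as.numeric(df[[5]])
    if (ncol(df) >= 6) out$strand <- as.character(df[[6]])
    out
  } else if (format == "narrowPeak") {
    if (ncol(df) < 10) stop_fmt("narrowPeak requires 10 columns, got %d", ncol(df))
    chk_coords(df[[2]], df[[3]])
    summit_off <- as.integer(df[[10]])
    start <- as.integer(df[[2]]); end <- as.integer(df[[3]])
    mid <- start + (end - start) %/% 2L
    summit <- ifelse(summit_off < 0, mid, start + summit_off)
    data.frame(chrom = as.character(df[[1]]), start = start, end = end,
               name = as.character(df[[4]]), score = as.numeric(df[[5]]),
               strand = as.character(df[[6]]), signal = as.numeric(df[[7]]),
               p = as.numeric(df[[8]]), q = as.numeric(df[[9]]),
               summit = as.integer(summit), stringsAsFactors = FALSE)
  } else {
    if (ncol(df) < 6) stop_fmt("bedpe_tsv requires >= 6 columns")
    chk_coords(df[[2]], df[[3]], "anchor1")
    chk_coords(df[[5]], df[[6]], "anchor2")
    data.frame(chrom1 = as.character(df[[1]]), start1 = as.integer(df[[2]]),
               end1 = as.integer(df[[3]]), chrom2 = as.character(df[[4]]),
               start2 = as.integer(df[[5]]), end2 = as.integer(df[[6]]),
               stringsAsFactors = FALSE)
  }
}

empty_intervals <- function(format) {
  switch(format,
    bed = data.frame(chrom = character(), start = integer(), end = integer()),
    narrowPeak = data.frame(chrom = character(), start = integer(), end = integer(),
                            name = character(), score = numeric(), strand = character(),
                            signal = numeric(), p = numeric(), q = numeric(),
                            summit = integer()),
    bedpe_tsv = data.frame(chrom1 = character(), start1 = integer(), end1 = integer(),
                           chrom2 = character(), start2 = integer(), end2 = integer()))
}

#' Write peaks as ENCODE narrowPeak
#'
#' The absolute `summit` column is converted back to a summit offset
#' (column 10). Missing optional columns are filled with narrowPeak
#' placeholder values.
#' @param peaks data.frame as returned by [read_intervals()] narrowPeak mode
#' @param path output file
#' @return `path`, invisibly
#' @export
write_narrowpeak <- function(peaks, path) {
  n <- nrow(peaks)
  get <- function(col, default) if (col %in% names(peaks)) peaks[[col]] else rep(default, n)
  mid <- peaks$start + (peaks$end - peaks$start) %/% 2L
  summit <- if ("summit" %in% names(peaks)) peaks$summit else mid
  out <- data.frame(peaks$chrom, peaks$start, peaks$end,
                    get("name", sprintf("peak_%d", seq_len(max(n, 0)))),
                    get("score", 0), get("strand", "."),
                    get("signal", 0), get("p", -1), get("q", -1),
                    as.integer(summit - peaks$start))
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write BED intervals
#' @param df interval data.frame (chrom/start/end, optional name/score/strand)
#' @param path output file
#' @return `path`, invisibly
#' @export
write_bed <- function(df, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"), names(df))
  write.table(df[, cols, drop = FALSE], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a count matrix container
#'
#' @param counts non-negative integer matrix, features x samples, with
#'   dimnames
#' @param library_sizes named per-sample totals; defaults to column sums
#' @param tmm_factors optional named per-sample TMM factors
#' @return an object of class `count_matrix`
#' @export
count_matrix <- function(counts, library_sizes = NULL, tmm_factors = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_fmt("counts must have feature and sample dimnames")
  if (any(counts < 0)) stop_fmt("counts must be non-negative")
  if (is.null(library_sizes)) library_sizes <- colSums(counts)
  library_sizes <- library_sizes[colnames(counts)]
  if (any(library_sizes < colSums(counts) - 1e-8))
    stop_fmt("library_sizes smaller than in-feature column sums")
  structure(list(counts = counts, library_sizes = library_sizes,
                 tmm_factors = tmm_factors),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d features x %d samples%s\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$tmm_factors)) "" else " (TMM-normalized)"))
  invisible(x)
}

#' Write a count matrix to TSV (feature_id + one column per sample)
#'
#' Library sizes and TMM factors, when present, go to a `<path>.sizes.tsv`
#' sidecar so the matrix file stays a plain feature-by-sample grid.
#' @param cm a `count_matrix`
#' @param path output TSV
#' @return `path`, invisibly
#' @export
write_count_matrix <- function(cm, path) {
  df <- data.frame(feature_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- data.frame(sample_id = colnames(cm$counts),
                     library_size = as.numeric(cm$library_sizes),
                     tmm_factor = if (is.null(cm$tmm_factors)) NA_real_
                                  else as.numeric(cm$tmm_factors[colnames(cm$counts)]))
  write.table(side, paste0(path, ".sizes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a count matrix written by [write_count_matrix()]
#' @param path TSV path
#' @return a `count_matrix`
#' @export
read_count_matrix <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  side_path <- paste0(path, ".sizes.tsv")
  ls <- NULL; tf <- NULL
  if (file.exists(side_path)) {
    side <- read.delim(side_path, stringsAsFactors = FALSE)
    ls <- setNames(side$library_size, side$sample_id)
    if (!all(is.na(side$tmm_factor))) tf <- setNames(side$tmm_factor, side$sample_id)
  }
  count_matrix(m, library_sizes = ls, tmm_factors = tf)
}

#' Write position weight matrices as MEME-like text
#'
#' One `MOTIF <tf_id>` block per PWM followed by a
#' `letter-probability matrix` header and one row of A/C/G/T probabilities
#' per motif position.
#' @param pwms named list of position x 4 probability matrices
#' @param path output file
#' @param background length-4 background probabilities (A,C,G,T)
#' @return `path`, invisibly
#' @export
write_pwms <- function(pwms, path, background = rep(0.25, 4)) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("MEME-like motif file", "",
               "ALPHABET= ACGT", "",
               paste("Background letter frequencies:"),
               paste(sprintf("%s %.6f", c("A", "C", "G", "T"), background), collapse = " "),
               ""), con)
  for (id in names(pwms)) {
    m <- pwms[[id]]
    writeLines(sprintf("MOTIF %s", id), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d", nrow(m)), con)
    writeLines(apply(m, 1, function(r) paste(sprintf("%.6f", r), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read PWMs written by [write_pwms()]
#' @param path motif text file
#' @return list with `pwms` (named list of matrices) and `background`
#' @export
read_pwms <- function(path) {
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bg_i <- grep("^Background letter frequencies", lines)
  if (length(bg_i)) {
    toks <- strsplit(trimws(lines[bg_i[1] + 1]), "\\s+")[[1]]
    bg <- as.numeric(toks[c(2, 4, 6, 8)])
  }
  motif_i <- grep("^MOTIF ", lines)
  pwms <- list()
  for (i in motif_i) {
    id <- strsplit(lines[i], "\\s+")[[1]][2]
    hdr <- lines[i + 1]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", hdr))
    rows <- lines[(i + 2):(i + 1 + w)]
    m <- do.call(rbind, lapply(strsplit(trimws(rows), "\\s+"), as.numeric))
    colnames(m) <- c("A", "C", "G", "T")
    pwms[[id]] <- m
  }
  list(pwms = pwms, background = bg)
}

#' Write named result tables with a run manifest
#'
#' Each table is written as a TSV with header and deterministic column
#' order. `manifest.json` records file names, row counts and the
#' configuration hash; a rerun with the same config and seed is
#' byte-identical. Writing over an existing manifest with a different
#' config hash is refused unless `overwrite = TRUE`.
#'
#' @param tables named list of data.frames
#' @param out_dir output directory (created if needed)
#' @param cfg the `pipeline_config` of the run
#' @param overwrite allow replacing results from a different configuration
#' @return the manifest, invisibly
#' @export
write_results <- function(tables, out_dir, cfg = pipeline_config(), overwrite = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(cfg)
  man_path <- file.path(out_dir, "manifest.json")
  if (file.exists(man_path)) {
    old <- jsonlite::read_json(man_path)
    if (!identical(old$config_hash, hash) && !overwrite)
      stop_fmt("manifest in %s was produced by a different config (hash %s != %s); use overwrite = TRUE",
               out_dir, old$config_hash, hash)
  }
  entries <- lapply(names(tables), function(nm) {
    df <- tables[[nm]]
    df <- df[, sort(names(df)), drop = FALSE]
    f <- paste0(nm, ".tsv")
    write.table(df, file.path(out_dir, f), sep = "\t", quote = FALSE,
                row.names = FALSE)
    list(file = f, rows = nrow(df))
  })
  manifest <- list(config_hash = hash, seed = cfg$seed, tables = setNames(entries, names(tables)))
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
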