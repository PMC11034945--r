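#' Pipeline configuration
#'
#' Collects every tunable constant of the pipeline in one serializable list.
#' Defaults reproduce the study design this package emulates:
#'
#' * promoter windows of 4 kb upstream / 1 kb downstream of the TSS,
#' * 150 bp motif-scan windows centered on H3K27ac peak summits,
#' * 5 kb genome bins for chromatin-signal clustering,
#' * low-count filter "fewer than `min_count` reads in over `min_sample_frac`
#'   of samples",
#' * PageRank damping 0.85 with L1 tolerance 1e-8,
#' * FDR alpha 0.05, pairwise-PageRank reversal threshold 0.5,
#' * age-correlation thresholds 0.50 (neuronal) and 0.60 (glial).
#'
#' @param ... named overrides of any default field.
#' @return an object of class `pipeline_config` (a named list).
#' @examples
#' cfg <- pipeline_config(seed = 42, fdr_alpha = 0.1)
#' cfg$promoter_up
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    promoter_up = 4000L,
    promoter_down = 1000L,
    motif_window = 150L,
    bin_size = 5000L,
    min_count = 20L,
    min_sample_frac = 0.5,
    damping = 0.85,
    ppr_tol = 1e-8,
    fdr_alpha = 0.05,
    ppr_delta_threshold = 0.5,
    age_r_threshold_neuron = 0.50,
    age_r_threshold_glia = 0.60,
    great_basal_up = 5000L,
    great_basal_down = 1000L,
    great_max_extension = 1e6,
    pc_r_cut = 0.3,
    pc_p_cut = 0.05,
    n_pcs_chip = 6L,
    n_pcs_rna = 10L,
    top_tfs = 4L,
    min_tf_count = 3L,
    n_clusters = 50L,
    n_sections = 6L,
    seed = 1L
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(cfg))
    if (length(bad)) stop_fmt("unknown config field(s): %s", paste(bad, collapse = ", "))
    cfg[names(ov)] <- ov
  }
  stopifnot(cfg$damping > 0, cfg$damping < 1, cfg$ppr_tol > 0,
            cfg$min_sample_frac >= 0, cfg$min_sample_frac <= 1)
  structure(cfg, class = "pipeline_config")
}

#' Write a configuration to a flat `key: value` text file
#' @param cfg a `pipeline_config`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_config <- function(cfg, path) {
  lines <- vapply(names(cfg), function(k) {
    sprintf("%s: %s", k, format(cfg[[k]], scientific = FALSE, digits = 15))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a configuration written by [write_config()]
#' @param path config file
#' @return a `pipeline_config`
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z0-9_]+)\\s*:\\s*(.*)$", lines))
  bad <- vapply(kv, length, integer(1)) != 3
  if (any(bad)) stop_fmt("malformed config line: %s", lines[bad][1])
  keys <- vapply(kv, `[`, character(1), 2)
  vals <- vapply(kv, `[`, character(1), 3)
  defaults <- pipeline_config()
  out <- lapply(seq_along(keys), function(i) {
    v <- suppressWarnings(as.numeric(vals[i]))
    if (is.na(v)) stop_fmt("non-numeric config value for %s", keys[i])
    if (keys[i] %in% names(defaults) && is.integer(defaults[[keys[i]]])) as.integer(v) else v
  })
  do.call(pipeline_config, setNames(out, keys))
}

config_hash <- function(cfg) {
  fnv1a_hash(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA))
}
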