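## Stage-oriented pipeline: simulate -> qc -> peaks -> differential ->
## network -> pagerank -> compare -> episig -> report. Each stage is a
## function of the on-disk study plus the shared config, so the CLI
## subcommands and the in-memory `run_pipeline()` share one code path.
## Everything is a pure function of (study, config$seed); reruns are
## byte-identical.

#' Write a synthetic study to disk
#'
#' Materializes a genome model and simulated cohort in the formats the
#' rest of the pipeline reads: sample sheet CSV, gene/loop TSVs, PWM
#' text, genome FASTA-like text, count-matrix TSVs and the planted truth
#' table.
#'
#' @param dir output directory
#' @param cfg a `pipeline_config`
#' @param model_args overrides for [make_genome_model()]
#' @param n_pairs_af,n_pairs_at cohort sizes
#' @param params [cohort_params()]
#' @return the in-memory study list, invisibly
#' @export
write_synthetic_study <- function(dir, cfg = pipeline_config(),
                                  model_args = list(),
                                  n_pairs_af = 15, n_pairs_at = 14,
                                  params = cohort_params()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  model <- do.call(make_genome_model, c(model_args, list(seed = cfg$seed)))
  sim <- simulate_cohort(model, n_pairs_af, n_pairs_at, params, seed = cfg$seed)
  write_config(cfg, file.path(dir, "config.txt"))
  write_sample_sheet(sim$sheet, file.path(dir, "sheet.csv"))
  write.table(model$genes, file.path(dir, "genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(model$loops, file.path(dir, "loops.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_pwms(model$pwms, file.path(dir, "motifs.meme"), model$background)
  write.table(model$true_network, file.path(dir, "true_network.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(chrom = names(model$chrom_lengths),
                         length = as.integer(model$chrom_lengths)),
              file.path(dir, "chrom_sizes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  con <- file(file.path(dir, "genome.fa"), "w")
  for (ch in names(model$seqs)) {
    writeLines(paste0(">", ch), con)
    writeLines(model$seqs[[ch]], con)
  }
  close(con)
  write_bed(model$cpg_islands, file.path(dir, "cpg_islands.bed"))
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$features$chip, file.path(dir, "chip_features.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  dir.create(file.path(dir, "counts"), showWarnings = FALSE)
  for (key in names(sim$counts))
    write_count_matrix(sim$counts[[key]], file.path(dir, "counts", paste0(key, ".tsv")))
  invisible(c(sim, list(model = model, dir = dir, cfg = cfg)))
}

#' Load a study directory written by [write_synthetic_study()]
#' @param dir study directory
#' @return study list (sheet, counts, truth, model pieces)
#' @export
load_study <- function(dir) {
  cfg <- read_config(file.path(dir, "config.txt"))
  sheet <- read_sample_sheet(file.path(dir, "sheet.csv"))
  genes <- read.delim(file.path(dir, "genes.tsv"), stringsAsFactors = FALSE)
  loops <- read_intervals(file.path(dir, "loops.tsv"), "bedpe_tsv")
  pw <- read_pwms(file.path(dir, "motifs.meme"))
  cs <- read.delim(file.path(dir, "chrom_sizes.tsv"), stringsAsFactors = FALSE)
  fa <- readLines(file.path(dir, "genome.fa"))
  hdr <- grep("^>", fa)
  seqs <- setNames(lapply(seq_along(hdr), function(i) {
    to <- if (i < length(hdr)) hdr[i + 1] - 1 else length(fa)
    paste(fa[(hdr[i] + 1):to], collapse = "")
  }), sub("^>", "", fa[hdr]))
  counts_files <- list.files(file.path(dir, "counts"), pattern = "\\.tsv$", full.names = TRUE)
  counts_files <- counts_files[!grepl("sizes\\.tsv$", counts_files)]
  counts <- setNames(lapply(counts_files, read_count_matrix),
                     sub("\\.tsv$", "", basename(counts_files)))
  truth_path <- file.path(dir, "truth.tsv")
  list(cfg = cfg, sheet = sheet, genes = genes, loops = loops,
       pwms = pw$pwms, background = pw$background,
       chrom_lengths = setNames(cs$length, cs$chrom), seqs = seqs,
       counts = counts,
       chip_features = read.delim(file.path(dir, "chip_features.tsv"), stringsAsFactors = FALSE),
       true_network = read.delim(file.path(dir, "true_network.tsv"), stringsAsFactors = FALSE),
       cpg_islands = read_intervals(file.path(dir, "cpg_islands.bed"), "bed"),
       truth = if (file.exists(truth_path)) read.delim(truth_path, stringsAsFactors = FALSE) else NULL,
       dir = dir)
}

## cohort-specific set lists -> called-effect table (empty-safe)
called_from_sets <- function(sets) {
  mk <- function(ids, cl) data.frame(feature_id = as.character(ids),
                                     effect_class = rep(cl, length(ids)),
                                     stringsAsFactors = FALSE)
  rbind(mk(sets$af_only, "AF_reversed"), mk(sets$at_only, "AT_induced"),
        mk(sets$shared, "shared"))
}

## subject-level (replicate-summed) counts for one assay/fraction key
subject_counts <- function(study, key) {
  cm <- study$counts[[key]]
  sheet <- study$sheet[match(colnames(cm$counts), study$sheet$sample_id), ]
  subj <- unique(sheet$subject_id)
  m <- vapply(subj, function(s) {
    cols <- sheet$sample_id[sheet$subject_id == s]
    rowSums(cm$counts[, cols, drop = FALSE])
  }, numeric(nrow(cm$counts)))
  lib <- vapply(subj, function(s) {
    cols <- sheet$sample_id[sheet$subject_id == s]
    sum(cm$library_sizes[cols])
  }, numeric(1))
  meta <- sheet[!duplicated(sheet$subject_id),
                c("subject_id", "pair_id", "group", "cohort", "sex", "age", "pmd")]
  list(cm = count_matrix(m, library_sizes = lib), meta = meta)
}

#' Peaks stage: high-confidence and master consensus peaks plus counts
#'
#' Per ChIP sample, each replicate's detected peaks are the feature
#' intervals whose replicate count reaches the detection threshold; the
#' sample's high-confidence set is the replicate intersection-support
#' union-merge, and the master set is the union-merge across samples.
#' Subject-level count matrices over the master set are TMM-normalized
#' and low-count filtered.
#'
#' @param study loaded study
#' @param cfg `pipeline_config`
#' @param detect_min minimum replicate count for a detected peak
#' @return list per assay/fraction key: `highconf` (per subject), `master`,
#'   `counts` (filtered, TMM-normalized subject `count_matrix`), `meta`
#' @export
pipeline_peaks <- function(study, cfg = pipeline_config(), detect_min = 10L) {
  feats <- study$chip_features
  keys <- grep("^(H3K27ac|H3K4me3)\\.", names(study$counts), value = TRUE)
  out <- list()
  for (key in keys) {
    cm <- study$counts[[key]]
    sheet <- study$sheet[match(colnames(cm$counts), study$sheet$sample_id), ]
    subj <- unique(sheet$subject_id)
    highconf <- setNames(lapply(subj, function(s) {
      reps <- sheet$sample_id[sheet$subject_id == s]
      rep_peaks <- lapply(reps, function(r) {
        det <- cm$counts[, r] >= detect_min
        p <- feats[det, c("chrom", "start", "end", "summit"), drop = FALSE]
        p$score <- log1p(cm$counts[det, r])
        p$name <- feats$feature_id[det]
        p
      })
      Reduce(high_confidence_peaks, rep_peaks)
    }), subj)
    master <- consensus_master(highconf)
    ## map master peaks back to feature counts (feature fully within one
    ## master peak at this scale)
    ov <- GenomicRanges::findOverlaps(as_granges(feats), as_granges(master))
    f2m <- rep(NA_integer_, nrow(feats))
    f2m[S4Vectors::queryHits(ov)] <- S4Vectors::subjectHits(ov)
    sc <- subject_counts(study, key)
    mcounts <- rowsum(sc$cm$counts[!is.na(f2m), , drop = FALSE],
                      group = f2m[!is.na(f2m)])
    rownames(mcounts) <- master$name[as.integer(rownames(mcounts))]
    mcm <- count_matrix(mcounts, library_sizes = sc$cm$library_sizes)
    mcm <- filter_low(tmm_normalize(mcm), cfg$min_count, cfg$min_sample_frac)
    out[[key]] <- list(highconf = highconf, master = master,
                       counts = mcm, meta = sc$meta,
                       feature_of_master = setNames(feats$feature_id[!is.na(f2m)],
                                                    master$name[f2m[!is.na(f2m)]]))
  }
  out
}

## expression matrices and covariate-aware differential for one key
run_differential <- function(cm, meta, cfg, adjust, n_pcs) {
  covars <- meta[, c("sex", "age", "pmd"), drop = FALSE]
  norm <- normalized_log(cm)
  sel <- tryCatch(
    pc_covariate_select(norm, covars, n_pcs = min(n_pcs, ncol(norm) - 1L),
                        r_cut = cfg$pc_r_cut, p_cut = cfg$pc_p_cut),
    error = function(e) character())
  cv <- if (length(sel)) covars[, sel, drop = FALSE] else NULL
  nb_differential(cm, meta$group, covariates = cv, adjust_method = adjust,
                  alpha = cfg$fdr_alpha)
}

#' Differential stage: per-cohort NB tests and peak annotation
#'
#' ChIP features use Bonferroni adjustment, RNA uses BH (FDR), matching
#' the two conventions of the study design. Results are computed for each
#' cohort separately (AF pairs, AT pairs) and for the pooled cohort.
#'
#' @param study loaded study
#' @param pk output of [pipeline_peaks()]
#' @param cfg `pipeline_config`
#' @return list: `results[[key]][[cohort]]` differential tables,
#'   `annotation[[key]]` peak annotations, `rna` subject expression info
#' @export
pipeline_differential <- function(study, pk, cfg = pipeline_config()) {
  results <- list(); annotation <- list()
  for (key in names(pk)) {
    meta <- pk[[key]]$meta
    cm <- pk[[key]]$counts
    results[[key]] <- lapply(c(all = "all", AF = "AF", AT = "AT"), function(co) {
      sel <- if (co == "all") rep(TRUE, nrow(meta)) else meta$cohort == co
      sub <- count_matrix(cm$counts[, meta$subject_id[sel], drop = FALSE],
                          library_sizes = cm$library_sizes[meta$subject_id[sel]])
      sub <- tmm_normalize(sub)
      run_differential(sub, meta[sel, ], cfg, "bonferroni", cfg$n_pcs_chip)
    })
    annotation[[key]] <- annotate_peaks(pk[[key]]$master, study$genes, study$loops,
                                        cfg$promoter_up, cfg$promoter_down)
  }
  rna <- list()
  for (key in grep("^RNA\\.", names(study$counts), value = TRUE)) {
    sc <- subject_counts(study, key)
    cm <- filter_low(tmm_normalize(sc$cm), cfg$min_count, cfg$min_sample_frac)
    res <- lapply(c(all = "all", AF = "AF", AT = "AT"), function(co) {
      sel <- if (co == "all") rep(TRUE, nrow(sc$meta)) else sc$meta$cohort == co
      sub <- count_matrix(cm$counts[, sc$meta$subject_id[sel], drop = FALSE],
                          library_sizes = cm$library_sizes[sc$meta$subject_id[sel]])
      sub <- tmm_normalize(sub)
      run_differential(sub, sc$meta[sel, ], cfg, "bh", cfg$n_pcs_rna)
    })
    rna[[key]] <- list(results = res, counts = cm, meta = sc$meta)
  }
  list(results = results, annotation = annotation, rna = rna)
}

#' Network + PageRank stage
#'
#' Motif hits are computed once per (ChIP feature, TF) on the 150 bp
#' summit windows; per subject, the network is restricted to features in
#' that subject's high-confidence H3K27ac peak set, node weights come
#' from the subject's expression z-scores, and edge weights combine TF
#' expression with pooled peak intensity. Personalized PageRank runs per
#' subject; per-TF scores are z-scored across subjects within the
#' fraction.
#'
#' @param study loaded study
#' @param pk output of [pipeline_peaks()]
#' @param diff output of [pipeline_differential()]
#' @param cfg `pipeline_config`
#' @return list per fraction: `networks` (per subject), `ppr` (subjects x
#'   genes), `ppr_z` (subjects x TFs, z-scored), `motif_edges`
#' @export
pipeline_network <- function(study, pk, diff, cfg = pipeline_config()) {
  feats <- study$chip_features
  tf_ids <- names(study$pwms)
  ## motif hits per (feature, tf): fixed across subjects
  hit_tab <- motif_edge_table(study, cfg)
  out <- list()
  for (fr in unique(study$sheet$fraction)) {
    k27 <- paste0("H3K27ac.", fr)
    rna_key <- paste0("RNA.", fr)
    if (!k27 %in% names(pk) || !rna_key %in% names(diff$rna)) next
    rna <- diff$rna[[rna_key]]
    norm <- normalized_log(rna$counts)
    zmat <- scale(norm)                      # z across genes, per sample
    pooled <- rowMeans(sweep(study$counts[[k27]]$counts, 2,
                             colSums(study$counts[[k27]]$counts) / 1e6, "/"))
    inten <- setNames(pooled, rownames(study$counts[[k27]]$counts))
    subj <- colnames(norm)
    networks <- setNames(lapply(subj, function(s) {
      hc <- pk[[k27]]$highconf[[s]]
      present <- feats$feature_id[GenomicRanges::countOverlaps(
        as_granges(feats), as_granges(hc)) > 0]
      active <- active_promoters(hc, study$genes, cfg$promoter_up, cfg$promoter_down)
      me <- hit_tab[hit_tab$peak_id %in% present &
                      (hit_tab$provenance == "enhancer" | hit_tab$gene %in% active), ]
      build_network(me, setNames(zmat[, s], rownames(zmat)), inten, study$genes)
    }), subj)
    ppr <- t(vapply(networks, function(nw) {
      personalized_pagerank(nw, cfg$damping, cfg$ppr_tol)$scores
    }, numeric(nrow(study$genes))))
    rownames(ppr) <- subj
    ppr_z <- scale(ppr[, intersect(tf_ids, colnames(ppr)), drop = FALSE])
    ppr_z[, !is.finite(colSums(ppr_z))] <- 0
    out[[fr]] <- list(networks = networks, ppr = ppr, ppr_z = ppr_z,
                      motif_edges = hit_tab)
  }
  out
}

## scan every TF PWM against every chip feature's summit window
motif_edge_table <- function(study, cfg) {
  feats <- study$chip_features
  rows <- list()
  for (i in seq_len(nrow(feats))) {
    win <- summit_window(feats[i, ], cfg$motif_window, study$chrom_lengths)
    seqstr <- substr(study$seqs[[win$chrom]], win$start + 1L, win$end)
    for (tf in names(study$pwms)) {
      hits <- scan_motif(study$pwms[[tf]], seqstr, p_threshold = 1e-4,
                         background = study$background)
      if (nrow(hits) > 0)
        rows[[length(rows) + 1]] <- data.frame(
          tf = tf, gene = feats$gene_id[i], peak_id = feats$feature_id[i],
          provenance = feats$kind[i], stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(tf = character(), gene = character(),
                      peak_id = character(), provenance = character()))
  unique(do.call(rbind, rows))
}

#' Compare stage: reversal classification, regulatees, cohort sets, age
#'
#' @param study loaded study
#' @param net output of [pipeline_network()]
#' @param diff output of [pipeline_differential()]
#' @param cfg `pipeline_config`
#' @return list per fraction: `reversal`, `top_tfs`, `regulatees`,
#'   `cohort_sets`, `age` (per mode/cohort correlation tables)
#' @export
pipeline_compare <- function(study, net, diff, cfg = pipeline_config()) {
  out <- list()
  for (fr in names(net)) {
    rna <- diff$rna[[paste0("RNA.", fr)]]
    meta <- rna$meta
    meta$sample_id <- meta$subject_id
    ppr_z <- net[[fr]]$ppr_z
    af_meta <- meta[meta$cohort == "AF", ]
    at_meta <- meta[meta$cohort == "AT", ]
    d_af <- pairwise_diff(ppr_z[af_meta$sample_id, , drop = FALSE], af_meta)
    d_at <- pairwise_diff(ppr_z[at_meta$sample_id, , drop = FALSE], at_meta)
    to_mat <- function(d) {
      feats <- unique(d$feature_id)
      ## pairwise_diff stacks one feature-block per pair
      m <- matrix(d$delta, nrow = length(unique(d$pair_id)), byrow = TRUE,
                  dimnames = list(unique(d$pair_id), feats))
      m
    }
    m_af <- to_mat(d_af); m_at <- to_mat(d_at)
    reversal <- classify_reversal(m_af, m_at,
                                  threshold = cfg$ppr_delta_threshold,
                                  alpha = cfg$fdr_alpha)
    tf_diff <- rna$results$all[rna$results$all$feature_id %in% colnames(ppr_z), ]
    rank_tab <- ppr_rank_tfs(net[[fr]]$ppr_z, tf_diff, meta, alpha = cfg$fdr_alpha)
    top <- head(rank_tab$tf, cfg$top_tfs)
    regul <- if (length(top) >= cfg$min_tf_count)
      extract_regulatees(net[[fr]]$networks, top, rna$results$all, meta,
                         min_tf_count = cfg$min_tf_count, alpha = cfg$fdr_alpha)
      else character()
    sets <- cohort_specific_sets(rna$results$AF, rna$results$AT, cfg$fdr_alpha)
    ## age correlations: pairwise expression and pairwise PPR per cohort
    norm <- t(normalized_log(rna$counts))
    r_thr <- if (fr == "NeuNpos") cfg$age_r_threshold_neuron else cfg$age_r_threshold_glia
    age_tabs <- list()
    for (co in c("AF", "AT")) {
      cm_meta <- meta[meta$cohort == co, ]
      for (mode in c("expression", "ppr")) {
        vals <- if (mode == "expression") norm[cm_meta$sample_id, , drop = FALSE]
                else ppr_z[cm_meta$sample_id, , drop = FALSE]
        d <- pairwise_diff(vals, cm_meta)
        dm <- to_mat(d)
        ages <- cm_meta$age[match(rownames(dm), cm_meta$pair_id)]
        corr <- suppressWarnings(age_correlation(dm, ages))
        age_tabs[[paste(mode, co, sep = "_")]] <-
          c(age_correlated_features(corr, r_thr), list(correlations = corr))
      }
    }
    out[[fr]] <- list(reversal = reversal, rank = rank_tab, top_tfs = top,
                      regulatees = regul, cohort_sets = sets, age = age_tabs)
  }
  out
}

#' EpiSig stage: binned signal clustering with enrichment
#'
#' Per dataset (subject x ChIP assay within the fraction), per-bin raw
#' counts are composed from a Poisson background plus the dataset's
#' feature counts placed at the feature summit bins; enriched bins are
#' clustered and sections formed, annotation coverage computed, and
#' differential features tested for per-cluster enrichment.
#'
#' @param study loaded study
#' @param pk output of [pipeline_peaks()]
#' @param diff output of [pipeline_differential()]
#' @param cfg `pipeline_config`
#' @param background_lambda Poisson background rate per bin
#' @return list: `clusters`, `sections`, `annotation`, `enrichment`
#' @export
pipeline_episig <- function(study, pk, diff, cfg = pipeline_config(),
                            background_lambda = 2) {
  bins <- genome_bins(study$chrom_lengths, cfg$bin_size)
  feats <- study$chip_features
  fbin <- features_to_bins_raw(bins, feats)
  keys <- grep("^(H3K27ac|H3K4me3)\\.", names(study$counts), value = TRUE)
  raw_cols <- list()
  with_seed(child_seed(study$cfg$seed, 9L), {
    for (key in keys) {
      sc <- subject_counts(study, key)
      for (s in colnames(sc$cm$counts)) {
        col <- stats::rpois(nrow(bins), background_lambda)
        add <- rowsum(sc$cm$counts[, s], group = fbin)
        col[as.integer(rownames(add))] <- col[as.integer(rownames(add))] + add[, 1]
        raw_cols[[paste(key, s, sep = ".")]] <- col
      }
    }
  })
  bm <- bin_matrix_from_counts(bins, do.call(cbind, raw_cols))
  enriched <- select_enriched(bm)
  k <- min(cfg$n_clusters, max(2L, length(enriched) %/% 5L))
  clusters <- cluster_bins(bm, enriched, k, seed = study$cfg$seed)
  sections <- group_sections(clusters, min(cfg$n_sections, k), seed = study$cfg$seed)
  ann <- annotate_clusters(clusters, study$genes, study$cpg_islands,
                           cfg$promoter_up, cfg$promoter_down)
  ## differential features: significant ChIP peaks + DEG TSS bins
  diff_int <- list()
  for (key in names(diff$results)) {
    res <- diff$results[[key]]$all
    sig_master <- res$feature_id[res$significant]
    m <- pk[[key]]$master
    diff_int[[key]] <- m[m$name %in% sig_master, c("chrom", "start", "end")]
  }
  degs <- unlist(lapply(diff$rna, function(r) {
    r$results$all$feature_id[r$results$all$significant]
  }))
  dbins <- unique(c(
    features_to_bins(clusters, do.call(rbind, diff_int)),
    features_to_bins(clusters, unique(degs), genes = study$genes)))
  enr <- cluster_enrichment(clusters, dbins, alpha = cfg$fdr_alpha)
  list(clusters = clusters, sections = sections, annotation = ann,
       enrichment = enr, bin_matrix_dims = dim(bm$raw))
}

## bin index (into the full bin table) of each feature's summit
features_to_bins_raw <- function(bins, feats) {
  idx <- integer(nrow(feats))
  for (ch in unique(feats$chrom)) {
    sel <- feats$chrom == ch
    b <- bins[bins$chrom == ch, ]
    idx[sel] <- which(bins$chrom == ch)[findInterval(feats$summit[sel], b$start)]
  }
  idx
}

#' QC stage: tag-level metrics for representative samples
#'
#' Simulates read tags for a small number of representative ChIP samples
#' (tag simulation is the QC substrate; counts drive the differential
#' pipeline) and computes FRiP, PBC, NSC/RSC and the fragment-length
#' estimate, plus replicate correlations from the count matrices.
#'
#' @param study loaded study
#' @param cfg `pipeline_config`
#' @param n_samples number of representative samples
#' @param depth tag depth per sample
#' @return data.frame of QC records
#' @export
pipeline_qc <- function(study, cfg = pipeline_config(), n_samples = 2,
                        depth = 20000) {
  feats <- study$chip_features
  model_like <- list(chrom_lengths = study$chrom_lengths)
  keys <- grep("^H3K27ac\\.", names(study$counts), value = TRUE)
  cm <- study$counts[[keys[1]]]
  sheet <- study$sheet[match(colnames(cm$counts), study$sheet$sample_id), ]
  subj <- unique(sheet$subject_id)[seq_len(n_samples)]
  out <- list()
  for (i in seq_along(subj)) {
    s <- subj[i]
    tags <- simulate_tags(model_like, feats[, c("chrom", "start", "end")],
                          depth = depth, fragment_length = 200, read_length = 50,
                          in_peak_frac = 0.6, dup_rate = 0.1,
                          seed = child_seed(study$cfg$seed, 20L + i))
    reps <- sheet$sample_id[sheet$subject_id == s]
    rc <- if (length(reps) >= 2) list(cm$counts[, reps[1]], cm$counts[, reps[2]]) else NULL
    out[[s]] <- qc_record(s, tags, feats[, c("chrom", "start", "end")],
                          max_shift = 400, replicate_counts = rc)
  }
  do.call(rbind, out)
}

#' Run the full pipeline on a synthetic study
#'
#' simulate -> qc -> peaks -> differential -> network/pagerank ->
#' compare -> episig -> report, writing all stage outputs and a manifest
#' under `out_dir`. Deterministic and byte-identical given the config
#' (including its seed).
#'
#' @param out_dir output directory (study files + `results/`)
#' @param cfg `pipeline_config`
#' @param model_args overrides for [make_genome_model()]
#' @param n_pairs_af,n_pairs_at cohort sizes
#' @param params [cohort_params()]
#' @param fractions which cell fractions to process
#' @return list of all stage outputs, invisibly
#' @export
run_pipeline <- function(out_dir, cfg = pipeline_config(),
                         model_args = list(), n_pairs_af = 15, n_pairs_at = 14,
                         params = cohort_params(),
                         fractions = "NeuNpos") {
  write_synthetic_study(out_dir, cfg, model_args, n_pairs_af, n_pairs_at, params)
  study <- load_study(out_dir)
  study$sheet <- study$sheet[study$sheet$fraction %in% fractions, ]
  study$counts <- study$counts[sub("^[^.]+\\.", "", names(study$counts)) %in% fractions]
  qc <- pipeline_qc(study, cfg)
  pk <- pipeline_peaks(study, cfg)
  diff <- pipeline_differential(study, pk, cfg)
  net <- pipeline_network(study, pk, diff, cfg)
  cmp <- pipeline_compare(study, net, diff, cfg)
  epi <- pipeline_episig(study, pk, diff, cfg)

  ## report: recovery of planted truth from the RNA differential calls
  fr <- fractions[1]
  rna_all <- diff$rna[[paste0("RNA.", fr)]]$results
  called <- called_from_sets(cmp[[fr]]$cohort_sets)
  gene_truth <- study$truth[study$truth$feature_kind %in% c("gene", "TF"), ]
  report <- truth_report(gene_truth, called)

  tables <- list(
    qc = qc,
    differential_rna_all = rna_all$all,
    reversal = cmp[[fr]]$reversal,
    tf_rank = cmp[[fr]]$rank,
    episig_enrichment = epi$enrichment,
    episig_annotation = epi$annotation,
    truth_recovery = report)
  write_results(tables, file.path(out_dir, "results"), cfg, overwrite = TRUE)
  invisible(list(study = study, qc = qc, peaks = pk, differential = diff,
                 network = net, compare = cmp, episig = epi, report = report))
}
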