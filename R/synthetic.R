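## Synthetic study generator: a small genome with genes, TFs, motifs, a
## known TF->gene network, chromatin loops, matched-pair cohorts with
## negative-binomial counts, planted effect classes, and read-level tags.
## Everything is a pure function of (arguments, seed).

DNA <- c("A", "C", "G", "T")

#' Build a synthetic genome model
#'
#' Creates a toy genome with named chromosomes, genes with TSS and strand,
#' a designated TF subset each carrying a high-information PWM, a known
#' (planted) TF-to-gene regulatory network, distal enhancers linked to
#' ~20% of genes through a chromatin-loop table, and random background
#' sequence with each regulator's consensus motif planted in its targets'
#' promoter (and linked enhancer) so that motif scanning can recover the
#' network.
#'
#' @param n_chrom number of chromosomes
#' @param n_genes number of genes (>= 10 unless 0 TFs are requested)
#' @param n_tfs number of TFs (<= n_genes)
#' @param seed integer seed; the model is a pure function of it
#' @param chrom_length length of every chromosome in bp
#' @return an object of class `genome_model`: `chrom_lengths`, `genes`,
#'   `tf_ids`, `pwms`, `background`, `true_network`, `loops`, `seqs`,
#'   `cpg_islands`
#' @export
make_genome_model <- function(n_chrom = 2, n_genes = 60, n_tfs = 8, seed = 1,
                              chrom_length = 200000L) {
  if (n_tfs > n_genes) stop_fmt("n_tfs (%d) > n_genes (%d)", n_tfs, n_genes)
  if (n_genes < 10) stop_fmt("n_genes must be >= 10")
  with_seed(child_seed(seed, 1L), {
    chroms <- paste0("chr", seq_len(n_chrom))
    chrom_lengths <- setNames(rep(as.integer(chrom_length), n_chrom), chroms)

    ## genes evenly interleaved across chromosomes, TSS jittered on a grid
    ## that keeps promoter windows (4 kb / 1 kb) inside the chromosome
    per_chrom <- diff(floor(seq(0, n_genes, length.out = n_chrom + 1)))
    genes <- do.call(rbind, lapply(seq_len(n_chrom), function(ci) {
      k <- per_chrom[ci]
      if (k == 0) return(NULL)
      lo <- 10000; hi <- chrom_length - 10000
      tss <- sort(as.integer(round(seq(lo, hi, length.out = k) +
                                     runif(k, -500, 500))))
      data.frame(chrom = chroms[ci], tss = tss,
                 strand = sample(c("+", "-"), k, replace = TRUE),
                 body_length = as.integer(sample(2000:6000, k, replace = TRUE)),
                 stringsAsFactors = FALSE)
    }))
    genes$gene_id <- sprintf("G%03d", seq_len(nrow(genes)))
    genes$body_start <- ifelse(genes$strand == "+", genes$tss,
                               pmax(0L, genes$tss - genes$body_length))
    genes$body_end <- ifelse(genes$strand == "+",
                             pmin(chrom_length, genes$tss + genes$body_length),
                             genes$tss + 1L)
    genes <- genes[, c("gene_id", "chrom", "tss", "strand", "body_start", "body_end")]

    tf_ids <- if (n_tfs > 0) genes$gene_id[sample(nrow(genes), n_tfs)] else character()

    ## one high-information PWM per TF: consensus base probability 0.85.
    ## Widths 8-12: a width-7 motif is the shortest whose perfect match
    ## clears an exact p <= 1e-4 under the uniform background (0.25^7 ~
    ## 6e-5), so 8 leaves headroom for near-consensus matches
    pwms <- setNames(lapply(seq_along(tf_ids), function(i) {
      w <- sample(8:12, 1)
      cons <- sample(4, w, replace = TRUE)
      m <- matrix(0.05, w, 4, dimnames = list(NULL, DNA))
      m[cbind(seq_len(w), cons)] <- 0.85
      m
    }), tf_ids)

    ## planted network: 3-8 regulatees per TF (self-targets excluded)
    true_network <- if (n_tfs > 0) do.call(rbind, lapply(tf_ids, function(tf) {
      pool <- setdiff(genes$gene_id, tf)
      tgt <- sample(pool, min(length(pool), sample(3:8, 1)))
      data.frame(tf = tf, gene = tgt, stringsAsFactors = FALSE)
    })) else data.frame(tf = character(), gene = character())

    ## ~20% of genes get a distal enhancer linked by a loop to the promoter
    n_enh <- max(1L, round(0.2 * nrow(genes)))
    enh_genes <- sample(genes$gene_id, n_enh)
    loops <- do.call(rbind, lapply(enh_genes, function(g) {
      gi <- genes[genes$gene_id == g, ]
      offset <- sample(c(-1, 1), 1) * sample(12000:30000, 1)
      center <- gi$tss + offset
      center <- min(max(center, 1000), chrom_length - 1000)
      data.frame(chrom1 = gi$chrom, start1 = as.integer(center - 500),
                 end1 = as.integer(center + 500),
                 chrom2 = gi$chrom, start2 = as.integer(gi$tss - 200),
                 end2 = as.integer(gi$tss + 200),
                 gene_id = g, enh_center = as.integer(center),
                 stringsAsFactors = FALSE)
    }))

    ## random sequence, then plant each regulator's consensus near its
    ## targets' TSS (and in the linked enhancer when one exists) so the
    ## 150 bp summit windows of promoter/enhancer peaks contain the motif
    seqs <- setNames(lapply(chrom_lengths, function(L) {
      sample(DNA, L, replace = TRUE)
    }), chroms)
    consensus_of <- function(tf) DNA[apply(pwms[[tf]], 1, which.max)]
    plant <- function(chrom, at, word) {
      idx <- seq(at + 1L, at + length(word))  # `at` is 0-based
      if (idx[1] >= 1 && idx[length(idx)] <= length(seqs[[chrom]]))
        seqs[[chrom]][idx] <<- word
    }
    if (nrow(true_network) > 0) {
      for (g in unique(true_network$gene)) {
        regs <- true_network$tf[true_network$gene == g]
        gi <- genes[genes$gene_id == g, ]
        li <- loops[loops$gene_id == g, , drop = FALSE]
        for (k in seq_along(regs)) {
          word <- consensus_of(regs[k])
          plant(gi$chrom, gi$tss - 65L + 14L * (k - 1L), word)
          if (nrow(li) == 1)
            plant(li$chrom1, li$enh_center - 65L + 14L * (k - 1L), word)
        }
      }
    }

    ## CpG islands: short GC-marked intervals near a third of the TSSs
    cpg_genes <- genes[sample(nrow(genes), max(1L, nrow(genes) %/% 3L)), ]
    cpg <- data.frame(chrom = cpg_genes$chrom,
                      start = pmax(0L, cpg_genes$tss - 300L),
                      end = cpg_genes$tss + 300L, stringsAsFactors = FALSE)

    structure(list(chrom_lengths = chrom_lengths, genes = genes,
                   tf_ids = tf_ids, pwms = pwms, background = rep(0.25, 4),
                   true_network = true_network,
                   loops = loops[, 1:6],
                   loop_genes = loops[, c("gene_id", "enh_center", "chrom1")],
                   seqs = lapply(seqs, paste, collapse = ""),
                   cpg_islands = cpg),
              class = "genome_model")
  })
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("genome_model: %d chrom (%s bp), %d genes, %d TFs, %d planted edges, %d loops\n",
              length(x$chrom_lengths), format(sum(x$chrom_lengths), big.mark = ","),
              nrow(x$genes), length(x$tf_ids), nrow(x$true_network), nrow(x$loops)))
  invisible(x)
}

#' Default synthetic-cohort noise and effect settings
#'
#' Negative-binomial counts with log-normal baseline means
#' (`meanlog = 4`, `sdlog = 1`) and dispersion 0.1 — a standard bulk
#' RNA/ChIP count model. Effects are planted as log2 fold changes of 1
#' (2-fold) on the case mean of the applicable cohort; age-correlated
#' features tilt the case-minus-control log2 mean by
#' `age_slope * (age - 50)` per pair. Ages are uniform on \[20, 80\] and
#' shared exactly within a matched pair.
#'
#' @param ... overrides of any field
#' @return named list of simulation parameters
#' @export
cohort_params <- function(...) {
  p <- list(dispersion = 0.1, meanlog = 4, sdlog = 1,
            n_af_reversed = 10L, n_at_induced = 10L, n_shared = 10L,
            n_age_correlated = 10L,
            log2_effect = 1, age_slope = 0.03,
            age_range = c(20, 80), n_replicates_chip = 2L)
  ov <- list(...)
  bad <- setdiff(names(ov), names(p))
  if (length(bad)) stop_fmt("unknown cohort_params field(s): %s", paste(bad, collapse = ", "))
  p[names(ov)] <- ov
  if (p$dispersion <= 0) stop_fmt("dispersion must be positive")
  p
}

#' Simulate a matched-pair cohort with planted effects
#'
#' Generates a sample sheet for `n_pairs_af` antipsychotic-free (AF) and
#' `n_pairs_at` antipsychotic-treated (AT) case/control pairs, and
#' feature-by-sample count matrices for each requested assay/fraction
#' combination. Features are genes for RNA and promoter/enhancer elements
#' for the ChIP marks. Counts are negative-binomial around log-normal
#' baselines; planted effect classes multiply the case mean by
#' `2^log2_effect` in the applicable cohort only (`AF_reversed` in AF
#' pairs, `AT_induced` in AT pairs, `shared` in both), and
#' `age_correlated` features tilt the case mean by
#' `age_slope * (age - 50)` log2 units.
#'
#' @param model a `genome_model`
#' @param n_pairs_af,n_pairs_at pair counts per cohort (sum >= 2)
#' @param params see [cohort_params()]
#' @param seed integer seed
#' @param fractions cell fractions to generate
#' @param assays assays to generate
#' @return list with `sheet` (sample sheet), `counts` (named list
#'   `<assay>.<fraction>` of `count_matrix`), `truth` (EffectTruth table),
#'   `features` (feature annotation incl. genomic position), `params`
#' @export
simulate_cohort <- function(model, n_pairs_af = 15, n_pairs_at = 14,
                            params = cohort_params(), seed = 1,
                            fractions = c("NeuNpos", "NeuNneg"),
                            assays = c("H3K27ac", "H3K4me3", "RNA")) {
  if (n_pairs_af + n_pairs_at < 2) stop_fmt("need at least 2 pairs in total")
  if (params$dispersion <= 0) stop_fmt("dispersion must be positive")
  with_seed(child_seed(seed, 2L), {
    n_pairs <- n_pairs_af + n_pairs_at
    pair_id <- sprintf("P%02d", seq_len(n_pairs))
    cohort <- rep(c("AF", "AT"), c(n_pairs_af, n_pairs_at))
    age <- round(runif(n_pairs, params$age_range[1], params$age_range[2]), 1)
    sex <- sample(c("M", "F"), n_pairs, replace = TRUE)

    subjects <- data.frame(
      pair_id = rep(pair_id, each = 2),
      cohort = rep(cohort, each = 2),
      group = rep(c("case", "control"), n_pairs),
      age = rep(age, each = 2), sex = rep(sex, each = 2),
      pmd = round(runif(2 * n_pairs, 5, 40), 1),
      stringsAsFactors = FALSE)
    subjects$subject_id <- sprintf("S%02d%s", rep(seq_len(n_pairs), each = 2),
                                   c("c", "n"))

    ## feature universes
    feat <- synth_features(model)
    gene_feats <- feat$gene; chip_feats <- feat$chip

    ## effect truth assigned at gene level and propagated to that gene's
    ## chromatin features, so RNA and ChIP stages see a coherent signal
    g_ids <- model$genes$gene_id
    n_eff <- params$n_af_reversed + params$n_at_induced + params$n_shared +
      params$n_age_correlated
    if (n_eff > length(g_ids))
      stop_fmt("more planted effects (%d) than genes (%d)", n_eff, length(g_ids))
    picked <- sample(g_ids, n_eff)
    class_of <- setNames(rep("null", length(g_ids)), g_ids)
    idx <- 0
    for (cl in c("AF_reversed", "AT_induced", "shared", "age_correlated")) {
      k <- params[[switch(cl, AF_reversed = "n_af_reversed",
                          AT_induced = "n_at_induced", shared = "n_shared",
                          age_correlated = "n_age_correlated")]]
      if (k > 0) class_of[picked[idx + seq_len(k)]] <- cl
      idx <- idx + k
    }
    sign_of <- setNames(sample(c(-1, 1), length(g_ids), replace = TRUE), g_ids)

    truth_gene <- data.frame(
      feature_id = g_ids,
      feature_kind = ifelse(g_ids %in% model$tf_ids, "TF", "gene"),
      effect_class = unname(class_of[g_ids]),
      log2_effect = ifelse(class_of[g_ids] %in% c("AF_reversed", "AT_induced", "shared"),
                           params$log2_effect * sign_of[g_ids], 0),
      age_slope = ifelse(class_of[g_ids] == "age_correlated",
                         params$age_slope * sign_of[g_ids], 0),
      stringsAsFactors = FALSE)
    truth_chip <- data.frame(
      feature_id = chip_feats$feature_id,
      feature_kind = chip_feats$kind,
      effect_class = unname(class_of[chip_feats$gene_id]),
      log2_effect = truth_gene$log2_effect[match(chip_feats$gene_id, g_ids)],
      age_slope = truth_gene$age_slope[match(chip_feats$gene_id, g_ids)],
      stringsAsFactors = FALSE)
    truth <- unique(rbind(truth_gene, truth_chip))

    sheet_rows <- list(); counts <- list()
    for (fr in fractions) {
      for (as_ in assays) {
        n_rep <- if (as_ == "RNA") 1L else params$n_replicates_chip
        ids <- feat_ids <- if (as_ == "RNA") g_ids else chip_feats$feature_id
        f_truth <- if (as_ == "RNA") truth_gene else truth_chip
        base_mu <- rlnorm(length(ids), params$meanlog, params$sdlog)
        samp <- expand.grid(rep = seq_len(n_rep),
                            si = seq_len(nrow(subjects)), stringsAsFactors = FALSE)
        sample_id <- sprintf("%s_%s_%s_r%d", subjects$subject_id[samp$si], fr, as_, samp$rep)
        m <- matrix(0L, length(ids), nrow(samp),
                    dimnames = list(ids, sample_id))
        for (j in seq_len(nrow(samp))) {
          sub <- subjects[samp$si[j], ]
          lfc <- rep(0, length(ids))
          if (sub$group == "case") {
            on_af <- f_truth$effect_class == "AF_reversed" & sub$cohort == "AF"
            on_at <- f_truth$effect_class == "AT_induced" & sub$cohort == "AT"
            on_sh <- f_truth$effect_class == "shared"
            lfc <- lfc + f_truth$log2_effect * (on_af | on_at | on_sh)
            lfc <- lfc + f_truth$age_slope * (sub$age - 50) *
              (f_truth$effect_class == "age_correlated")
          }
          mu <- base_mu * 2^lfc
          m[, j] <- rnbinom(length(ids), size = 1 / params$dispersion, mu = mu)
        }
        key <- paste(as_, fr, sep = ".")
        ## library sizes: in-feature totals plus 20% out-of-feature reads
        lib <- round(colSums(m) * 1.25)
        counts[[key]] <- count_matrix(m, library_sizes = lib)
        sheet_rows[[key]] <- data.frame(
          sample_id = sample_id,
          subject_id = subjects$subject_id[samp$si],
          pair_id = subjects$pair_id[samp$si],
          group = subjects$group[samp$si],
          cohort = subjects$cohort[samp$si],
          fraction = fr, assay = as_, replicate = samp$rep,
          sex = subjects$sex[samp$si], age = subjects$age[samp$si],
          pmd = subjects$pmd[samp$si], stringsAsFactors = FALSE)
      }
    }
    sheet <- do.call(rbind, sheet_rows)
    rownames(sheet) <- NULL
    validate_sample_sheet(sheet)
    list(sheet = sheet, counts = counts, truth = truth,
         features = feat, params = params)
  })
}

## Feature universes derived from the genome model: one promoter element
## per gene, one enhancer element per loop-linked gene.
synth_features <- function(model) {
  g <- model$genes
  prom <- data.frame(feature_id = paste0("prom_", g$gene_id),
                     kind = "promoter", gene_id = g$gene_id,
                     chrom = g$chrom,
                     start = pmax(0L, g$tss - 1000L), end = g$tss + 1000L,
                     summit = g$tss, stringsAsFactors = FALSE)
  lg <- model$loop_genes
  enh <- data.frame(feature_id = paste0("enh_", lg$gene_id),
                    kind = "enhancer", gene_id = lg$gene_id,
                    chrom = lg$chrom1,
                    start = lg$enh_center - 500L, end = lg$enh_center + 500L,
                    summit = lg$enh_center, stringsAsFactors = FALSE)
  list(gene = data.frame(feature_id = g$gene_id, gene_id = g$gene_id,
                         stringsAsFactors = FALSE),
       chip = rbind(prom, enh))
}

#' Simulate strand-specific read tags
#'
#' Draws `depth` distinct fragments of length `fragment_length`; a fraction
#' `in_peak_frac` start inside the supplied enriched regions
#' (width-weighted), the rest are uniform background. The plus-strand tag
#' is the fragment's 5' start and the minus-strand tag is
#' `start + fragment_length - 1`. Distinct fragments are unique by
#' construction (the model of library complexity), and PCR duplicates are
#' then injected at rate `dup_rate`, so the downstream PCR bottleneck
#' coefficient is 1 exactly when `dup_rate = 0`.
#'
#' @param model a `genome_model`
#' @param enriched_regions data.frame chrom/start/end (0-based half-open)
#' @param depth number of distinct fragments
#' @param fragment_length fragment length (> read_length)
#' @param read_length read length in bp
#' @param in_peak_frac fraction of fragments from enriched regions
#' @param dup_rate duplicate injection rate in \[0, 1)
#' @param seed integer seed
#' @return an object of class `tag_set`: per-chromosome sorted `plus` and
#'   `minus` 5' positions plus `read_length` and `fragment_length`
#' @export
simulate_tags <- function(model, enriched_regions, depth = 50000,
                          fragment_length = 200, read_length = 50,
                          in_peak_frac = 0.5, dup_rate = 0.1, seed = 1) {
  if (fragment_length <= read_length)
    stop_fmt("fragment_length must exceed read_length")
  if (in_peak_frac > 0 && (is.null(enriched_regions) || nrow(enriched_regions) == 0))
    stop_fmt("in_peak_frac > 0 requires non-empty enriched_regions")
  with_seed(child_seed(seed, 3L), {
    chroms <- names(model$chrom_lengths)
    lens <- as.numeric(model$chrom_lengths)
    n_peak <- rbinom(1, depth, in_peak_frac)
    n_bg <- depth - n_peak
    frags <- data.frame(chrom = character(), start = integer())
    if (n_bg > 0) {
      ch <- sample(chroms, n_bg, replace = TRUE, prob = lens)
      st <- floor(runif(n_bg) * (model$chrom_lengths[ch] - fragment_length))
      frags <- rbind(frags, data.frame(chrom = ch, start = as.integer(st)))
    }
    if (n_peak > 0) {
      w <- enriched_regions$end - enriched_regions$start
      ri <- sample(nrow(enriched_regions), n_peak, replace = TRUE, prob = w)
      st <- enriched_regions$start[ri] +
        floor(runif(n_peak) * pmax(1, w[ri] - fragment_length))
      st <- pmax(0, pmin(st, model$chrom_lengths[enriched_regions$chrom[ri]] - fragment_length))
      frags <- rbind(frags, data.frame(chrom = enriched_regions$chrom[ri],
                                       start = as.integer(st)))
    }
    frags <- unique(frags)               # distinct-fragment library
    if (dup_rate > 0) {
      dup <- frags[runif(nrow(frags)) < dup_rate, , drop = FALSE]
      frags <- rbind(frags, dup)
    }
    tags <- setNames(lapply(chroms, function(ch) {
      st <- frags$start[frags$chrom == ch]
      list(plus = sort(st), minus = sort(st + fragment_length - 1L))
    }), chroms)
    structure(list(tags = tags, read_length = as.integer(read_length),
                   fragment_length = as.integer(fragment_length),
                   chrom_lengths = model$chrom_lengths),
              class = "tag_set")
  })
}

#' @export
print.tag_set <- function(x, ...) {
  n <- sum(vapply(x$tags, function(t) length(t$plus) + length(t$minus), numeric(1)))
  cat(sprintf("tag_set: %d tags on %d chromosomes (read %d bp, fragment %d bp)\n",
              n, length(x$tags), x$read_length, x$fragment_length))
  invisible(x)
}

#' Simulate per-pair difference scores with planted reversal structure
#'
#' Emulates the z-scored personalized-PageRank (or expression) pairwise
#' case-minus-control differences that the reversal classifier consumes.
#' `AF_reversed` features get a mean difference of `delta` in AF pairs
#' only; `AT_induced` in AT pairs only; `age_correlated` features get a
#' difference of `age_slope_score * (age - 50)`; nulls are pure noise with
#' standard deviation `noise_sd`.
#'
#' @param n_features total features (e.g. TFs)
#' @param n_pairs_af,n_pairs_at pairs per cohort
#' @param n_af_reversed,n_at_induced,n_age_correlated planted counts
#' @param delta planted mean pairwise difference (score units)
#' @param age_slope_score planted age slope (score units per year)
#' @param noise_sd per-pair noise standard deviation
#' @param seed integer seed
#' @return list with `af` and `at` (pairs x features delta matrices),
#'   `ages_af`, `ages_at`, and `truth`
#' @export
simulate_pairwise_scores <- function(n_features = 100, n_pairs_af = 15,
                                     n_pairs_at = 14, n_af_reversed = 0,
                                     n_at_induced = 0, n_age_correlated = 0,
                                     delta = 1.0, age_slope_score = 0.03,
                                     noise_sd = 0.25, seed = 1) {
  n_eff <- n_af_reversed + n_at_induced + n_age_correlated
  if (n_eff > n_features) stop_fmt("planted effects exceed n_features")
  with_seed(child_seed(seed, 4L), {
    ids <- sprintf("TF%03d", seq_len(n_features))
    cls <- rep("null", n_features)
    if (n_eff > 0) {
      pick <- sample(n_features, n_eff)
      cls[pick] <- rep(c("AF_reversed", "AT_induced", "age_correlated"),
                       c(n_af_reversed, n_at_induced, n_age_correlated))
    }
    sgn <- sample(c(-1, 1), n_features, replace = TRUE)
    ages_af <- round(runif(n_pairs_af, 20, 80), 1)
    ages_at <- round(runif(n_pairs_at, 20, 80), 1)
    mk <- function(n_pairs, ages, on_class) {
      m <- matrix(rnorm(n_pairs * n_features, sd = noise_sd), n_pairs, n_features,
                  dimnames = list(sprintf("P%02d", seq_len(n_pairs)), ids))
      shift <- ifelse(cls == on_class, delta * sgn, 0)
      m <- sweep(m, 2, shift, "+")
      agei <- which(cls == "age_correlated")
      for (f in agei) m[, f] <- m[, f] + age_slope_score * sgn[f] * (ages - 50)
      m
    }
    list(af = mk(n_pairs_af, ages_af, "AF_reversed"),
         at = mk(n_pairs_at, ages_at, "AT_induced"),
         ages_af = ages_af, ages_at = ages_at,
         truth = data.frame(feature_id = ids, effect_class = cls,
                            sign = sgn, stringsAsFactors = FALSE))
  })
}

#' Recovery metrics against planted truth
#'
#' For each effect class, sensitivity is the fraction of planted features
#' that were called with that class, and the false-classification rate is
#' the fraction of features NOT of that class that were nevertheless
#' called with it. Exact set arithmetic, no estimation.
#'
#' @param truth data.frame with `feature_id` and `effect_class`
#' @param called data.frame with `feature_id` and `effect_class`
#'   (non-null calls only, or with "null"/"neither" rows which are ignored)
#' @return data.frame per class: `class`, `n_true`, `n_called`,
#'   `sensitivity`, `false_rate`
#' @export
truth_report <- function(truth, called) {
  unknown <- setdiff(called$feature_id, truth$feature_id)
  if (length(unknown))
    stop_fmt("called features not in truth: %s", paste(head(unknown, 3), collapse = ", "))
  classes <- setdiff(unique(truth$effect_class), c("null", "neither"))
  out <- lapply(classes, function(cl) {
    truth_set <- truth$feature_id[truth$effect_class == cl]
    called_set <- called$feature_id[called$effect_class == cl]
    not_class <- setdiff(truth$feature_id, truth_set)
    data.frame(class = cl, n_true = length(truth_set), n_called = length(called_set),
               sensitivity = if (length(truth_set)) length(intersect(called_set, truth_set)) / length(truth_set) else NA_real_,
               false_rate = if (length(not_class)) length(setdiff(called_set, truth_set)) / length(not_class) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
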