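## Matched-pair cohort comparison: per-pair case-minus-control
## differences, AF/AT reversal classification, regulatee extraction from
## differential edge weights, cohort-specific DEG sets, and
## age-correlation of raw or pairwise values.

#' Per-pair case-minus-control differences
#'
#' @param values samples x features numeric matrix (rownames are sample
#'   ids)
#' @param pairs data.frame with `sample_id`, `pair_id`, `group` (one row
#'   per sample; both members of every pair present), optionally `age`
#' @return data.frame `pair_id`, `feature_id`, `delta`, and `age` when
#'   supplied
#' @export
pairwise_diff <- function(values, pairs) {
  pairs <- unique(pairs[, intersect(c("sample_id", "pair_id", "group", "age"), names(pairs))])
  missing <- setdiff(pairs$sample_id, rownames(values))
  if (length(missing))
    stop_fmt("values missing for sample(s): %s", paste(head(missing, 3), collapse = ", "))
  out <- list()
  for (p in unique(pairs$pair_id)) {
    rows <- pairs[pairs$pair_id == p, ]
    cs <- rows$sample_id[rows$group == "case"]
    ct <- rows$sample_id[rows$group == "control"]
    if (length(cs) != 1 || length(ct) != 1)
      stop_fmt("pair %s lacks a unique case/control sample", p)
    d <- values[cs, ] - values[ct, ]
    rec <- data.frame(pair_id = p, feature_id = colnames(values),
                      delta = as.numeric(d), stringsAsFactors = FALSE)
    if ("age" %in% names(rows)) rec$age <- rows$age[1]
    out[[p]] <- rec
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify features as treatment-recovered or treatment-induced
#'
#' For every feature, mean pairwise differences are computed separately
#' in the antipsychotic-free (AF) and antipsychotic-treated (AT) cohorts.
#' A feature whose AF and AT means differ by more than `threshold`
#' becomes a candidate: `recovered` when the AF alteration exceeds the AT
#' one (the alteration is present untreated and absent under treatment),
#' `treatment_induced` for the converse. Candidates are then tested with
#' a two-sided Wilcoxon signed-rank on the class-defining cohort's
#' pairwise differences against zero, BH-adjusted across candidates, and
#' demoted to `neither` unless `fdr < alpha`.
#'
#' @param af_deltas,at_deltas pairs x features matrices of pairwise
#'   differences (same feature columns)
#' @param threshold minimum |AF mean - AT mean| (default 0.5)
#' @param alpha FDR cutoff for candidate confirmation
#' @return data.frame `feature_id`, `af_mean_delta`, `at_mean_delta`,
#'   `class`, `fdr`
#' @export
classify_reversal <- function(af_deltas, at_deltas, threshold = 0.5,
                              alpha = 0.05) {
  if (!identical(colnames(af_deltas), colnames(at_deltas)))
    stop_fmt("AF and AT delta matrices must share feature columns")
  if (nrow(af_deltas) < 2 || nrow(at_deltas) < 2)
    stop_fmt("each cohort needs >= 2 pairs")
  af_mean <- colMeans(af_deltas)
  at_mean <- colMeans(at_deltas)
  diff <- af_mean - at_mean
  cand_class <- ifelse(abs(diff) > threshold,
                       ifelse(abs(af_mean) > abs(at_mean), "recovered", "treatment_induced"),
                       "neither")
  fdr <- rep(NA_real_, length(diff))
  ci <- which(cand_class != "neither")
  if (length(ci)) {
    pv <- vapply(ci, function(i) {
      m <- if (cand_class[i] == "recovered") af_deltas[, i] else at_deltas[, i]
      suppressWarnings(wilcox.test(m, mu = 0, exact = FALSE)$p.value)
    }, numeric(1))
    fdr[ci] <- bh_adjust(pv)
    demote <- ci[fdr[ci] >= alpha]
    cand_class[demote] <- "neither"
  }
  data.frame(feature_id = colnames(af_deltas),
             af_mean_delta = unname(af_mean), at_mean_delta = unname(at_mean),
             class = unname(cand_class), fdr = unname(fdr),
             stringsAsFactors = FALSE)
}

#' Dysregulated regulatees shared by the top TFs
#'
#' For each of the `top_tfs`, a gene counts as a dysregulated regulatee
#' when (i) the tf -> gene edge exists in the per-sample networks,
#' (ii) its paired edge-weight differences differ from zero (Wilcoxon
#' signed-rank, BH-adjusted below `alpha` across that TF's edges), and
#' (iii) the gene is differentially expressed. The returned set contains
#' genes that are regulatees of at least `min_tf_count` of the top TFs.
#'
#' @param networks named list (by sample id) of `reg_network`
#' @param top_tfs character vector of TF ids
#' @param degs `DifferentialResult` data.frame for gene expression
#' @param pairs sample sheet subset (`sample_id`, `pair_id`, `group`)
#' @param min_tf_count minimum number of top TFs regulating the gene
#' @param alpha edge-weight FDR cutoff
#' @return character vector of regulatee gene ids
#' @export
extract_regulatees <- function(networks, top_tfs, degs, pairs,
                               min_tf_count = 3L, alpha = 0.05) {
  if (min_tf_count > length(top_tfs))
    stop_fmt("min_tf_count (%d) exceeds number of top TFs (%d)",
             min_tf_count, length(top_tfs))
  deg_set <- degs$feature_id[degs$significant]
  if (!length(deg_set)) return(character())
  counts <- list()
  for (tf in top_tfs) {
    ## edge-weight matrix samples x genes for this TF (0 when absent)
    genes <- unique(unlist(lapply(networks, function(nw) nw$edges$gene[nw$edges$tf == tf])))
    genes <- intersect(genes, deg_set)
    if (!length(genes)) next
    m <- t(vapply(networks, function(nw) {
      e <- nw$edges[nw$edges$tf == tf, ]
      setNames(e$weight[match(genes, e$gene)], genes)
    }, numeric(length(genes))))
    if (length(genes) == 1) {
      m <- matrix(m, ncol = 1, dimnames = list(names(networks), genes))
    } else rownames(m) <- names(networks)
    m[is.na(m)] <- 0
    d <- pairwise_diff(m, pairs)
    pv <- vapply(genes, function(g) {
      x <- d$delta[d$feature_id == g]
      if (all(x == 0)) return(1)
      suppressWarnings(wilcox.test(x, mu = 0, exact = FALSE)$p.value)
    }, numeric(1))
    fdr <- bh_adjust(pv)
    counts[[tf]] <- genes[fdr < alpha]
  }
  tab <- table(unlist(counts))
  sort(names(tab)[tab >= min_tf_count])
}

#' Cohort-specific and shared significant feature sets
#'
#' @param af_results,at_results `DifferentialResult` data.frames over the
#'   same feature universe
#' @param alpha significance cutoff on the adjusted p-value
#' @return list of character vectors: `af_only`, `at_only`, `shared`
#' @export
cohort_specific_sets <- function(af_results, at_results, alpha = 0.05) {
  if (!setequal(af_results$feature_id, at_results$feature_id)) {
    miss <- union(setdiff(af_results$feature_id, at_results$feature_id),
                  setdiff(at_results$feature_id, af_results$feature_id))
    stop_fmt("feature universes differ; e.g.: %s", paste(head(miss, 5), collapse = ", "))
  }
  af_sig <- af_results$feature_id[af_results$p_adj < alpha]
  at_sig <- at_results$feature_id[at_results$p_adj < alpha]
  list(af_only = sort(setdiff(af_sig, at_sig)),
       at_only = sort(setdiff(at_sig, af_sig)),
       shared = sort(intersect(af_sig, at_sig)))
}

#' Pearson age correlation with t-distribution p-values
#'
#' Per feature, the Pearson correlation r between the feature's values
#' (raw expression or pairwise case-minus-control differences) and age,
#' with the two-sided p-value from `t = r * sqrt((n - 2) / (1 - r^2))` on
#' a t-distribution with n - 2 degrees of freedom. Zero-variance features
#' are skipped with a warning.
#'
#' @param values samples-or-pairs x features matrix
#' @param ages numeric vector aligned to rows of `values`
#' @return data.frame `feature_id`, `r`, `p`, `n`
#' @export
age_correlation <- function(values, ages) {
  if (nrow(values) != length(ages)) stop_fmt("ages must align with rows of values")
  if (nrow(values) < 3) stop_fmt("need n >= 3")
  skipped <- character()
  out <- lapply(colnames(values), function(f) {
    x <- values[, f]
    if (sd(x) == 0 || sd(ages) == 0) {
      skipped <<- c(skipped, f)
      return(NULL)
    }
    n <- length(x)
    r <- cor(x, ages)
    tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    data.frame(feature_id = f, r = r, p = 2 * pt(-abs(tstat), df = n - 2),
               n = n, stringsAsFactors = FALSE)
  })
  if (length(skipped))
    warning(sprintf("skipped zero-variance feature(s): %s",
                    paste(head(skipped, 5), collapse = ", ")), call. = FALSE)
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(feature_id = character(), r = numeric(),
                                      p = numeric(), n = integer())
  rownames(res) <- NULL
  res
}

#' Age-correlated feature selection with sign summary
#'
#' Features with `|r| >= r_threshold` (inclusive, matching the printed
#' ">= 0.50" / ">= 0.60" rules) plus counts and sign fractions.
#'
#' @param correlations output of [age_correlation()]
#' @param r_threshold absolute-correlation threshold in (0, 1)
#' @return list: `features` (subset of `correlations`), `summary`
#'   (n_selected, n_positive, n_negative, frac_positive, frac_negative)
#' @export
age_correlated_features <- function(correlations, r_threshold) {
  if (r_threshold <= 0 || r_threshold >= 1)
    stop_fmt("r_threshold must lie in (0, 1)")
  sel <- correlations[abs(correlations$r) >= r_threshold, , drop = FALSE]
  n <- nrow(sel)
  np <- sum(sel$r > 0); nn <- sum(sel$r < 0)
  list(features = sel,
       summary = data.frame(n_selected = n, n_positive = np, n_negative = nn,
                            frac_positive = if (n) np / n else NA_real_,
                            frac_negative = if (n) nn / n else NA_real_))
}
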