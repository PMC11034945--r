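## Consensus-peak construction and the count pipeline: a minimal
## Poisson-background peak caller (a documented stand-in for MACS2 at
## synthetic scale), replicate high-confidence peaks, the cross-sample
## master set, count-matrix assembly with input subtraction, TMM
## normalization, the low-count filter, and PC-guided covariate
## regression.

#' Minimal Poisson-background peak caller
#'
#' Per position (or bin), an upper-tail Poisson p-value is computed
#' against the maximum of the global mean coverage and the local mean in a
#' +/-5 kb window; p-values are BH-adjusted genome-wide and positions
#' with q below the cutoff are merged into peaks when separated by at
#' most 100 bp. The summit is the position of maximum coverage within the
#' merged region. This is a deliberately small stand-in for MACS2 used on
#' synthetic coverage; it is not a reimplementation of MACS2.
#'
#' @param coverage named list (per chromosome) of non-negative coverage
#'   vectors; element i covers positions `(i-1)*bin_width .. i*bin_width-1`
#' @param background_lambda numeric background rate, or `"global"` to use
#'   the genome-wide mean
#' @param q_cutoff BH q-value cutoff (the MACS2 default 0.05)
#' @param bin_width width in bp represented by one coverage element
#' @param local_halfwidth local-background half window in bp
#' @param merge_gap maximum gap in bp between merged significant bins
#' @return data.frame of peaks: chrom, start, end, summit (absolute bp),
#'   score (-log10 q at the summit), q
#' @export
call_peaks_poisson <- function(coverage, background_lambda = "global",
                               q_cutoff = 0.05, bin_width = 1L,
                               local_halfwidth = 5000L, merge_gap = 100L) {
  if (any(unlist(coverage) < 0)) stop_fmt("coverage must be non-negative")
  all_vals <- unlist(coverage, use.names = FALSE)
  if (!length(all_vals) || all(all_vals == 0))
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      summit = integer(), score = numeric(), q = numeric()))
  global_mean <- if (identical(background_lambda, "global")) mean(all_vals)
                 else as.numeric(background_lambda)
  half_bins <- max(1L, as.integer(local_halfwidth %/% bin_width))
  pvals <- lapply(coverage, function(v) {
    n <- length(v)
    ## centered running mean over +/- half_bins via cumulative sums
    cs <- cumsum(c(0, v))
    lo <- pmax(seq_len(n) - half_bins, 1L)
    hi <- pmin(seq_len(n) + half_bins, n)
    local_mean <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
    lambda <- pmax(global_mean, local_mean)
    ppois(v - 1, lambda, lower.tail = FALSE)
  })
  q <- stats::p.adjust(unlist(pvals, use.names = FALSE), method = "BH")
  offs <- cumsum(c(0, vapply(coverage, length, numeric(1))))
  out <- list()
  for (ci in seq_along(coverage)) {
    v <- coverage[[ci]]
    qc <- q[(offs[ci] + 1):offs[ci + 1]]
    sig <- which(qc < q_cutoff)
    if (!length(sig)) next
    gap_bins <- max(1L, as.integer(ceiling(merge_gap / bin_width)))
    brk <- c(0, which(diff(sig) > gap_bins), length(sig))
    for (k in seq_len(length(brk) - 1)) {
      idx <- sig[(brk[k] + 1):brk[k + 1]]
      s_bin <- idx[which.max(v[idx])]
      out[[length(out) + 1]] <- data.frame(
        chrom = names(coverage)[ci],
        start = as.integer((idx[1] - 1L) * bin_width),
        end = as.integer(idx[length(idx)] * bin_width),
        summit = as.integer((s_bin - 1L) * bin_width + bin_width %/% 2L),
        score = -log10(max(qc[s_bin], 1e-300)),
        q = qc[s_bin], stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(call_peaks_poisson(list(), q_cutoff = q_cutoff))
  do.call(rbind, out)
}

#' High-confidence peaks supported by both technical replicates
#'
#' Every rep1/rep2 peak pair overlapping by at least 1 bp contributes the
#' union of the two intervals; overlap chains are merged transitively.
#' Peaks present in only one replicate are dropped. The summit of a merged
#' peak is taken from the highest-scoring contributing source peak.
#'
#' @param rep1,rep2 peak data.frames (chrom/start/end, optional
#'   summit/score)
#' @return merged high-confidence peak data.frame
#' @export
high_confidence_peaks <- function(rep1, rep2) {
  if (nrow(rep1) == 0 || nrow(rep2) == 0)
    return(rep1[0, intersect(names(rep1), c("chrom", "start", "end", "summit", "score")), drop = FALSE])
  g1 <- as_granges(rep1); g2 <- as_granges(rep2)
  ov <- GenomicRanges::findOverlaps(g1, g2)
  if (!length(ov)) return(rep1[0, , drop = FALSE])
  pieces <- GenomicRanges::punion(g1[S4Vectors::queryHits(ov)],
                                  g2[S4Vectors::subjectHits(ov)], fill.gap = TRUE)
  merged <- GenomicRanges::reduce(pieces)
  df <- granges_to_df(merged)
  ## summit/score from the best supporting source peak
  src <- rbind(peak_core(rep1), peak_core(rep2))
  annotate_summits(df, src)
}

peak_core <- function(p) {
  data.frame(chrom = p$chrom, start = p$start, end = p$end,
             summit = if ("summit" %in% names(p)) p$summit
                      else p$start + (p$end - p$start) %/% 2L,
             score = if ("score" %in% names(p)) p$score else 0,
             stringsAsFactors = FALSE)
}

annotate_summits <- function(merged, src) {
  gm <- as_granges(merged); gs <- as_granges(src)
  ov <- GenomicRanges::findOverlaps(gm, gs)
  merged$summit <- merged$start + (merged$end - merged$start) %/% 2L
  merged$score <- 0
  if (length(ov)) {
    byq <- split(S4Vectors::subjectHits(ov), S4Vectors::queryHits(ov))
    for (qi in names(byq)) {
      cand <- byq[[qi]]
      best <- cand[which.max(src$score[cand])]
      i <- as.integer(qi)
      merged$summit[i] <- src$summit[best]
      merged$score[i] <- src$score[best]
    }
  }
  merged$summit <- pmin(pmax(merged$summit, merged$start), merged$end - 1L)
  merged
}

#' Master consensus peak set across samples
#'
#' Union-merge of all per-sample high-confidence peak sets: intervals
#' overlapping by at least 1 bp are chained transitively into one master
#' peak. Each master peak records the number of contributing samples.
#'
#' @param per_sample list of peak data.frames (one per sample)
#' @return master peak data.frame with `n_samples` support column
#' @export
consensus_master <- function(per_sample) {
  if (!length(per_sample)) stop_fmt("need at least one sample peak set")
  nonempty <- per_sample[vapply(per_sample, nrow, numeric(1)) > 0]
  if (!length(nonempty))
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      summit = integer(), score = numeric(), n_samples = integer()))
  all_gr <- as_granges(do.call(rbind, lapply(nonempty, function(p) p[, c("chrom", "start", "end")])))
  merged <- granges_to_df(GenomicRanges::reduce(all_gr))
  src <- do.call(rbind, lapply(nonempty, peak_core))
  merged <- annotate_summits(merged, src)
  gm <- as_granges(merged)
  support <- Reduce(`+`, lapply(nonempty, function(p) {
    as.integer(GenomicRanges::countOverlaps(gm, as_granges(p)) > 0)
  }))
  merged$n_samples <- support
  merged$name <- sprintf("master_%d", seq_len(nrow(merged)))
  merged
}

#' Count matrix over a master peak set
#'
#' With an input control, the per-peak count is
#' `max(ChIP - input, min_count)` (background subtraction with a floor, as
#' in TMM-minus-full scoring); without one, raw ChIP counts are used.
#' Library sizes are the full library totals, not the in-peak totals.
#'
#' @param chip_counts features x samples matrix of in-peak ChIP counts
#'   (rows follow `master`)
#' @param master master peak data.frame (non-overlapping)
#' @param input_counts optional matrix of matching input-control counts
#' @param library_sizes named full library totals per sample
#' @param min_count floor after input subtraction
#' @return a `count_matrix`
#' @export
build_count_matrix <- function(chip_counts, master, input_counts = NULL,
                               library_sizes = NULL, min_count = 1L) {
  chip_counts <- as.matrix(chip_counts)
  if (nrow(chip_counts) != nrow(master))
    stop_fmt("counts rows (%d) do not match master peaks (%d)",
             nrow(chip_counts), nrow(master))
  if (is.null(rownames(chip_counts)))
    rownames(chip_counts) <- master$name %||% sprintf("master_%d", seq_len(nrow(master)))
  m <- chip_counts
  if (!is.null(input_counts)) {
    input_counts <- as.matrix(input_counts)
    if (!identical(dim(input_counts), dim(chip_counts)))
      stop_fmt("input_counts dimensions do not match chip_counts")
    m <- pmax(chip_counts - input_counts, min_count)
  }
  if (is.null(library_sizes)) library_sizes <- colSums(chip_counts)
  count_matrix(m, library_sizes = pmax(library_sizes, colSums(m)))
}

#' Count tags over intervals
#'
#' @param tags a `tag_set`
#' @param intervals data.frame chrom/start/end
#' @return integer vector of per-interval tag counts (both strands)
#' @export
count_tags_in_intervals <- function(tags, intervals) {
  out <- integer(nrow(intervals))
  for (ch in unique(intervals$chrom)) {
    sel <- which(intervals$chrom == ch)
    t <- tags$tags[[ch]]
    if (is.null(t)) next
    pos <- sort(c(t$plus, t$minus))
    out[sel] <- findInterval(intervals$end[sel] - 1L, pos) -
      findInterval(intervals$start[sel] - 1L, pos)
  }
  out
}

## --- TMM normalization ----------------------------------------------------

#' Trimmed mean of M-values normalization factors
#'
#' Composition-robust between-sample normalization for count libraries.
#' The reference sample is the column whose 75th-percentile
#' (library-size-scaled) count is closest to the mean of those
#' percentiles. For every other sample, log2 ratios M and average
#' log-intensities A are computed over features with nonzero counts in
#' both columns, doubly trimmed (default 30% on M, 5% on A), and averaged
#' with inverse asymptotic-variance weights. Factors are rescaled so their
#' geometric mean is 1.
#'
#' @param cm a `count_matrix` (>= 2 samples, no all-zero column)
#' @param trim_m two-sided trim fraction on M values
#' @param trim_a two-sided trim fraction on A values
#' @return named vector of normalization factors (geometric mean 1)
#' @export
tmm_factors <- function(cm, trim_m = 0.30, trim_a = 0.05) {
  x <- cm$counts
  if (ncol(x) < 2) stop_fmt("TMM needs >= 2 samples")
  if (any(colSums(x) == 0)) stop_fmt("TMM undefined for an all-zero column")
  lib <- as.numeric(cm$library_sizes)
  q75 <- vapply(seq_len(ncol(x)), function(j) quantile(x[, j], 0.75) / lib[j], numeric(1))
  ref <- which.min(abs(q75 - mean(q75)))
  f <- vapply(seq_len(ncol(x)), function(j) {
    if (j == ref) return(1)
    tmm_pair(x[, j], x[, ref], lib[j], lib[ref], trim_m, trim_a)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(x))
}

tmm_pair <- function(obs, ref, n_obs, n_ref, trim_m, trim_a) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  if (!length(obs)) return(1)
  p_obs <- obs / n_obs; p_ref <- ref / n_ref
  M <- log2(p_obs / p_ref)
  A <- 0.5 * log2(p_obs * p_ref)
  fin <- is.finite(M) & is.finite(A)
  M <- M[fin]; A <- A[fin]
  if (!length(M) || max(abs(M)) < 1e-6) return(1)
  ## binomial asymptotic variance of M
  v <- (n_obs - obs[fin]) / (n_obs * obs[fin]) + (n_ref - ref[fin]) / (n_ref * ref[fin])
  n <- length(M)
  loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
  loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
  rM <- rank(M); rA <- rank(A)
  keep2 <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(keep2)) return(1)
  2^(sum(M[keep2] / v[keep2]) / sum(1 / v[keep2]))
}

#' Attach TMM factors to a count matrix
#' @param cm a `count_matrix`
#' @param ... passed to [tmm_factors()]
#' @return the `count_matrix` with `tmm_factors` set
#' @export
tmm_normalize <- function(cm, ...) {
  cm$tmm_factors <- tmm_factors(cm, ...)
  cm
}

#' Normalized log2 counts-per-million view
#'
#' log2(CPM + 0.5) using effective library sizes
#' `library_size * tmm_factor`.
#' @param cm a TMM-normalized `count_matrix`
#' @return numeric matrix, features x samples
#' @export
normalized_log <- function(cm) {
  f <- cm$tmm_factors %||% setNames(rep(1, ncol(cm$counts)), colnames(cm$counts))
  eff <- as.numeric(cm$library_sizes) * as.numeric(f[colnames(cm$counts)])
  log2(sweep(cm$counts, 2, eff / 1e6, "/") + 0.5)
}

#' Remove features with low counts in too many samples
#'
#' A feature is removed iff the number of samples with count below
#' `min_count` exceeds `frac` of the samples — the literal reading of
#' "fewer than 20 reads in over 50% of the samples". The inequality is
#' strict: a feature low in exactly half the samples is kept.
#'
#' @param cm a `count_matrix`
#' @param min_count count threshold (default 20)
#' @param frac sample-fraction threshold (default 0.5)
#' @return filtered `count_matrix` (feature order preserved)
#' @export
filter_low <- function(cm, min_count = 20L, frac = 0.5) {
  n_low <- rowSums(cm$counts < min_count)
  keep <- n_low <= frac * ncol(cm$counts)
  count_matrix(cm$counts[keep, , drop = FALSE],
               library_sizes = cm$library_sizes,
               tmm_factors = cm$tmm_factors)
}

## --- PC-guided covariate handling ----------------------------------------

encode_covariates <- function(covariates) {
  out <- list(); dropped <- character()
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    if (!is.numeric(v)) {
      lev <- sort(unique(as.character(v)))
      if (length(lev) == 1) { dropped <- c(dropped, nm); next }
      if (length(lev) == 2) {
        v <- as.numeric(as.character(v) == lev[2])
      } else {
        for (l in lev[-1]) out[[paste(nm, l, sep = "_")]] <- as.numeric(as.character(covariates[[nm]]) == l)
        next
      }
    }
    if (var(v) == 0) { dropped <- c(dropped, nm); next }
    out[[nm]] <- v
  }
  if (length(dropped))
    warning(sprintf("excluded zero-variance covariate(s): %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)
  as.data.frame(out, optional = TRUE)
}

#' Select covariates correlated with top principal components
#'
#' Principal components of the feature-centered log-scale matrix are
#' computed over samples; a covariate is selected when any of the top
#' `n_pcs` PCs correlates with it at `|r| >= r_cut` and `p <= p_cut`.
#' Zero-variance covariates are excluded with a warning.
#'
#' @param normalized features x samples numeric matrix (e.g.
#'   [normalized_log()])
#' @param covariates per-sample data.frame (numeric, factors are
#'   binary/dummy encoded)
#' @param n_pcs number of leading PCs examined
#' @param r_cut,p_cut selection thresholds
#' @return character vector of selected covariate names
#' @export
pc_covariate_select <- function(normalized, covariates, n_pcs = 6L,
                                r_cut = 0.3, p_cut = 0.05) {
  if (ncol(normalized) <= n_pcs)
    stop_fmt("need more samples (%d) than PCs (%d)", ncol(normalized), n_pcs)
  enc <- encode_covariates(covariates)
  if (!ncol(enc)) return(character())
  centered <- normalized - rowMeans(normalized)
  pc <- prcomp(t(centered), center = FALSE, scale. = FALSE)
  k <- min(n_pcs, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  sel <- vapply(names(enc), function(nm) {
    any(vapply(seq_len(k), function(i) {
      ct <- stats::cor.test(scores[, i], enc[[nm]])
      abs(ct$estimate) >= r_cut && ct$p.value <= p_cut
    }, logical(1)))
  }, logical(1))
  names(enc)[sel]
}

#' Regress covariates out of a normalized matrix
#'
#' Per feature, ordinary least-squares residuals against the covariate
#' design (with intercept), plus the feature mean so the location is
#' preserved. Residuals are orthogonal to every covariate column.
#'
#' @param normalized features x samples numeric matrix
#' @param covariates per-sample data.frame of covariates to remove
#' @return residualized matrix of the same shape
#' @export
regress_out <- function(normalized, covariates) {
  enc <- encode_covariates(covariates)
  if (!ncol(enc)) return(normalized)
  X <- cbind(intercept = 1, as.matrix(enc))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop_fmt("rank-deficient covariate design; collinear column(s): %s",
             paste(bad, collapse = ", "))
  }
  fitted <- t(qr.fitted(qrX, t(normalized)))
  res <- normalized - fitted
  res + rowMeans(normalized)
}
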