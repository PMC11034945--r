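## ENCODE-style ChIP-seq quality metrics on tag sets: FRiP, PBC (PBC1),
## strand cross-correlation with NSC/RSC and fragment-length estimation,
## saturation curves, replicate correlation, and the ChIP-qPCR enrichment
## formula.

n_tags_total <- function(tags) {
  sum(vapply(tags$tags, function(t) length(t$plus) + length(t$minus), numeric(1)))
}

#' Fraction of reads in peaks (FRiP)
#'
#' Counts tag 5' positions (both strands) falling inside any peak interval
#' and divides by the total tag count. Peaks are merged first so
#' overlapping intervals are not double-counted.
#'
#' @param tags a `tag_set`
#' @param peaks data.frame chrom/start/end (0-based half-open)
#' @return fraction in \[0, 1\]
#' @export
frip <- function(tags, peaks) {
  total <- n_tags_total(tags)
  if (total == 0) stop_fmt("FRiP undefined on an empty tag set")
  if (is.null(peaks) || nrow(peaks) == 0) return(0)
  merged <- granges_to_df(GenomicRanges::reduce(as_granges(peaks)))
  inside <- 0
  for (ch in names(tags$tags)) {
    p <- merged[merged$chrom == ch, , drop = FALSE]
    if (nrow(p) == 0) next
    for (strand in c("plus", "minus")) {
      pos <- tags$tags[[ch]][[strand]]
      if (!length(pos)) next
      ## position x is inside [start, end) iff the latest start <= x has end > x
      i <- findInterval(pos, p$start)
      hit <- i > 0 & pos < p$end[pmax(i, 1)]
      inside <- inside + sum(hit)
    }
  }
  inside / total
}

#' PCR bottleneck coefficient (PBC1)
#'
#' The unit is the strand-specific genomic position: PBC1 is the number of
#' positions covered by exactly one tag divided by the number of distinct
#' positions.
#'
#' @param tags a `tag_set`
#' @return fraction in \[0, 1\]
#' @export
pbc <- function(tags) {
  if (n_tags_total(tags) == 0) stop_fmt("PBC undefined on an empty tag set")
  strand_keys <- function(ch, s, pos) {
    if (!length(pos)) return(character())  # paste0 ignores length-0 inputs
    paste0(ch, s, pos)
  }
  keys <- unlist(lapply(names(tags$tags), function(ch) {
    c(strand_keys(ch, "+", tags$tags[[ch]]$plus),
      strand_keys(ch, "-", tags$tags[[ch]]$minus))
  }))
  tab <- table(keys)
  sum(tab == 1) / length(tab)
}

## binarized per-base coverage of tag 5' positions on one chromosome
binary_coverage <- function(pos, len) {
  v <- logical(len)
  v[unique(pos[pos >= 0 & pos < len]) + 1L] <- TRUE
  v
}

pearson_shift <- function(x, y, d) {
  ## cor(x[1:(L-d)], y[(1+d):L]) without copying via running sums
  L <- length(x)
  n <- L - d
  xs <- x[seq_len(n)]; ys <- y[d + seq_len(n)]
  sx <- sum(xs); sy <- sum(ys)
  sxx <- sum(xs); syy <- sum(ys)            # binary: x^2 == x
  sxy <- sum(xs & ys)
  num <- sxy - sx * sy / n
  den <- sqrt((sxx - sx^2 / n) * (syy - sy^2 / n))
  if (den == 0) return(NA_real_)
  num / den
}

#' Strand cross-correlation profile with NSC, RSC and fragment length
#'
#' For each shift d the Pearson correlation between the binarized
#' plus-strand 5'-position coverage and the minus-strand coverage shifted
#' upstream by d is computed per chromosome and averaged with
#' chromosome-length weights. The fragment length estimate is the argmax
#' of the profile outside a +/-10 bp phantom window around the read
#' length; NSC = cc(fragment)/min(cc) and
#' RSC = (cc(fragment) - min(cc)) / (cc(read_length) - min(cc)).
#' Quality thresholds in common use are NSC >= 1.05 and RSC >= 1.0.
#'
#' @param tags a `tag_set`
#' @param max_shift largest shift evaluated (> read length)
#' @return list: `profile` (data.frame shift, cc), `fragment_length_est`,
#'   `nsc`, `rsc`
#' @export
cross_correlation <- function(tags, max_shift = 400) {
  if (max_shift <= tags$read_length)
    stop_fmt("max_shift must exceed the read length")
  shifts <- 0:max_shift
  chroms <- names(tags$tags)
  covs <- lapply(chroms, function(ch) {
    len <- tags$chrom_lengths[[ch]]
    list(p = binary_coverage(tags$tags[[ch]]$plus, len),
         m = binary_coverage(tags$tags[[ch]]$minus, len),
         len = len)
  })
  if (all(vapply(covs, function(cv) !any(cv$p) || !any(cv$m), logical(1))))
    stop_fmt("cross-correlation undefined: all-zero coverage")
  w <- vapply(covs, function(cv) cv$len, numeric(1))
  cc <- vapply(shifts, function(d) {
    vals <- vapply(covs, function(cv) pearson_shift(cv$p, cv$m, d), numeric(1))
    ok <- is.finite(vals)
    if (!any(ok)) return(NA_real_)
    sum(vals[ok] * w[ok]) / sum(w[ok])
  }, numeric(1))
  profile <- data.frame(shift = shifts, cc = cc)
  phantom <- abs(shifts - tags$read_length) <= 10
  cand <- which(!phantom & is.finite(cc))
  frag_i <- cand[which.max(cc[cand])]
  frag_est <- shifts[frag_i]
  cc_min <- min(cc, na.rm = TRUE)
  cc_frag <- cc[frag_i]
  cc_read <- cc[shifts == tags$read_length]
  nsc <- cc_frag / cc_min
  rsc <- (cc_frag - cc_min) / (cc_read - cc_min)
  list(profile = profile, fragment_length_est = frag_est,
       nsc = nsc, rsc = rsc)
}

#' Peak-count saturation curve under tag subsampling
#'
#' Subsamples the tag set without replacement at each fraction, reruns the
#' supplied peak-calling function, and reports the peak count. At fraction
#' 1.0 the full tag set is used unchanged, so that point is
#' seed-independent.
#'
#' @param tags a `tag_set`
#' @param fractions increasing fractions in (0, 1]
#' @param caller function(tag_set) -> peak data.frame
#' @param seed integer seed for the subsampling
#' @return data.frame with `fraction` and `n_peaks`
#' @export
saturation_curve <- function(tags, fractions, caller, seed = 1) {
  if (any(fractions <= 0 | fractions > 1)) stop_fmt("fractions must lie in (0, 1]")
  if (is.unsorted(fractions, strictly = TRUE)) stop_fmt("fractions must be strictly increasing")
  res <- vapply(seq_along(fractions), function(i) {
    f <- fractions[i]
    sub <- if (f == 1) tags else subsample_tags(tags, f, child_seed(seed, 100L + i))
    nrow(caller(sub))
  }, numeric(1))
  data.frame(fraction = fractions, n_peaks = res)
}

subsample_tags <- function(tags, fraction, seed) {
  with_seed(seed, {
    out <- tags
    for (ch in names(tags$tags)) {
      for (s in c("plus", "minus")) {
        pos <- tags$tags[[ch]][[s]]
        k <- round(length(pos) * fraction)
        out$tags[[ch]][[s]] <- sort(pos[sample(length(pos), k)])
      }
    }
    out
  })
}

#' Pearson correlation between technical replicates
#'
#' Computed on log1p-transformed counts over the consensus features.
#' @param counts_rep1,counts_rep2 equal-length non-negative count vectors
#' @return Pearson correlation
#' @export
replicate_correlation <- function(counts_rep1, counts_rep2) {
  if (length(counts_rep1) != length(counts_rep2) || length(counts_rep1) < 3)
    stop_fmt("replicate vectors must have equal length >= 3")
  x <- log1p(counts_rep1); y <- log1p(counts_rep2)
  if (sd(x) == 0 || sd(y) == 0) stop_fmt("zero variance in a replicate vector")
  cor(x, y)
}

#' ChIP-qPCR fold enrichment
#'
#' Relative fold enrichment of a positive-region primer (P) against the
#' common negative primer (N): `2^(Cq(N) - Cq(P))`.
#' @param cq_negative,cq_positive quantification cycles
#' @return fold enrichment
#' @export
qpcr_enrichment <- function(cq_negative, cq_positive) {
  if (!all(is.finite(c(cq_negative, cq_positive))))
    stop_fmt("Cq values must be finite")
  2^(cq_negative - cq_positive)
}

#' Assemble a QC record for one sample
#'
#' @param sample_id identifier
#' @param tags a `tag_set`
#' @param peaks called peaks for FRiP
#' @param max_shift cross-correlation shift range
#' @param replicate_counts optional list of two replicate count vectors
#' @return one-row data.frame of QC metrics
#' @export
qc_record <- function(sample_id, tags, peaks, max_shift = 400,
                      replicate_counts = NULL) {
  cc <- cross_correlation(tags, max_shift)
  data.frame(
    sample_id = sample_id,
    n_tags = n_tags_total(tags),
    frip = frip(tags, peaks),
    pbc = pbc(tags),
    nsc = cc$nsc, rsc = cc$rsc,
    fragment_length_est = cc$fragment_length_est,
    replicate_pearson = if (is.null(replicate_counts)) NA_real_
      else replicate_correlation(replicate_counts[[1]], replicate_counts[[2]]),
    stringsAsFactors = FALSE)
}
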