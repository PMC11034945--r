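## Negative-binomial differential testing with TMM offsets, multiple-test
## adjustment, enhancer/promoter classification, enhancer-gene linking
## (chromatin loops with nearest-gene fallback), GREAT-style basal-plus-
## extension region-gene mapping, exact hypergeometric overlap tests, and
## the QQ genomic-inflation lambda.

#' Negative-binomial Wald test per feature
#'
#' Fits, per feature, an NB log-linear model
#' `count ~ group + covariates + offset(log(library_size * tmm_factor))`.
#' The dispersion is estimated per feature by maximum likelihood, then
#' shrunk halfway (weight 0.5) toward a mean-dispersion trend fitted
#' across features; the model is refit at the shrunk dispersion and the
#' group coefficient is assessed with a Wald z test. This is a documented
#' NB-Wald equivalent of the external differential packages the design is
#' modeled on, not a numerical clone of them.
#'
#' @param cm a filtered, TMM-normalized `count_matrix`
#' @param group factor/character per sample with levels control, case
#'   (log2 fold change is case vs control)
#' @param covariates optional per-sample data.frame regressed within the
#'   GLM
#' @param adjust_method `"bonferroni"` (ChIP convention here) or `"bh"`
#'   (FDR, RNA convention)
#' @param alpha significance level applied to the adjusted p-value
#' @return data.frame of per-feature results: `feature_id`,
#'   `baseline_mean`, `log2_fc`, `p`, `p_adj`, `adjust_method`,
#'   `significant`
#' @export
nb_differential <- function(cm, group, covariates = NULL,
                            adjust_method = c("bonferroni", "bh"),
                            alpha = 0.05) {
  adjust_method <- match.arg(adjust_method)
  x <- cm$counts
  if (any(x != floor(x))) stop_fmt("counts must be integers")
  group <- as.character(group)
  if (!all(group %in% c("case", "control"))) stop_fmt("group must be case/control")
  if (min(table(group)) < 2) stop_fmt("each group needs >= 2 samples")
  f <- cm$tmm_factors %||% setNames(rep(1, ncol(x)), colnames(x))
  offs <- log(as.numeric(cm$library_sizes) * as.numeric(f[colnames(x)]))
  design <- data.frame(group_case = as.numeric(group == "case"))
  if (!is.null(covariates)) {
    enc <- encode_covariates(covariates)
    for (nm in names(enc)) design[[nm]] <- enc[[nm]]
  }
  X <- cbind(`(Intercept)` = 1, as.matrix(design))

  fits <- lapply(seq_len(nrow(x)), function(i) nb_fit_ml(x[i, ], X, offs))
  alpha_ml <- vapply(fits, `[[`, numeric(1), "alpha")
  mean_norm <- vapply(seq_len(nrow(x)), function(i) mean(x[i, ] / exp(offs)) * exp(mean(offs)), numeric(1))
  alpha_trend <- dispersion_trend(mean_norm, alpha_ml)
  alpha_shrunk <- 0.5 * alpha_ml + 0.5 * alpha_trend

  res <- lapply(seq_len(nrow(x)), function(i) {
    nb_wald(x[i, ], X, offs, alpha_shrunk[i])
  })
  p <- vapply(res, `[[`, numeric(1), "p")
  lfc <- vapply(res, `[[`, numeric(1), "log2_fc")
  ## degenerate fits (e.g. all-identical counts) are reported as p = 1
  p[!is.finite(p)] <- 1
  p_adj <- if (adjust_method == "bonferroni") pmin(p * length(p), 1) else bh_adjust(p)
  data.frame(feature_id = rownames(x), baseline_mean = mean_norm,
             log2_fc = lfc, p = p, p_adj = p_adj,
             adjust_method = adjust_method, significant = p_adj < alpha,
             stringsAsFactors = FALSE)
}

## Per-feature NB fit with ML dispersion via MASS::glm.nb; Poisson-like
## fallback (tiny dispersion) when the ML fit degenerates.
nb_fit_ml <- function(y, X, offs) {
  df <- as.data.frame(X[, -1, drop = FALSE])
  df$y <- y; df$.off <- offs
  fml <- stats::as.formula(paste("y ~", paste(c(colnames(X)[-1], "offset(.off)"), collapse = " + ")))
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(fml, data = df, control = stats::glm.control(maxit = 50))),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$theta) || fit$theta <= 0)
    return(list(alpha = 1e-8))
  list(alpha = min(1 / fit$theta, 10))
}

## mean-dispersion trend: lowess of log alpha on log mean, floored
dispersion_trend <- function(mean_norm, alpha_ml) {
  ok <- is.finite(alpha_ml) & alpha_ml > 0 & mean_norm > 0
  if (sum(ok) < 10) return(rep(mean(alpha_ml[ok]) %||% 0.1, length(alpha_ml)))
  lo <- stats::lowess(log(mean_norm[ok]), log(pmax(alpha_ml[ok], 1e-8)), f = 0.5)
  tr <- approx(lo$x, lo$y, xout = log(pmax(mean_norm, min(mean_norm[ok]))),
               rule = 2)$y
  pmax(exp(tr), 1e-8)
}

## Wald test at fixed dispersion alpha: refit with negative.binomial(theta)
nb_wald <- function(y, X, offs, alpha) {
  theta <- 1 / max(alpha, 1e-8)
  fit <- tryCatch(suppressWarnings(
    stats::glm.fit(X, y, offset = offs,
                   family = MASS::negative.binomial(theta = theta))),
    error = function(e) NULL)
  if (is.null(fit) || is.null(fit$coefficients) || anyNA(fit$coefficients))
    return(list(log2_fc = NA_real_, p = NA_real_))
  beta <- fit$coefficients
  ## Wald SE from the weighted information matrix
  w <- fit$weights
  XtWX <- crossprod(X * sqrt(w))
  cov_beta <- tryCatch(solve(XtWX), error = function(e) NULL)
  if (is.null(cov_beta)) return(list(log2_fc = NA_real_, p = NA_real_))
  j <- which(colnames(X) == "group_case")
  se <- sqrt(cov_beta[j, j])
  z <- beta[j] / se
  list(log2_fc = beta[j] / log(2), p = 2 * pnorm(-abs(z)))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic FDR step-up with enforced monotonicity; ties are handled
#' stably. Values must lie in \[0, 1\].
#' @param pvals numeric vector of p-values
#' @return adjusted p-values in input order
#' @export
bh_adjust <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop_fmt("p-values must lie in [0, 1]")
  n <- length(pvals)
  if (n == 0) return(numeric())
  o <- order(pvals, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(n / (n:1) * pvals[o]))[ro]
  adj
}

#' Bonferroni adjustment
#' @param pvals numeric vector of p-values in \[0, 1\]
#' @return `min(m * p, 1)` per value
#' @export
bonferroni_adjust <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop_fmt("p-values must lie in [0, 1]")
  pmin(pvals * length(pvals), 1)
}

#' Promoter windows for a gene annotation
#'
#' Strand-aware window `[TSS - up, TSS + down)` on the plus strand,
#' `[TSS - down, TSS + up)` on the minus strand.
#' @param genes data.frame with `gene_id`, `chrom`, `tss`, `strand`
#' @param up,down window extents in bp
#' @return data.frame `gene_id`, `chrom`, `start`, `end`
#' @export
promoter_windows <- function(genes, up = 4000L, down = 1000L) {
  plus <- genes$strand == "+"
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = pmax(0L, as.integer(ifelse(plus, genes$tss - up, genes$tss - down))),
             end = as.integer(ifelse(plus, genes$tss + down, genes$tss + up)),
             stringsAsFactors = FALSE)
}

#' Classify peaks as promoter- or enhancer-class
#'
#' A peak overlapping (>= 1 bp) any strand-aware promoter window
#' (`up`/`down` around the TSS) is promoter-class; all remaining peaks are
#' enhancer-class.
#'
#' @param peaks peak data.frame (chrom/start/end, optional name)
#' @param genes gene annotation with `gene_id`, `chrom`, `tss`, `strand`
#' @param promoter_up,promoter_down window extents in bp
#' @return data.frame `feature_id`, `class`
#' @export
classify_enhancer_promoter <- function(peaks, genes, promoter_up = 4000L,
                                       promoter_down = 1000L) {
  ids <- peaks$name %||% sprintf("peak_%d", seq_len(nrow(peaks)))
  if (nrow(peaks) == 0)
    return(data.frame(feature_id = character(), class = character()))
  pw <- promoter_windows(genes, promoter_up, promoter_down)
  hit <- GenomicRanges::countOverlaps(as_granges(peaks), as_granges(pw)) > 0
  data.frame(feature_id = ids, class = ifelse(hit, "promoter", "enhancer"),
             stringsAsFactors = FALSE)
}

#' Link an enhancer peak to its target gene
#'
#' If the enhancer overlaps a chromatin-loop anchor whose partner anchor
#' overlaps a gene's promoter window, that gene is returned with source
#' `"loop"`. Otherwise the gene with the smallest
#' `|enhancer midpoint - TSS|` is returned with source `"nearest"`; ties
#' break to the smaller TSS coordinate, then lexicographic `gene_id`.
#'
#' @param enhancer one-row peak data.frame (chrom/start/end)
#' @param loops loop table (chrom1/start1/end1/chrom2/start2/end2)
#' @param genes gene annotation
#' @param promoter_up,promoter_down promoter window extents
#' @return list with `gene` and `link_source`
#' @export
link_enhancer <- function(enhancer, loops, genes, promoter_up = 4000L,
                          promoter_down = 1000L) {
  if (nrow(genes) == 0) stop_fmt("empty gene annotation")
  pw <- promoter_windows(genes, promoter_up, promoter_down)
  ge <- as_granges(enhancer)
  if (!is.null(loops) && nrow(loops) > 0) {
    ## loops are symmetric: test the enhancer against both anchors
    for (swap in c(FALSE, TRUE)) {
      a1 <- if (!swap) loops[, c("chrom1", "start1", "end1")] else loops[, c("chrom2", "start2", "end2")]
      a2 <- if (!swap) loops[, c("chrom2", "start2", "end2")] else loops[, c("chrom1", "start1", "end1")]
      names(a1) <- names(a2) <- c("chrom", "start", "end")
      hits <- S4Vectors::queryHits(GenomicRanges::findOverlaps(as_granges(a1), ge))
      if (length(hits)) {
        partner <- a2[hits, , drop = FALSE]
        ov <- GenomicRanges::findOverlaps(as_granges(partner), as_granges(pw))
        if (length(ov)) {
          cand <- sort(unique(pw$gene_id[S4Vectors::subjectHits(ov)]))
          return(list(gene = cand[1], link_source = "loop"))
        }
      }
    }
  }
  mid <- enhancer$start[1] + (enhancer$end[1] - enhancer$start[1]) %/% 2
  same <- genes[genes$chrom == enhancer$chrom[1], , drop = FALSE]
  if (nrow(same) == 0) same <- genes
  d <- abs(mid - same$tss)
  ord <- order(d, same$tss, same$gene_id)
  list(gene = same$gene_id[ord[1]], link_source = "nearest")
}

#' Annotate every peak with class and linked gene
#'
#' Promoter-class peaks link to the overlapped promoter's gene (overlap
#' based); enhancer-class peaks link through [link_enhancer()].
#' @param peaks peak data.frame with `name`
#' @param genes gene annotation
#' @param loops loop table (may be NULL)
#' @param promoter_up,promoter_down promoter window extents
#' @return data.frame `feature_id`, `class`, `linked_gene`, `link_source`
#' @export
annotate_peaks <- function(peaks, genes, loops = NULL, promoter_up = 4000L,
                           promoter_down = 1000L) {
  cls <- classify_enhancer_promoter(peaks, genes, promoter_up, promoter_down)
  pw <- promoter_windows(genes, promoter_up, promoter_down)
  out <- cls
  out$linked_gene <- NA_character_
  out$link_source <- NA_character_
  gp <- as_granges(peaks); gw <- as_granges(pw)
  ov <- GenomicRanges::findOverlaps(gp, gw)
  byq <- split(S4Vectors::subjectHits(ov), S4Vectors::queryHits(ov))
  for (i in seq_len(nrow(peaks))) {
    if (cls$class[i] == "promoter") {
      cand <- pw$gene_id[byq[[as.character(i)]]]
      out$linked_gene[i] <- sort(cand)[1]
      out$link_source[i] <- "overlap"
    } else {
      lk <- link_enhancer(peaks[i, , drop = FALSE], loops, genes,
                          promoter_up, promoter_down)
      out$linked_gene[i] <- lk$gene
      out$link_source[i] <- lk$link_source
    }
  }
  out
}

#' GREAT-style basal-plus-extension region-to-gene mapping
#'
#' Every gene gets a strand-aware basal domain (`basal_up` upstream to
#' `basal_down` downstream of the TSS) extended in both directions up to
#' `max_extension` bp or until it meets the nearest neighboring gene's
#' basal domain. A region is associated with every gene whose regulatory
#' domain it intersects.
#'
#' @param regions interval data.frame (chrom/start/end)
#' @param genes gene annotation
#' @param basal_up,basal_down basal domain extents in bp
#' @param max_extension maximum extension in bp
#' @param chrom_lengths optional named chromosome lengths for clipping
#' @return list (one per region) of associated gene-id character vectors
#' @export
great_region_gene <- function(regions, genes, basal_up = 5000L,
                              basal_down = 1000L, max_extension = 1e6,
                              chrom_lengths = NULL) {
  basal <- promoter_windows(genes, up = basal_up, down = basal_down)
  dom <- basal
  for (ch in unique(dom$chrom)) {
    sel <- which(dom$chrom == ch)[order(basal$start[which(dom$chrom == ch)])]
    bs <- basal$start[sel]; be <- basal$end[sel]
    n <- length(sel)
    ## extension stops at the nearest neighboring basal domain (or the
    ## max_extension cap); it never shrinks the basal domain itself
    prev_end <- if (n > 1) c(0, cummax(be)[-n]) else 0
    suffix_min <- rev(cummin(rev(bs)))
    next_start <- if (n > 1) c(suffix_min[-1], Inf) else Inf
    chr_end <- if (is.null(chrom_lengths)) Inf else chrom_lengths[[ch]]
    dom$start[sel] <- pmin(bs, pmax(bs - max_extension, prev_end))
    dom$end[sel] <- pmax(be, pmin(be + max_extension, next_start, chr_end))
  }
  dom$start <- as.integer(pmax(dom$start, 0))
  dom$end <- as.integer(dom$end)
  if (nrow(regions) == 0) return(list())
  ov <- GenomicRanges::findOverlaps(as_granges(regions), as_granges(dom))
  byq <- split(dom$gene_id[S4Vectors::subjectHits(ov)], S4Vectors::queryHits(ov))
  lapply(seq_len(nrow(regions)), function(i) {
    sort(unique(byq[[as.character(i)]])) %||% character()
  })
}

#' Exact upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability of at least
#' `k` marked items in a draw of `n` from a universe of `N` items of
#' which `K` are marked. Computed by direct summation of exact terms on
#' the log scale.
#'
#' @param k observed overlap
#' @param K size of the marked set
#' @param n draw size
#' @param N universe size
#' @return probability
#' @export
hypergeometric_p <- function(k, K, n, N) {
  if (K > N || n > N || k > min(K, n) || k < 0)
    stop_fmt("inconsistent hypergeometric sizes (k=%d K=%d n=%d N=%d)", k, K, n, N)
  i <- k:min(K, n)
  min(1, sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n))))
}

#' QQ genomic-inflation lambda
#'
#' `median(qchisq(1 - p, df = 1)) / qchisq(0.5, df = 1)`. Uniform
#' p-values give lambda 1; deflated tests (p piled toward 1) give
#' lambda < 1. Zero p-values are mapped to the smallest representable
#' positive double before the transform.
#' @param pvals non-empty p-value vector
#' @return lambda
#' @export
qq_lambda <- function(pvals) {
  if (!length(pvals)) stop_fmt("qq_lambda needs a non-empty p-value vector")
  p <- pmax(pvals, .Machine$double.xmin)
  median(qchisq(1 - p, df = 1)) / qchisq(0.5, df = 1)
}
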