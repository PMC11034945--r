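## Per-sample TF->gene regulatory networks: PWM motif scanning with exact
## p-values (dynamic programming over the discretized score distribution),
## active-promoter detection from H3K27ac, 150 bp summit windows,
## expression-weighted network assembly, and personalized PageRank with
## reversed-edge seeding.

REVCOMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp <- function(seq) {
  paste(rev(REVCOMP[strsplit(seq, "")[[1]]]), collapse = "")
}

## log-odds score matrix (positions x 4) with a small pseudocount
pwm_logodds <- function(pwm, background, pseudo = 1e-3) {
  m <- (pwm + pseudo) / (1 + 4 * pseudo)
  log2(sweep(m, 2, background, "/"))
}

## Exact p-values of log-odds scores under the background model, by
## dynamic programming over a discretized score grid (FIMO's approach).
pwm_score_distribution <- function(lo, background, granularity = 1e-3) {
  q <- round(lo / granularity)       # integer score matrix; scoring uses
  offset <- apply(q, 1, min)         # the same q so p-lookup is exact
  qs <- sweep(q, 1, offset)          # non-negative integers per row
  dist <- 1                          # P(score index = 0) = 1 at width 0
  for (i in seq_len(nrow(qs))) {
    width <- max(qs[i, ])
    new <- numeric(length(dist) + width)
    for (b in 1:4) {
      s <- qs[i, b]
      new[(s + 1):(s + length(dist))] <- new[(s + 1):(s + length(dist))] +
        background[b] * dist
    }
    dist <- new
  }
  ## upper-tail: P(score >= x)
  tail_p <- rev(cumsum(rev(dist)))
  list(tail_p = tail_p, q = q, offset = sum(offset), granularity = granularity)
}

pwm_score_p <- function(dist, score_int) {
  idx <- score_int - dist$offset + 1
  idx <- pmin(pmax(idx, 1), length(dist$tail_p))
  dist$tail_p[idx]
}

#' Scan a sequence with a PWM, reporting hits with exact p-values
#'
#' Scores every window on both strands with the log-odds of the PWM
#' against the background, computes the exact p-value of each score from
#' the discretized score distribution (dynamic programming over motif
#' positions), and returns hits with `p <= p_threshold`. Windows
#' containing N are skipped.
#'
#' @param pwm positions x 4 probability matrix (columns A,C,G,T)
#' @param sequence DNA string over A,C,G,T,N
#' @param p_threshold hit p-value cutoff (default 1e-4)
#' @param background length-4 background probabilities
#' @return data.frame `position` (0-based window start), `strand`,
#'   `score`, `p`
#' @export
scan_motif <- function(pwm, sequence, p_threshold = 1e-4,
                       background = rep(0.25, 4)) {
  w <- nrow(pwm)
  n <- nchar(sequence)
  empty <- data.frame(position = integer(), strand = character(),
                      score = numeric(), p = numeric())
  if (w > n) return(empty)
  lo <- pwm_logodds(pwm, background)
  dist <- pwm_score_distribution(lo, background)
  chars <- strsplit(toupper(sequence), "")[[1]]
  code <- match(chars, DNA)                     # NA for N
  hits <- list()
  for (strand in c("+", "-")) {
    loS <- if (strand == "+") lo else lo[rev(seq_len(w)), c(4, 3, 2, 1)]
    qS <- if (strand == "+") dist$q else dist$q[rev(seq_len(w)), c(4, 3, 2, 1)]
    scores <- rep(NA_real_, n - w + 1)
    scores_int <- rep(NA_real_, n - w + 1)
    ok <- !is.na(code)
    for (start in seq_len(n - w + 1)) {
      idx <- start:(start + w - 1)
      if (!all(ok[idx])) next
      pick <- cbind(seq_len(w), code[idx])
      scores[start] <- sum(loS[pick])
      scores_int[start] <- sum(qS[pick])
    }
    valid <- which(!is.na(scores))
    if (!length(valid)) next
    p <- pwm_score_p(dist, scores_int[valid])
    keep <- p <= p_threshold
    if (any(keep))
      hits[[strand]] <- data.frame(position = valid[keep] - 1L, strand = strand,
                                   score = scores[valid][keep], p = p[keep],
                                   stringsAsFactors = FALSE)
  }
  if (!length(hits)) return(empty)
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out[order(out$position, out$strand), , drop = FALSE]
}

#' Genes with an active promoter
#'
#' A gene is active iff any H3K27ac peak overlaps its strand-aware
#' promoter window (`up` upstream to `down` downstream of the TSS).
#' @param peaks H3K27ac peak data.frame
#' @param genes gene annotation
#' @param up,down window extents in bp
#' @return character vector of active gene ids
#' @export
active_promoters <- function(peaks, genes, up = 4000L, down = 1000L) {
  if (nrow(peaks) == 0) return(character())
  pw <- promoter_windows(genes, up, down)
  hit <- GenomicRanges::countOverlaps(as_granges(pw), as_granges(peaks)) > 0
  pw$gene_id[hit]
}

#' Window centered on a peak summit
#'
#' `[summit - width/2, summit + width/2)`, clipped to the chromosome.
#' @param peak one-row peak data.frame with `chrom` and `summit`
#' @param width window width in bp (150 bp default)
#' @param chrom_lengths optional named chromosome lengths for clipping
#' @return one-row interval data.frame
#' @export
summit_window <- function(peak, width = 150L, chrom_lengths = NULL) {
  half <- width %/% 2L
  start <- max(0L, as.integer(peak$summit[1] - half))
  end <- as.integer(peak$summit[1] + (width - half))
  if (width == 0) end <- start
  if (!is.null(chrom_lengths))
    end <- min(end, chrom_lengths[[peak$chrom[1]]])
  data.frame(chrom = peak$chrom[1], start = start, end = max(start, end),
             stringsAsFactors = FALSE)
}

#' Assemble a per-sample TF->gene regulatory network
#'
#' Nodes are genes with weight `e^z` (z the sample's expression z-score;
#' genes without a measurement get z = 0, with a warning for TFs). A
#' directed edge tf -> gene is formed for every motif hit of the TF in a
#' peak assigned to the gene (its promoter or a linked enhancer), with
#' weight `sqrt(e^{z_tf} * I_peak / median(I))` combining the TF's
#' expression with the pooled H3K27ac peak intensity. Parallel edges
#' collapse to the maximum weight.
#'
#' @param motif_edges data.frame `tf`, `gene`, `peak_id`, `provenance`
#'   (promoter/enhancer) from motif scanning
#' @param expression_z named per-gene z-scores
#' @param peak_intensity named pooled normalized intensity per peak_id
#' @param genes gene annotation (defines the node universe)
#' @return object of class `reg_network`: `nodes` (gene, z, node_weight),
#'   `edges` (tf, gene, weight, provenance, peak_id)
#' @export
build_network <- function(motif_edges, expression_z, peak_intensity, genes) {
  ids <- genes$gene_id
  z <- setNames(rep(0, length(ids)), ids)
  known <- intersect(ids, names(expression_z))
  z[known] <- expression_z[known]
  miss_tf <- setdiff(unique(motif_edges$tf), names(expression_z))
  if (length(miss_tf))
    warning(sprintf("TF(s) without expression measurement get z = 0: %s",
                    paste(miss_tf, collapse = ", ")), call. = FALSE)
  nodes <- data.frame(gene = ids, z = unname(z[ids]),
                      node_weight = exp(unname(z[ids])), stringsAsFactors = FALSE)
  if (nrow(motif_edges) == 0) {
    return(structure(list(nodes = nodes,
                          edges = data.frame(tf = character(), gene = character(),
                                             weight = numeric(), provenance = character(),
                                             peak_id = character())),
                     class = "reg_network"))
  }
  med_i <- median(peak_intensity)
  if (!is.finite(med_i) || med_i <= 0) med_i <- 1
  inten <- peak_intensity[motif_edges$peak_id]
  inten[is.na(inten)] <- med_i
  w <- sqrt(exp(z[motif_edges$tf]) * as.numeric(inten) / med_i)
  edges <- data.frame(tf = motif_edges$tf, gene = motif_edges$gene,
                      weight = as.numeric(w),
                      provenance = motif_edges$provenance,
                      peak_id = motif_edges$peak_id, stringsAsFactors = FALSE)
  ## collapse parallel tf->gene edges to the max weight
  key <- paste(edges$tf, edges$gene, sep = "\r")
  ord <- order(key, -edges$weight)
  edges <- edges[ord, , drop = FALSE]
  edges <- edges[!duplicated(key[ord]), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "reg_network")
}

#' @export
print.reg_network <- function(x, ...) {
  cat(sprintf("reg_network: %d nodes, %d edges (%d TFs)\n",
              nrow(x$nodes), nrow(x$edges), length(unique(x$edges$tf))))
  invisible(x)
}

#' Personalized PageRank with reversed-edge seeding
#'
#' The seed vector is the normalized node weights. Edge directionality is
#' reversed (gene -> TF) so that influence flows from regulatees back to
#' their regulators; the transition matrix is column-normalized over the
#' reversed edges using edge weights, dangling nodes teleport to the
#' seed, and `r <- (1 - d) s + d W r` is iterated until the L1 change
#' drops below `tol`. Scores are reported for the original orientation
#' and sum to 1.
#'
#' @param network a `reg_network`
#' @param damping damping factor d in (0, 1)
#' @param tol L1 convergence tolerance
#' @param max_iter iteration cap (error on non-convergence)
#' @return list: `scores` (named, sums to 1), `iterations`, `damping`
#' @export
personalized_pagerank <- function(network, damping = 0.85, tol = 1e-8,
                                  max_iter = 1000L) {
  nodes <- network$nodes$gene
  n <- length(nodes)
  if (n == 0) stop_fmt("network has no nodes")
  s <- network$nodes$node_weight
  if (sum(s) <= 0) s <- rep(1, n)
  s <- s / sum(s)
  ## reversed edges: gene -> tf, weighted; W[to, from] = w / out(from)
  e <- network$edges
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(e) > 0) {
    from <- match(e$gene, nodes); to <- match(e$tf, nodes)
    for (k in seq_len(nrow(e))) W[to[k], from[k]] <- W[to[k], from[k]] + e$weight[k]
    colsum <- colSums(W)
    pos <- colsum > 0
    W[, pos] <- sweep(W[, pos, drop = FALSE], 2, colsum[pos], "/")
  }
  dangling <- colSums(W) == 0
  r <- s
  for (it in seq_len(max_iter)) {
    r_new <- (1 - damping) * s + damping * (W %*% r + sum(r[dangling]) * s)
    r_new <- as.numeric(r_new)
    if (sum(abs(r_new - r)) < tol) {
      r <- r_new / sum(r_new)
      return(list(scores = setNames(r, nodes), iterations = it, damping = damping))
    }
    r <- r_new
  }
  stop_fmt("personalized PageRank did not converge in %d iterations", max_iter)
}

#' Rank TFs by absolute pairwise change in PageRank
#'
#' TFs are first filtered to those differentially expressed (adjusted
#' p < alpha), then ranked by the absolute mean over matched pairs of
#' (case PPR - control PPR), descending. Per-TF z-scored PPR across
#' samples is returned alongside for heatmap use.
#'
#' @param ppr_matrix samples x TF matrix of PPR (or z-scored PPR) values
#' @param tf_differential `DifferentialResult` data.frame for TF
#'   expression
#' @param pairs sample sheet subset mapping sample ids to pair/group
#'   (columns `sample_id`, `pair_id`, `group`)
#' @param alpha expression FDR cutoff
#' @return data.frame ranked by `abs_mean_delta`: `tf`, `mean_delta`,
#'   `abs_mean_delta`, `expr_p_adj`, plus attribute `zscores`
#' @export
ppr_rank_tfs <- function(ppr_matrix, tf_differential, pairs, alpha = 0.05) {
  tfs <- intersect(colnames(ppr_matrix), tf_differential$feature_id)
  sig <- tf_differential$feature_id[tf_differential$p_adj < alpha]
  tfs <- tfs[tfs %in% sig]
  if (!length(tfs)) {
    out <- data.frame(tf = character(), mean_delta = numeric(),
                      abs_mean_delta = numeric(), expr_p_adj = numeric())
    attr(out, "zscores") <- ppr_matrix[, 0, drop = FALSE]
    return(out)
  }
  missing <- setdiff(unique(pairs$sample_id), rownames(ppr_matrix))
  if (length(missing))
    stop_fmt("PPR missing for sample(s): %s", paste(head(missing, 3), collapse = ", "))
  deltas <- pairwise_diff(ppr_matrix[, tfs, drop = FALSE], pairs)
  md <- vapply(tfs, function(tf) mean(deltas$delta[deltas$feature_id == tf]), numeric(1))
  out <- data.frame(tf = tfs, mean_delta = unname(md),
                    abs_mean_delta = abs(unname(md)),
                    expr_p_adj = tf_differential$p_adj[match(tfs, tf_differential$feature_id)],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$abs_mean_delta, out$tf), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "zscores") <- scale(ppr_matrix[, tfs, drop = FALSE])
  out
}
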