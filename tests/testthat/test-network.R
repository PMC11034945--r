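cons_pwm <- function(word, p = 0.97) {
  base <- match(strsplit(word, "")[[1]], c("A", "C", "G", "T"))
  m <- matrix((1 - p) / 3, length(base), 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  m[cbind(seq_along(base), base)] <- p
  m
}

test_that("motif scanning finds the consensus on both strands with exact p", {
  pwm <- cons_pwm("ACGTAC")
  hits <- scan_motif(pwm, "TTACGTACTT", p_threshold = 1e-2)
  plus <- hits[hits$strand == "+", ]
  expect_equal(plus$position, 2L)
  expect_equal(plus$score, max(hits$score))

  rc <- "AAGTACGTAA"  # revcomp of TTACGTACTT
  hits_rc <- scan_motif(pwm, rc, p_threshold = 1e-2)
  minus <- hits_rc[hits_rc$strand == "-", ]
  expect_equal(nrow(minus), 1)
  expect_equal(minus$score, plus$score, tolerance = 1e-9)

  expect_equal(nrow(scan_motif(pwm, "ACG")), 0)          # PWM longer than seq
  ## N at index 2 knocks out window starts 1-2 on both strands (4 hits)
  expect_equal(nrow(scan_motif(pwm, "ANGTACGTAA", p_threshold = 1)),
               nrow(scan_motif(pwm, "AAGTACGTAA", p_threshold = 1)) - 4L)
})

test_that("motif p-values match exhaustive k-mer enumeration", {
  pwm <- cons_pwm("ACGT", p = 0.7)
  lo <- epiregpair:::pwm_logodds(pwm, rep(0.25, 4))
  dist <- epiregpair:::pwm_score_distribution(lo, rep(0.25, 4))
  ## enumerate all 256 4-mers with the same integer discretization
  kmers <- expand.grid(b1 = 1:4, b2 = 1:4, b3 = 1:4, b4 = 1:4)
  scores_int <- apply(kmers, 1, function(b) sum(dist$q[cbind(1:4, as.integer(b))]))
  for (s in unique(scores_int)) {
    oracle_p <- mean(scores_int >= s)
    expect_equal(epiregpair:::pwm_score_p(dist, s), oracle_p, tolerance = 1e-12)
  }
})

test_that("active promoters respect the strand-aware window boundary", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", tss = 10000L,
                      strand = "+", stringsAsFactors = FALSE)
  over_tss <- data.frame(chrom = "chr1", start = 9900L, end = 10100L)
  expect_equal(active_promoters(over_tss, genes), "g1")
  ## width-1 peak exactly 4001 bp upstream misses the [tss-4000, tss+1000) window
  outside <- data.frame(chrom = "chr1", start = 5998L, end = 5999L)
  expect_equal(length(active_promoters(outside, genes)), 0)
  inside_edge <- data.frame(chrom = "chr1", start = 6000L, end = 6001L)
  expect_equal(active_promoters(inside_edge, genes), "g1")
  expect_equal(length(active_promoters(over_tss[0, ], genes)), 0)
})

test_that("summit windows are centered, clipped and degenerate-safe", {
  pk <- data.frame(chrom = "chr1", summit = 1000L)
  w <- summit_window(pk, 150)
  expect_equal(c(w$start, w$end), c(925L, 1075L))
  near0 <- summit_window(data.frame(chrom = "chr1", summit = 30L), 150)
  expect_equal(near0$start, 0L)
  zero <- summit_window(pk, 0)
  expect_equal(zero$start, zero$end)
  clipped <- summit_window(pk, 150, chrom_lengths = c(chr1 = 1050L))
  expect_equal(clipped$end, 1050L)
})

test_that("network edge weights follow the sqrt(e^z * intensity) composition", {
  genes <- data.frame(gene_id = c("T1", "G1", "G2"), chrom = "chr1",
                      tss = c(1000L, 5000L, 9000L), strand = "+",
                      stringsAsFactors = FALSE)
  me <- data.frame(tf = "T1", gene = c("G1", "G2"), peak_id = c("p1", "p2"),
                   provenance = "promoter", stringsAsFactors = FALSE)
  z0 <- setNames(rep(0, 3), genes$gene_id)
  inten <- c(p1 = 2, p2 = 2)                        # both at the median
  nw <- build_network(me, z0, inten, genes)
  expect_equal(nw$nodes$node_weight, rep(1, 3))
  expect_equal(nw$edges$weight, c(1, 1))

  inten2 <- c(p1 = 2, p2 = 4)                       # doubled -> sqrt(2) on that edge
  nw2 <- build_network(me, z0, inten2, genes)
  w_p2 <- nw2$edges$weight[nw2$edges$peak_id == "p2"]
  w_p1 <- nw2$edges$weight[nw2$edges$peak_id == "p1"]
  expect_equal(w_p2 / w_p1, sqrt(2), tolerance = 1e-12)

  ## TF missing from the expression table -> z = 0 with warning
  expect_warning(nw3 <- build_network(me, c(G1 = 1), inten, genes), "z = 0")
  expect_equal(nw3$nodes$node_weight[nw3$nodes$gene == "T1"], 1)

  ## parallel edges collapse to the max weight
  me_dup <- rbind(me, data.frame(tf = "T1", gene = "G1", peak_id = "p2",
                                 provenance = "enhancer"))
  nw4 <- build_network(me_dup, z0, inten2, genes)
  eG1 <- nw4$edges[nw4$edges$gene == "G1", ]
  expect_equal(nrow(eG1), 1)
  ## max of sqrt(2/3) (p1) and sqrt(4/3) (p2), median intensity 3
  expect_equal(eG1$weight, sqrt(4 / 3), tolerance = 1e-12)
})

test_that("the synthetic model's planted edges are recovered by motif scanning", {
  m <- tiny_model(seed = 6)
  found <- list()
  for (g in unique(m$true_network$gene)) {
    gi <- m$genes[m$genes$gene_id == g, ]
    win_start <- gi$tss - 75L
    seqstr <- substr(m$seqs[[gi$chrom]], win_start + 1L, win_start + 150L)
    for (tf in m$tf_ids) {
      hits <- scan_motif(m$pwms[[tf]], seqstr, p_threshold = 1e-4,
                         background = m$background)
      if (nrow(hits) > 0)
        found[[length(found) + 1]] <- data.frame(tf = tf, gene = g)
    }
  }
  found <- do.call(rbind, found)
  planted <- paste(m$true_network$tf, m$true_network$gene)
  recovered <- paste(found$tf, found$gene)
  expect_true(all(planted %in% recovered))
})

test_that("personalized PageRank satisfies its contracts", {
  one <- build_network(data.frame(tf = character(), gene = character(),
                                  peak_id = character(), provenance = character()),
                       c(A = 0.3),
                       numeric(),
                       data.frame(gene_id = "A", chrom = "chr1", tss = 1L,
                                  strand = "+"))
  r1 <- personalized_pagerank(one)
  expect_equal(unname(r1$scores), 1.0)

  ## two nodes with symmetric edges and equal weights -> (0.5, 0.5)
  genes2 <- data.frame(gene_id = c("A", "B"), chrom = "chr1", tss = c(1L, 2L),
                       strand = "+")
  me <- data.frame(tf = c("A", "B"), gene = c("B", "A"),
                   peak_id = c("p", "q"), provenance = "promoter")
  nw <- build_network(me, c(A = 0, B = 0), c(p = 1, q = 1), genes2)
  r2 <- personalized_pagerank(nw)
  expect_equal(unname(r2$scores), c(0.5, 0.5), tolerance = 1e-7)

  ## asymmetric chain does not reach a 1e-300 L1 change in 2 iterations
  genes3 <- data.frame(gene_id = c("A", "B", "C"), chrom = "chr1",
                       tss = 1:3, strand = "+")
  me3 <- data.frame(tf = c("A", "B"), gene = c("B", "C"),
                    peak_id = c("p", "q"), provenance = "promoter")
  nw_chain <- build_network(me3, c(A = 1, B = 0, C = -1), c(p = 1, q = 2), genes3)
  expect_error(personalized_pagerank(nw_chain, tol = 1e-300, max_iter = 2L),
               "did not converge")
})

test_that("PageRank equals the dense linear solve and is scale-invariant", {
  set.seed(91)
  n <- 7
  genes <- data.frame(gene_id = LETTERS[1:n], chrom = "chr1",
                      tss = seq_len(n), strand = "+")
  me <- expand.grid(tf = LETTERS[1:4], gene = LETTERS[1:n],
                    stringsAsFactors = FALSE)
  me <- me[me$tf != me$gene & runif(nrow(me)) < 0.6, ]
  me$peak_id <- sprintf("p%d", seq_len(nrow(me)))
  me$provenance <- "promoter"
  z <- setNames(rnorm(n), LETTERS[1:n])
  inten <- setNames(runif(nrow(me), 0.5, 3), me$peak_id)
  nw <- build_network(me, z, inten, genes)
  d <- 0.85
  res <- personalized_pagerank(nw, damping = d, tol = 1e-12)

  ## oracle: r = (1-d) (I - d M)^{-1} s with dangling teleport folded into M
  s <- nw$nodes$node_weight / sum(nw$nodes$node_weight)
  W <- matrix(0, n, n, dimnames = list(LETTERS[1:n], LETTERS[1:n]))
  for (k in seq_len(nrow(nw$edges)))
    W[nw$edges$tf[k], nw$edges$gene[k]] <- W[nw$edges$tf[k], nw$edges$gene[k]] +
      nw$edges$weight[k]
  cs <- colSums(W)
  W[, cs > 0] <- sweep(W[, cs > 0, drop = FALSE], 2, cs[cs > 0], "/")
  M <- W + s %o% as.numeric(cs == 0)
  oracle <- as.numeric((1 - d) * solve(diag(n) - d * M, s))
  expect_equal(unname(res$scores), oracle, tolerance = 1e-8)
  expect_equal(sum(res$scores), 1, tolerance = 1e-8)

  ## uniform edge-weight scaling changes nothing
  nw_scaled <- nw
  nw_scaled$edges$weight <- nw$edges$weight * 37
  res2 <- personalized_pagerank(nw_scaled, damping = d, tol = 1e-12)
  expect_equal(res$scores, res2$scores, tolerance = 1e-9)

  ## adding an isolated zero-ish node barely shifts the others
  genes3 <- rbind(genes, data.frame(gene_id = "Z", chrom = "chr1", tss = 99L,
                                    strand = "+"))
  nw3 <- build_network(me, c(z, Z = -20), inten, genes3)
  res3 <- personalized_pagerank(nw3, damping = d, tol = 1e-12)
  expect_equal(unname(res3$scores[LETTERS[1:n]]), oracle, tolerance = 1e-6)
})

test_that("TF ranking filters on expression FDR and sorts by |mean delta|", {
  ppr <- matrix(c(0.5, 0.4, 0.45, 0.44,      # TF1 deltas +0.1, +0.01
                  0.2, 0.4, 0.30, 0.32),     # TF2 deltas -0.2, -0.02
                nrow = 4,
                dimnames = list(c("case1", "ctrl1", "case2", "ctrl2"),
                                c("TF1", "TF2")))
  pairs <- data.frame(sample_id = rownames(ppr),
                      pair_id = c("P1", "P1", "P2", "P2"),
                      group = c("case", "control", "case", "control"))
  diffex <- data.frame(feature_id = c("TF1", "TF2"), p_adj = c(0.01, 0.01))
  rk <- ppr_rank_tfs(ppr, diffex, pairs)
  expect_equal(rk$tf, c("TF2", "TF1"))        # |-0.11| beats |0.055|
  expect_equal(rk$mean_delta[1], mean(c(-0.2, -0.02)))

  none <- data.frame(feature_id = c("TF1", "TF2"), p_adj = c(0.5, 0.9))
  expect_equal(nrow(ppr_rank_tfs(ppr, none, pairs)), 0)
})
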