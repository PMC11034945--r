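nb_null_cm <- function(n_feat, n_per_group, seed, mu = 100, size = 10) {
  withr::with_seed(seed, {
    m <- matrix(rnbinom(n_feat * 2 * n_per_group, mu = mu, size = size),
                n_feat, 2 * n_per_group,
                dimnames = list(sprintf("f%d", seq_len(n_feat)),
                                sprintf("s%d", seq_len(2 * n_per_group))))
    tmm_normalize(count_matrix(m))
  })
}

test_that("nb_differential detects a planted 4-fold effect with high power", {
  withr::with_seed(101, {
    n <- 20                                # samples per group
    n_feat <- 200; n_hot <- 20             # mostly-null background so the
    base <- rlnorm(n_feat, 5, 0.7)         # planted effect survives TMM
    mu_ctrl <- matrix(base, n_feat, n)
    mu_case <- mu_ctrl
    mu_case[seq_len(n_hot), ] <- mu_case[seq_len(n_hot), ] * 4
    mu <- cbind(mu_case, mu_ctrl)
    m <- matrix(rnbinom(length(mu), mu = mu, size = 10), n_feat, 2 * n,
                dimnames = list(sprintf("f%d", seq_len(n_feat)),
                                sprintf("s%d", seq_len(2 * n))))
    cm <- tmm_normalize(count_matrix(m))
    grp <- rep(c("case", "control"), each = n)
    res <- nb_differential(cm, grp, adjust_method = "bh")
    hot <- seq_len(n_hot)
    expect_gte(mean(res$p[hot] < 0.05), 0.95)
    expect_gt(median(res$log2_fc[hot]), 1.5)  # near the planted log2 FC of 2
    expect_lt(mean(res$p[-hot] < 0.05), 0.15) # background stays quiet
  })
})

test_that("nb_differential is label-antisymmetric and validates inputs", {
  cm <- nb_null_cm(30, 5, seed = 7)
  grp <- rep(c("case", "control"), each = 5)
  res <- nb_differential(cm, grp, adjust_method = "bh")
  res_sw <- nb_differential(cm, rev(grp), adjust_method = "bh")
  expect_equal(res$log2_fc, -res_sw$log2_fc, tolerance = 1e-6)
  expect_equal(res$p, res_sw$p, tolerance = 1e-6)
  expect_true(all(res$p_adj >= res$p - 1e-12))
  expect_equal(res$significant, res$p_adj < 0.05)

  expect_error(nb_differential(cm, c("case", rep("control", 9)), adjust_method = "bh"),
               ">= 2 samples")
  bad <- cm; bad$counts[1, 1] <- 1.5
  expect_error(nb_differential(bad, grp, adjust_method = "bh"), "integers")
})

test_that("bonferroni and BH reproduce hand-computed adjustments", {
  ## bonferroni: m * p capped at 1
  expect_equal(bonferroni_adjust(c(0.01, 0.4, 0.5, 0.2, 0.3))[1], 0.05)
  expect_equal(bonferroni_adjust(c(0.5, 0.5, 0.5)), c(1, 1, 1))
  ## BH step-up, hand computation: (0.01,0.02,0.03,0.04)*4/(1:4) -> all 0.04
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  ## order handling and monotonicity against the stats oracle
  withr::with_seed(5, {
    p <- runif(200)
    expect_equal(bh_adjust(p), p.adjust(p, "BH"), tolerance = 1e-12)
  })
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("promoter windows and enhancer/promoter classification are strand-aware", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                      tss = c(10000L, 50000L), strand = c("+", "-"),
                      stringsAsFactors = FALSE)
  pw <- promoter_windows(genes, 4000, 1000)
  expect_equal(pw$start, c(6000L, 49000L))
  expect_equal(pw$end, c(11000L, 54000L))

  peaks <- data.frame(chrom = "chr1",
                      start = c(9000L, 30000L, 53950L),
                      end = c(9100L, 30100L, 54050L),
                      name = c("p1", "p2", "p3"), stringsAsFactors = FALSE)
  cls <- classify_enhancer_promoter(peaks, genes)
  expect_equal(cls$class, c("promoter", "enhancer", "promoter"))
})

test_that("enhancer linking prefers loops then nearest with deterministic ties", {
  genes <- data.frame(gene_id = c("G", "H"), chrom = "chr1",
                      tss = c(10000L, 40000L), strand = "+",
                      stringsAsFactors = FALSE)
  loops <- data.frame(chrom1 = "chr1", start1 = 20000L, end1 = 21000L,
                      chrom2 = "chr1", start2 = 9500L, end2 = 10500L)
  enh <- data.frame(chrom = "chr1", start = 20400L, end = 20600L)
  lk <- link_enhancer(enh, loops, genes)
  expect_equal(lk$gene, "G"); expect_equal(lk$link_source, "loop")

  far <- data.frame(chrom = "chr1", start = 38000L, end = 38200L)
  lk2 <- link_enhancer(far, loops, genes)
  expect_equal(lk2$gene, "H"); expect_equal(lk2$link_source, "nearest")

  ## exactly equidistant -> lower TSS coordinate wins
  mid <- data.frame(chrom = "chr1", start = 24950L, end = 25050L)  # midpoint 25000
  lk3 <- link_enhancer(mid, NULL, genes)
  expect_equal(lk3$gene, "G")
  expect_error(link_enhancer(enh, loops, genes[0, ]), "empty gene annotation")
})

test_that("GREAT mapping extends basal domains to neighbors and caps extension", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                      tss = c(100000L, 500000L), strand = "+",
                      stringsAsFactors = FALSE)
  ## basal: g1 [95000,101000), g2 [495000,501000)
  inside <- data.frame(chrom = "chr1", start = 96000L, end = 97000L)
  expect_equal(great_region_gene(inside, genes)[[1]], "g1")
  ## the gap between the two basal domains is shared by both extensions
  gap <- data.frame(chrom = "chr1", start = 200000L, end = 201000L)
  expect_equal(great_region_gene(gap, genes)[[1]], c("g1", "g2"))
  ## beyond max_extension past the last TSS -> empty
  far <- data.frame(chrom = "chr1", start = 2000000L, end = 2001000L)
  expect_equal(length(great_region_gene(far, genes, max_extension = 1e6)[[1]]), 0)
  ## every basal domain contains its own TSS
  doms <- great_region_gene(data.frame(chrom = "chr1", start = 100000L,
                                       end = 100001L), genes)
  expect_true("g1" %in% doms[[1]])
})

test_that("hypergeometric upper tail is exact", {
  ## C(5,4) C(5,0) / C(10,4) = 5/210
  expect_equal(hypergeometric_p(4, 5, 4, 10), 5 / 210, tolerance = 1e-14)
  expect_equal(hypergeometric_p(0, 5, 4, 10), 1.0)
  expect_equal(hypergeometric_p(6, 6, 6, 6), 1.0)
  expect_equal(hypergeometric_p(2, 3, 3, 6),
               (choose(3, 2) * choose(3, 1) + choose(3, 3)) / choose(6, 3),
               tolerance = 1e-14)
  expect_error(hypergeometric_p(5, 4, 4, 10), "inconsistent")
})

test_that("qq_lambda behaves at its reference points", {
  expect_equal(qq_lambda(rep(0.5, 10)), 1.0)
  withr::with_seed(3, {
    expect_true(abs(qq_lambda(runif(10000)) - 1) < 0.05)
  })
  ## p piled toward 1 -> deflation (lambda < 1)
  expect_lt(qq_lambda(runif(500, 0.5, 1)), 1)
  expect_error(qq_lambda(numeric()), "non-empty")
})
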