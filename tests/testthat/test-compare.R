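delta_mats <- function(sim) list(af = sim$af, at = sim$at)

test_that("pairwise differences are case-minus-control and antisymmetric", {
  vals <- matrix(c(1, 2, 5, 3, 4, 7), nrow = 2, byrow = TRUE,
                 dimnames = list(c("caseA", "ctrlA"), c("f1", "f2", "f3")))
  pairs <- data.frame(sample_id = c("caseA", "ctrlA"), pair_id = "P1",
                      group = c("case", "control"))
  d <- pairwise_diff(vals, pairs)
  expect_equal(d$delta, c(1 - 3, 2 - 4, 5 - 7))

  swapped <- pairs; swapped$group <- rev(pairs$group)
  expect_equal(pairwise_diff(vals, swapped)$delta, -d$delta)

  same <- vals; same["caseA", ] <- same["ctrlA", ]
  expect_equal(pairwise_diff(same, pairs)$delta, rep(0, 3))
  expect_error(pairwise_diff(vals[1, , drop = FALSE], pairs), "missing for sample")
})

test_that("reversal classification applies the threshold and FDR filter", {
  sim <- simulate_pairwise_scores(60, 15, 14, n_af_reversed = 6,
                                  n_at_induced = 6, delta = 1.0,
                                  noise_sd = 0.25, seed = 21)
  calls <- classify_reversal(sim$af, sim$at, threshold = 0.5, alpha = 0.05)
  truth <- sim$truth
  rec <- calls$feature_id[calls$class == "recovered"]
  ind <- calls$feature_id[calls$class == "treatment_induced"]
  expect_true(all(truth$feature_id[truth$effect_class == "AF_reversed"] %in% rec))
  expect_true(all(truth$feature_id[truth$effect_class == "AT_induced"] %in% ind))
  expect_true(all(is.na(calls$fdr[calls$class == "neither"]) |
                    calls$fdr[calls$class == "neither"] >= 0 ))

  ## below-threshold difference stays neither regardless of consistency
  af <- matrix(rep(0.3, 30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  at <- matrix(rep(0.1, 30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  flat <- classify_reversal(af, at)
  expect_true(all(flat$class == "neither"))
  expect_error(classify_reversal(af[1, , drop = FALSE], at), ">= 2 pairs")
})

test_that("reversal classification is cohort-antisymmetric", {
  sim <- simulate_pairwise_scores(40, 12, 12, n_af_reversed = 5,
                                  n_at_induced = 5, seed = 33)
  fwd <- classify_reversal(sim$af, sim$at)
  rev <- classify_reversal(sim$at, sim$af)
  swap <- c(recovered = "treatment_induced", treatment_induced = "recovered",
            neither = "neither")
  expect_equal(unname(swap[fwd$class]), rev$class)
})

test_that("regulatee extraction requires edge shift, DEG status and TF count", {
  genes <- data.frame(gene_id = c("T1", "T2", "T3", "T4", "g1", "g2"),
                      chrom = "chr1", tss = 1:6, strand = "+")
  tfs <- c("T1", "T2", "T3", "T4")
  pairs <- data.frame(
    sample_id = c(sprintf("case%d", 1:6), sprintf("ctrl%d", 1:6)),
    pair_id = rep(sprintf("P%d", 1:6), 2),
    group = rep(c("case", "control"), each = 6))
  ## g1 regulated by all 4 TFs with a planted +1 edge-weight shift in cases;
  ## g2 regulated by only 2 TFs
  networks <- setNames(lapply(pairs$sample_id, function(s) {
    shift <- if (startsWith(s, "case")) 1 else 0
    me <- rbind(
      data.frame(tf = tfs, gene = "g1", peak_id = "p1", provenance = "promoter"),
      data.frame(tf = tfs[1:2], gene = "g2", peak_id = "p2", provenance = "promoter"))
    nw <- build_network(me, setNames(rep(0, 6), genes$gene_id),
                        c(p1 = 1, p2 = 1), genes)
    nw$edges$weight <- nw$edges$weight + shift + rnorm(nrow(nw$edges), sd = 0.01)
    nw
  }), pairs$sample_id)
  degs <- data.frame(feature_id = c("g1", "g2"), significant = c(TRUE, TRUE))
  withr::with_seed(2, {
    out <- extract_regulatees(networks, tfs, degs, pairs, min_tf_count = 3)
  })
  expect_equal(out, "g1")
  expect_equal(extract_regulatees(networks, tfs,
                                  data.frame(feature_id = character(),
                                             significant = logical()),
                                  pairs, min_tf_count = 3),
               character())
  expect_error(extract_regulatees(networks, tfs[1:2], degs, pairs,
                                  min_tf_count = 3), "exceeds")
})

test_that("cohort-specific sets partition significance correctly", {
  af <- data.frame(feature_id = c("a", "b", "c"), p_adj = c(0.01, 0.2, 0.03))
  at <- data.frame(feature_id = c("a", "b", "c"), p_adj = c(0.04, 0.01, 0.9))
  s <- cohort_specific_sets(af, at, 0.05)
  expect_equal(s$af_only, "c")
  expect_equal(s$at_only, "b")
  expect_equal(s$shared, "a")
  expect_equal(length(intersect(s$af_only, s$at_only)), 0)
  expect_error(cohort_specific_sets(af, at[1:2, ], 0.05), "universes differ")
})

test_that("age correlation matches the t closed form and is sign-symmetric", {
  ## r = 0.73 at n = 14 -> p ~ 0.0031 from t with 12 df
  withr::with_seed(8, {
    ages <- runif(14, 20, 80)
    x <- scale(ages)[, 1]
    ## unit-variance component exactly orthogonal to x -> cor(y, ages) = 0.73
    e <- scale(residuals(lm(rnorm(14) ~ x)))[, 1]
    y <- 0.73 * x + sqrt(1 - 0.73^2) * e
    vals <- matrix(y, ncol = 1, dimnames = list(NULL, "f"))
    res <- age_correlation(vals, ages)
    expect_equal(res$r, 0.73, tolerance = 1e-9)
    tstat <- 0.73 * sqrt(12 / (1 - 0.73^2))
    expect_equal(res$p, 2 * pt(-tstat, 12), tolerance = 1e-12)
    expect_equal(res$p, 0.0031, tolerance = 0.05)

    neg <- age_correlation(-vals, ages)
    expect_equal(neg$r, -res$r, tolerance = 1e-12)
    expect_equal(neg$p, res$p, tolerance = 1e-12)
  })

  perfect <- matrix(1:10, ncol = 1, dimnames = list(NULL, "lin"))
  res2 <- age_correlation(perfect, as.numeric(1:10))
  expect_equal(res2$r, 1)
  expect_lt(res2$p, 1e-12)

  const <- matrix(rep(1, 5), ncol = 1, dimnames = list(NULL, "flat"))
  expect_warning(out <- age_correlation(cbind(const, perfect[1:5, , drop = FALSE]),
                                        c(30, 40, 50, 60, 70)), "zero-variance")
  expect_equal(out$feature_id, "lin")
})

test_that("age threshold is inclusive and the sign summary is exact", {
  corr <- data.frame(feature_id = c("a", "b", "c", "d"),
                     r = c(0.60, -0.75, 0.59, 0.80), p = 0.01, n = 14)
  sel <- age_correlated_features(corr, 0.60)
  expect_setequal(sel$features$feature_id, c("a", "b", "d"))  # 0.60 kept
  expect_equal(sel$summary$n_negative, 1)
  expect_equal(sel$summary$frac_positive, 2 / 3)
  expect_error(age_correlated_features(corr, 1.2), "r_threshold")
})

test_that("planted age-correlated features clear the threshold at 25 pairs", {
  sim <- simulate_pairwise_scores(80, 25, 2, n_age_correlated = 10,
                                  age_slope_score = 0.03, noise_sd = 0.25,
                                  seed = 44)
  res <- age_correlation(sim$af, sim$ages_af)
  sel <- age_correlated_features(res, 0.50)
  planted <- sim$truth$feature_id[sim$truth$effect_class == "age_correlated"]
  hit <- mean(planted %in% sel$features$feature_id)
  expect_gte(hit, 0.8)
})
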