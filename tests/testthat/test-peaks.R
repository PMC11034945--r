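test_that("poisson caller finds spikes and merges close ones", {
  flat <- list(chr1 = rep(5, 20000))
  expect_equal(nrow(call_peaks_poisson(flat)), 0)
  expect_equal(nrow(call_peaks_poisson(list(chr1 = rep(0, 1000)))), 0)

  cov <- rep(1, 20000)
  cov[5000:5299] <- 10
  cov[5150] <- 14                      # spike max
  pk <- call_peaks_poisson(list(chr1 = cov))
  expect_equal(nrow(pk), 1)
  expect_true(pk$start <= 5000 - 1 + 1 && pk$end >= 5299)
  expect_equal(pk$summit, 5149)        # 0-based position of the max

  ## two spikes 50 bp apart merge (gap <= 100 bp)
  cov2 <- rep(1, 20000)
  cov2[3000:3050] <- 12
  cov2[3100:3150] <- 12
  pk2 <- call_peaks_poisson(list(chr1 = cov2))
  expect_equal(nrow(pk2), 1)

  ## 150 bp apart stays two peaks
  cov3 <- rep(1, 20000)
  cov3[3000:3050] <- 12
  cov3[3201:3251] <- 12
  expect_equal(nrow(call_peaks_poisson(list(chr1 = cov3))), 2)
  expect_error(call_peaks_poisson(list(chr1 = c(-1, 2))), "non-negative")
})

test_that("high-confidence peaks are replicate-supported union-merges", {
  r1 <- data.frame(chrom = "chr1", start = 100L, end = 200L, summit = 150L, score = 5)
  r2 <- data.frame(chrom = "chr1", start = 150L, end = 250L, summit = 180L, score = 9)
  hc <- high_confidence_peaks(r1, r2)
  expect_equal(hc[, c("start", "end")], data.frame(start = 100L, end = 250L))
  expect_equal(hc$summit, 180L)        # from the higher-score source

  disjoint <- data.frame(chrom = "chr1", start = 500L, end = 600L,
                         summit = 550L, score = 1)
  expect_equal(nrow(high_confidence_peaks(r1, disjoint)), 0)

  r3 <- data.frame(chrom = "chr1", start = c(0L, 300L, 700L),
                   end = c(50L, 400L, 800L), summit = c(10L, 350L, 750L),
                   score = c(1, 2, 3))
  r4 <- data.frame(chrom = "chr1", start = c(20L, 390L), end = c(60L, 450L),
                   summit = c(30L, 400L), score = c(1, 1))
  expect_equal(nrow(high_confidence_peaks(r3, r4)), 2)
})

test_that("master consensus merges transitively and is sample-order invariant", {
  s1 <- data.frame(chrom = "chr1", start = 0L, end = 100L, summit = 50L, score = 1)
  s2 <- data.frame(chrom = "chr1", start = 50L, end = 150L, summit = 100L, score = 2)
  s3 <- data.frame(chrom = "chr1", start = 140L, end = 200L, summit = 160L, score = 3)
  m <- consensus_master(list(s1, s2, s3))
  expect_equal(nrow(m), 1)
  expect_equal(m$start, 0L); expect_equal(m$end, 200L)
  expect_equal(m$n_samples, 3L)

  m2 <- consensus_master(list(s3, s1, s2))
  expect_equal(m[, c("chrom", "start", "end", "n_samples")],
               m2[, c("chrom", "start", "end", "n_samples")])

  single <- consensus_master(list(s1))
  expect_equal(single[, c("start", "end")], s1[, c("start", "end")])
})

test_that("count matrix applies input subtraction with the floor", {
  master <- data.frame(chrom = "chr1", start = c(0L, 100L), end = c(50L, 150L),
                       name = c("m1", "m2"))
  chip <- matrix(c(10, 2, 8, 4), 2, 2, dimnames = list(c("m1", "m2"), c("s1", "s2")))
  inp <- matrix(c(3, 5, 1, 1), 2, 2, dimnames = dimnames(chip))
  cm <- build_count_matrix(chip, master, input_counts = inp,
                           library_sizes = c(s1 = 1000, s2 = 1000))
  expect_equal(unname(cm$counts[, "s1"]), c(7, 1))    # 10-3, max(2-5, 1)
  expect_equal(unname(cm$counts[, "s2"]), c(7, 3))
  expect_equal(as.numeric(cm$library_sizes), c(1000, 1000))

  raw <- build_count_matrix(chip, master)
  expect_equal(raw$counts, chip)
})

test_that("TMM factors match edgeR and the explicit trimmed-mean oracle", {
  skip_if_not_installed("edgeR")
  set.seed(31)
  m <- matrix(rnbinom(600 * 4, mu = 200, size = 5) + 1L, 600, 4,
              dimnames = list(sprintf("f%d", 1:600), sprintf("s%d", 1:4)))
  cm <- count_matrix(m)
  mine <- tmm_factors(cm)
  theirs <- edgeR::calcNormFactors(m, method = "TMM")
  expect_equal(unname(mine), unname(theirs), tolerance = 1e-10)
  expect_equal(exp(mean(log(mine))), 1, tolerance = 1e-6)

  ## identical columns and exact 2x scaling both give unit factors
  m2 <- cbind(s1 = m[, 1], s2 = m[, 1])
  expect_equal(unname(tmm_factors(count_matrix(m2))), c(1, 1))
  m3 <- cbind(s1 = m[, 1], s2 = 2L * m[, 1])
  expect_equal(unname(tmm_factors(count_matrix(m3))), c(1, 1), tolerance = 1e-12)

  expect_error(tmm_factors(count_matrix(m[, 1, drop = FALSE])), ">= 2 samples")
  zero <- m; zero[, 2] <- 0L
  expect_error(tmm_factors(count_matrix(zero)), "all-zero")
})

test_that("TMM pairwise factor equals a hand-rolled M/A computation", {
  obs <- c(100, 220, 40, 10, 900, 55, 70, 130, 65, 300)
  ref <- c(110, 200, 35, 12, 850, 60, 60, 140, 70, 310)
  n_obs <- 5000; n_ref <- 5200
  M <- log2((obs / n_obs) / (ref / n_ref))
  A <- 0.5 * log2((obs / n_obs) * (ref / n_ref))
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  n <- length(M)
  loM <- floor(n * 0.3) + 1; hiM <- n + 1 - loM
  loA <- floor(n * 0.05) + 1; hiA <- n + 1 - loA
  keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
  oracle <- 2^(sum(M[keep] / v[keep]) / sum(1 / v[keep]))
  expect_equal(epiregpair:::tmm_pair(obs, ref, n_obs, n_ref, 0.3, 0.05),
               oracle, tolerance = 1e-8)
})

test_that("low-count filter applies the strict over-half rule and is idempotent", {
  m <- rbind(a = c(19, 19, 19, 25), b = c(19, 19, 25, 25),
             c = c(25, 25, 25, 25), d = c(0, 0, 0, 0))
  colnames(m) <- sprintf("s%d", 1:4)
  cm <- count_matrix(m)
  f <- filter_low(cm, min_count = 20, frac = 0.5)
  expect_equal(rownames(f$counts), c("b", "c"))   # 3/4 low removed, 2/4 kept
  f2 <- filter_low(f, min_count = 20, frac = 0.5)
  expect_identical(f$counts, f2$counts)
  all_high <- count_matrix(m[3, , drop = FALSE] + 0)
  expect_equal(filter_low(all_high)$counts, all_high$counts)
})

test_that("PC-guided covariate selection finds planted structure only", {
  set.seed(17)
  n <- 50
  pc_driver <- rnorm(n)
  m <- outer(rnorm(200), pc_driver) + matrix(rnorm(200 * n, sd = 0.1), 200, n)
  rownames(m) <- sprintf("f%d", 1:200); colnames(m) <- sprintf("s%d", 1:n)
  centered <- m - rowMeans(m)
  pc1 <- prcomp(t(centered), center = FALSE)$x[, 1]
  covs <- data.frame(planted = pc1, noise = rnorm(n), constant = 1)
  expect_warning(sel <- pc_covariate_select(m, covs, n_pcs = 5), "zero-variance")
  expect_true("planted" %in% sel)
  expect_false("noise" %in% sel)
  expect_error(pc_covariate_select(m[, 1:4], data.frame(x = rnorm(4)), n_pcs = 6),
               "more samples")
})

test_that("regress_out produces orthogonal residuals and matches OLS", {
  set.seed(23)
  n <- 5
  cov1 <- c(1, 2, 3, 4, 5)
  m <- rbind(f1 = 2 * cov1, f2 = rnorm(n))
  colnames(m) <- sprintf("s%d", 1:n)
  out <- regress_out(m, data.frame(cov1 = cov1))
  ## feature = 2 x covariate -> residual constant at the feature mean
  expect_equal(unname(out["f1", ]), rep(mean(m["f1", ]), n), tolerance = 1e-10)
  ## orthogonality of centered residuals to the covariate
  res <- out - rowMeans(m)
  expect_lt(abs(sum(res["f2", ] * (cov1 - mean(cov1)))),
            1e-8 * sqrt(sum(res["f2", ]^2)) * sqrt(sum(cov1^2)) + 1e-12)
  ## closed-form normal-equation oracle
  X <- cbind(1, cov1)
  beta <- solve(t(X) %*% X, t(X) %*% m["f2", ])
  oracle <- m["f2", ] - as.numeric(X %*% beta) + mean(m["f2", ])
  expect_equal(unname(out["f2", ]), unname(oracle), tolerance = 1e-10)
  ## orthogonal covariate leaves input unchanged
  orth <- rep(c(-1, 1), length.out = n)
  feat <- rbind(f = rep(3, n))
  colnames(feat) <- colnames(m)
  expect_equal(regress_out(feat, data.frame(o = orth)), feat)
  expect_error(regress_out(m, data.frame(a = cov1, b = 2 * cov1)), "collinear")
})
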