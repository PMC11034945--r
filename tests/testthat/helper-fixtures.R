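# shared fixtures built in code; no files on disk

tiny_model <- function(seed = 1) make_genome_model(n_chrom = 1, n_genes = 12,
                                                   n_tfs = 3, seed = seed,
                                                   chrom_length = 150000L)

tiny_sheet <- function() {
  data.frame(
    sample_id = c("s1", "s2", "s3", "s4"),
    subject_id = c("A", "B", "C", "D"),
    pair_id = c("P1", "P1", "P2", "P2"),
    group = c("case", "control", "case", "control"),
    cohort = c("AF", "AF", "AT", "AT"),
    fraction = "NeuNpos", assay = "RNA", replicate = 1L,
    sex = c("M", "M", "F", "F"), age = c(40, 40, 60, 60),
    pmd = c(10, 12, 8, 9), stringsAsFactors = FALSE)
}

## tag_set built directly from explicit positions
manual_tags <- function(plus, minus, chrom_len = 10000L, read_length = 50L,
                        fragment_length = 200L, chrom = "chr1") {
  structure(list(
    tags = setNames(list(list(plus = sort(plus), minus = sort(minus))), chrom),
    read_length = as.integer(read_length),
    fragment_length = as.integer(fragment_length),
    chrom_lengths = setNames(as.integer(chrom_len), chrom)),
    class = "tag_set")
}

## adjusted Rand index (independent of any clustering code under test)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

## brute-force shifted-Pearson cross-correlation oracle
cc_oracle <- function(tags, max_shift) {
  chroms <- names(tags$tags)
  w <- vapply(chroms, function(ch) as.numeric(tags$chrom_lengths[[ch]]), numeric(1))
  vapply(0:max_shift, function(d) {
    vals <- vapply(chroms, function(ch) {
      len <- tags$chrom_lengths[[ch]]
      p <- rep(0, len); m <- rep(0, len)
      p[unique(tags$tags[[ch]]$plus) + 1] <- 1
      m[unique(tags$tags[[ch]]$minus) + 1] <- 1
      suppressWarnings(cor(p[1:(len - d)], m[(1 + d):len]))
    }, numeric(1))
    ok <- is.finite(vals)
    sum(vals[ok] * w[ok]) / sum(w[ok])
  }, numeric(1))
}

## helper: a bin_matrix with planted profile structure
planted_bins <- function(n_profiles, bins_per_profile, n_datasets, snr,
                         seed, bin_size = 5000L) {
  withr::with_seed(seed, {
    n_bins <- n_profiles * bins_per_profile
    cl <- setNames(n_bins * bin_size, "chr1")
    bins <- genome_bins(cl, bin_size)
    profiles <- matrix(rnorm(n_profiles * n_datasets, sd = snr),
                       n_profiles, n_datasets)
    truth <- rep(seq_len(n_profiles), each = bins_per_profile)
    mu <- exp(2 + profiles[truth, ] + matrix(rnorm(n_bins * n_datasets),
                                             n_bins, n_datasets))
    raw <- matrix(rpois(length(mu), mu), n_bins, n_datasets,
                  dimnames = list(NULL, sprintf("d%d", seq_len(n_datasets))))
    list(bm = bin_matrix_from_counts(bins, raw + 1L), truth = truth)
  })
}
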