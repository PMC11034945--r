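## Genome-wide 5 kb-bin signal integration: per-dataset bin counts with
## CPM/log1p normalization, Poisson enrichment detection, K-means
## clustering of standardized bin profiles (with k-means++ seeding and
## restarts), K-means grouping of cluster centroids into sections,
## annotation coverage, and hypergeometric enrichment of differential
## features per cluster. The original signature-detection tool this
## emulates is model-based and iterative; the contract exercised here —
## enriched bins -> profile clusters -> sections -> enrichment — is the
## same, the internals are a documented stand-in.

#' Tile the genome into fixed-width bins
#' @param chrom_lengths named chromosome lengths
#' @param bin_size bin width in bp (default 5000)
#' @return data.frame `chrom`, `start`, `end`, `bin_id`
#' @export
genome_bins <- function(chrom_lengths, bin_size = 5000L) {
  out <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(0L, len - 1L, by = bin_size)
    data.frame(chrom = ch, start = as.integer(starts),
               end = as.integer(pmin(starts + bin_size, len)),
               stringsAsFactors = FALSE)
  }))
  out$bin_id <- sprintf("%s:%d-%d", out$chrom, out$start, out$end)
  out
}

#' Bin tag counts across datasets with CPM/log1p normalization
#'
#' @param tag_sets named list of `tag_set` objects (one per dataset)
#' @param bin_size bin width in bp
#' @return object of class `bin_matrix`: `bins`, `raw` (counts),
#'   `values` (log1p CPM), `datasets`
#' @export
bin_signals <- function(tag_sets, bin_size = 5000L) {
  if (!length(tag_sets)) stop_fmt("need at least one dataset")
  cl <- tag_sets[[1]]$chrom_lengths
  bins <- genome_bins(cl, bin_size)
  raw <- vapply(tag_sets, function(ts) {
    if (n_tags_total(ts) == 0) stop_fmt("dataset with zero tags")
    count_tags_in_intervals(ts, bins)
  }, numeric(nrow(bins)))
  colnames(raw) <- names(tag_sets)
  depth <- colSums(raw)
  values <- log1p(sweep(raw, 2, depth / 1e6, "/"))
  structure(list(bins = bins, raw = raw, values = values,
                 datasets = names(tag_sets)),
            class = "bin_matrix")
}

#' Construct a bin_matrix from precomputed per-bin counts
#' @param bins bin table from [genome_bins()]
#' @param raw bins x datasets count matrix
#' @return a `bin_matrix`
#' @export
bin_matrix_from_counts <- function(bins, raw) {
  raw <- as.matrix(raw)
  stopifnot(nrow(raw) == nrow(bins))
  depth <- colSums(raw)
  if (any(depth == 0)) stop_fmt("dataset with zero counts")
  values <- log1p(sweep(raw, 2, depth / 1e6, "/"))
  structure(list(bins = bins, raw = raw, values = values,
                 datasets = colnames(raw)),
            class = "bin_matrix")
}

#' Select signal-enriched bins
#'
#' Per dataset, the raw bin count gets an upper-tail Poisson p-value
#' against the genome-wide mean, BH-adjusted within the dataset; a bin is
#' kept when significant in at least one dataset.
#'
#' @param bm a `bin_matrix`
#' @param q_cut per-dataset BH q cutoff
#' @return integer indices of enriched bins
#' @export
select_enriched <- function(bm, q_cut = 0.05) {
  sig <- vapply(seq_along(bm$datasets), function(j) {
    v <- bm$raw[, j]
    p <- ppois(v - 1, mean(v), lower.tail = FALSE)
    stats::p.adjust(p, method = "BH") < q_cut
  }, logical(nrow(bm$raw)))
  which(rowSums(sig) > 0)
}

## k-means++ seeding followed by Lloyd iterations; best of `restarts`
kmeanspp <- function(x, k, seed, restarts = 10L, iter_max = 100L) {
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      centers <- matrix(NA_real_, k, ncol(x))
      ci <- sample(nrow(x), 1)
      centers[1, ] <- x[ci, ]
      d2 <- rowSums((x - matrix(centers[1, ], nrow(x), ncol(x), byrow = TRUE))^2)
      if (k > 1) for (j in 2:k) {
        if (sum(d2) == 0) ci <- sample(nrow(x), 1)
        else ci <- sample(nrow(x), 1, prob = d2)
        centers[j, ] <- x[ci, ]
        dj <- rowSums((x - matrix(centers[j, ], nrow(x), ncol(x), byrow = TRUE))^2)
        d2 <- pmin(d2, dj)
      }
      fit <- suppressWarnings(
        kmeans(x, centers = centers, iter.max = iter_max, algorithm = "Lloyd"))
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
  })
  best
}

#' Cluster enriched bins by their multi-dataset signal profile
#'
#' Bin profiles are standardized per dataset (z across bins) and
#' clustered with K-means (k-means++ initialization, 10 restarts, best
#' inertia kept). Deterministic given the seed.
#'
#' @param bm a `bin_matrix`
#' @param enriched integer indices from [select_enriched()]
#' @param n_clusters number of clusters (>= 2, <= number of enriched bins)
#' @param seed integer seed
#' @return object of class `epi_clusters`: `assignment` (cluster id per
#'   enriched bin), `centroids` (clusters x datasets), `enriched`, `bins`
#' @export
cluster_bins <- function(bm, enriched, n_clusters, seed = 1) {
  if (n_clusters < 2) stop_fmt("n_clusters must be >= 2")
  if (n_clusters > length(enriched))
    stop_fmt("n_clusters (%d) exceeds enriched bins (%d)", n_clusters, length(enriched))
  x <- bm$values[enriched, , drop = FALSE]
  x <- scale(x)
  x[, !is.finite(colSums(x))] <- 0
  fit <- kmeanspp(x, n_clusters, seed)
  structure(list(assignment = fit$cluster,
                 centroids = fit$centers,
                 enriched = enriched, bins = bm$bins[enriched, , drop = FALSE],
                 datasets = bm$datasets),
            class = "epi_clusters")
}

#' Group clusters into sections by K-means on the centroids
#'
#' Sections are numbered 1..n by descending mean centroid signal.
#' @param clusters an `epi_clusters`
#' @param n_sections number of sections (<= number of clusters)
#' @param seed integer seed
#' @return integer vector: section id per cluster
#' @export
group_sections <- function(clusters, n_sections = 6L, seed = 1) {
  k <- nrow(clusters$centroids)
  if (n_sections > k) stop_fmt("n_sections (%d) exceeds clusters (%d)", n_sections, k)
  if (n_sections == k) {
    ord <- order(-rowMeans(clusters$centroids))
    return(order(ord))
  }
  fit <- kmeanspp(clusters$centroids, n_sections, seed)
  ## relabel sections by descending mean signal of their member centroids
  sec_mean <- vapply(seq_len(n_sections), function(s) {
    mean(clusters$centroids[fit$cluster == s, , drop = FALSE])
  }, numeric(1))
  relabel <- order(order(-sec_mean))
  relabel[fit$cluster]
}

#' Annotation coverage per cluster
#'
#' For each cluster, the fraction of member-bin bases overlapping
#' promoter windows, gene bodies and intergenic space (mutually exclusive
#' in that priority order, summing to 1), the CpG-island base fraction,
#' and per-chromosome bin fractions.
#'
#' @param clusters an `epi_clusters`
#' @param genes gene annotation (with `body_start`, `body_end`)
#' @param cpg_islands interval data.frame
#' @param promoter_up,promoter_down promoter window extents
#' @return data.frame per cluster with coverage fractions
#' @export
annotate_clusters <- function(clusters, genes, cpg_islands,
                              promoter_up = 4000L, promoter_down = 1000L) {
  pw_gr <- GenomicRanges::reduce(as_granges(promoter_windows(genes, promoter_up, promoter_down)))
  body <- data.frame(chrom = genes$chrom, start = genes$body_start,
                     end = genes$body_end)
  body_gr <- GenomicRanges::setdiff(GenomicRanges::reduce(as_granges(body)), pw_gr)
  cpg_gr <- GenomicRanges::reduce(as_granges(cpg_islands))
  frac_in <- function(bins_gr, target) {
    if (!length(target)) return(0)
    ov <- GenomicRanges::intersect(bins_gr, target)
    sum(GenomicRanges::width(ov)) / sum(GenomicRanges::width(bins_gr))
  }
  chroms <- unique(clusters$bins$chrom)
  out <- lapply(sort(unique(clusters$assignment)), function(cl) {
    b <- clusters$bins[clusters$assignment == cl, , drop = FALSE]
    bg <- GenomicRanges::reduce(as_granges(b))
    prom_f <- frac_in(bg, pw_gr)
    body_f <- frac_in(bg, body_gr)
    row <- data.frame(cluster = cl, n_bins = nrow(b),
                      frac_promoter = prom_f, frac_gene_body = body_f,
                      frac_intergenic = 1 - prom_f - body_f,
                      frac_cpg = frac_in(bg, cpg_gr), stringsAsFactors = FALSE)
    for (ch in chroms)
      row[[paste0("frac_", ch)]] <- mean(b$chrom == ch)
    row
  })
  do.call(rbind, out)
}

#' Hypergeometric enrichment of differential features per cluster
#'
#' With universe N = all enriched bins, marked set K = the cluster's
#' bins, draw n = bins carrying a differential feature: the upper-tail
#' hypergeometric p of the observed overlap k, BH-adjusted across
#' clusters. Selected clusters (fdr < alpha) are ranked by overlap count.
#'
#' @param clusters an `epi_clusters`
#' @param differential_bins indices (into the enriched-bin set) of bins
#'   overlapped by differential features; see [features_to_bins()]
#' @param alpha FDR cutoff for selection
#' @return data.frame per cluster: `cluster`, `k`, `K`, `p`, `fdr`,
#'   `selected`, ordered with selected clusters first by descending `k`
#' @export
cluster_enrichment <- function(clusters, differential_bins, alpha = 0.05) {
  N <- length(clusters$enriched)
  bad <- setdiff(differential_bins, seq_len(N))
  if (length(bad)) stop_fmt("differential bins outside the enriched universe")
  n <- length(unique(differential_bins))
  ids <- sort(unique(clusters$assignment))
  res <- do.call(rbind, lapply(ids, function(cl) {
    members <- which(clusters$assignment == cl)
    k <- length(intersect(members, differential_bins))
    data.frame(cluster = cl, k = k, K = length(members),
               p = hypergeometric_p(k, length(members), n, N),
               stringsAsFactors = FALSE)
  }))
  res$fdr <- bh_adjust(res$p)
  res$selected <- res$fdr < alpha
  res[order(-res$selected, -res$k, res$cluster), , drop = FALSE]
}

#' Map differential features to enriched-bin indices
#'
#' Interval features map to every enriched bin they overlap by >= 1 bp;
#' gene features map to the bin containing their TSS.
#'
#' @param clusters an `epi_clusters`
#' @param features interval data.frame (chrom/start/end) or, with
#'   `genes`, a character vector of gene ids
#' @param genes gene annotation (required for gene-id input)
#' @return integer indices into the enriched-bin set
#' @export
features_to_bins <- function(clusters, features, genes = NULL) {
  if (is.character(features)) {
    if (is.null(genes)) stop_fmt("gene annotation required for gene-id features")
    g <- genes[genes$gene_id %in% features, , drop = FALSE]
    features <- data.frame(chrom = g$chrom, start = g$tss, end = g$tss + 1L)
  }
  if (nrow(features) == 0) return(integer())
  ov <- GenomicRanges::findOverlaps(as_granges(clusters$bins), as_granges(features))
  sort(unique(S4Vectors::queryHits(ov)))
}
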