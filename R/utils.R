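#' @importFrom stats approx cor kmeans lm.fit median optimize p.adjust pchisq
#'   pnorm ppois prcomp pt qchisq quantile rbinom rlnorm rnbinom rnorm runif
#'   sd setNames var wilcox.test rgamma complete.cases
#' @importFrom utils read.csv read.delim write.csv head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

#' Convert 0-based half-open intervals to a GRanges object
#'
#' Internal coordinates are 0-based half-open (BED convention); GRanges is
#' 1-based closed, so start shifts by +1.
#' @param df data.frame with `chrom`, `start`, `end` columns
#' @return a [GenomicRanges::GRanges] object
#' @keywords internal
as_granges <- function(df) {
  strand <- if ("strand" %in% names(df)) df$strand else "*"
  strand[!strand %in% c("+", "-")] <- "*"
  GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand
  )
}

#' Convert a GRanges object back to 0-based half-open intervals
#' @param gr a GRanges
#' @return data.frame with chrom, start, end
#' @keywords internal
granges_to_df <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

## FNV-1a 32-bit over a character scalar; cheap content hash for manifests.
fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 0x811c9dc5
  for (b in bytes) {
    ## XOR touches only the low 8 bits; avoids bitwXor's 32-bit limit
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    ## 32-bit multiply by FNV prime 16777619; 16-bit split keeps every
    ## intermediate below 2^53 so double arithmetic stays exact
    h0 <- h %% 65536
    h1 <- h %/% 65536
    h <- (h0 * 16777619 + ((h1 * 16777619) %% 65536) * 65536) %% 4294967296
  }
  ## h can exceed .Machine$integer.max; format the two 16-bit halves
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

## Run `expr` under a locally-seeded RNG, restoring global state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

## Derive a stream-specific child seed, kept under 2^31.
child_seed <- function(seed, stream) {
  (seed * 1000003 + stream) %% 2147483647L
}
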