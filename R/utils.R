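# Internal helpers shared across modules. All genomic coordinates in this
# package are 0-based half-open; GRanges conversion shifts starts by +1.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded operations do not disturb the global stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# round-half-up; R's round() uses round-half-to-even which is not monotone in
# the way CN chaining expects (3.5 must clear a floor of 4)
round_half_up <- function(x) floor(x + 0.5)

# data.frame(chrom, start, end) [0-based half-open] -> GRanges
as_granges <- function(df) {
  if (nrow(df) == 0L)
    return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end)
  )
}

# GRanges -> data.frame(chrom, start, end) [0-based half-open]
as_regions <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

# indices of grid bins having >= 1 bp overlap with `regions`
bins_in_regions <- function(grid, regions) {
  if (nrow(regions) == 0L) return(integer(0))
  hits <- GenomicRanges::findOverlaps(as_granges(grid), as_granges(regions))
  sort(unique(S4Vectors::queryHits(hits)))
}

# total bases of `a` covered by the union of `b`
covered_bases <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(numeric(nrow(a)))
  ga <- as_granges(a)
  gb <- GenomicRanges::reduce(as_granges(b))
  hits <- GenomicRanges::findOverlaps(ga, gb)
  ov <- GenomicRanges::pintersect(ga[S4Vectors::queryHits(hits)],
                                  gb[S4Vectors::subjectHits(hits)])
  out <- numeric(nrow(a))
  if (length(hits)) {
    w <- tapply(GenomicRanges::width(ov), S4Vectors::queryHits(hits), sum)
    out[as.integer(names(w))] <- as.numeric(w)
  }
  out
}

# sort a region data.frame by (chromosome in grid order, start)
sort_regions <- function(df, chrom_levels = NULL) {
  if (is.null(chrom_levels)) chrom_levels <- unique(df$chrom)
  ord <- order(match(df$chrom, chrom_levels), df$start)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# derive a stream-specific 32-bit seed from a user seed
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + k) %% 2147483647)
}
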