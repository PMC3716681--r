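# Cross-individual CNVR calling: merge per-individual MCRs, build the
# region x individual CN matrix, and call variable regions by CN dispersion.

#' Merge MCRs across individuals into common regions
#'
#' Single-linkage union: overlapping or book-ended (shared boundary)
#' intervals from any individuals are merged transitively. The result is
#' independent of individual order and of how MCRs are split.
#'
#' @param mcrs an `mcr_set` data frame (possibly concatenated across
#'   individuals) or a list of them.
#' @param chrom_levels optional chromosome ordering for the output.
#' @return data frame of merged regions: chrom, start, end.
#' @export
merge_mcrs <- function(mcrs, chrom_levels = NULL) {
  df <- if (is.data.frame(mcrs)) mcrs else do.call(rbind, mcrs)
  if (is.null(df) || !nrow(df))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE))
  merged <- as_regions(GenomicRanges::reduce(as_granges(df)))
  sort_regions(merged, chrom_levels %||% unique(df$chrom))
}

#' Build the region x individual copy-number matrix
#'
#' Cell (r, i) is the mean continuous CN of individual i over the
#' non-excluded bins of region r; individuals without an MCR in r still get
#' their (near-diploid) value, so the matrix has no missing cells.
#'
#' @param regions merged regions from [merge_mcrs()].
#' @param cn_tracks named list of `cn_track`, one per individual.
#' @param grid a `bin_grid`.
#' @return `cn_matrix` object: list(regions, cn) with `cn` a numeric matrix,
#'   one column per individual.
#' @export
build_cn_matrix <- function(regions, cn_tracks, grid) {
  ids <- vapply(cn_tracks, function(t) t$id, character(1))
  names(cn_tracks) <- ids
  m <- matrix(NA_real_, nrow = nrow(regions), ncol = length(ids),
              dimnames = list(NULL, ids))
  if (nrow(regions)) {
    hits <- GenomicRanges::findOverlaps(as_granges(grid), as_granges(regions))
    bin_of <- S4Vectors::queryHits(hits)
    reg_of <- S4Vectors::subjectHits(hits)
    for (id in ids) {
      tr <- cn_tracks[[id]]
      ok <- !tr$excluded[bin_of] & !is.na(tr$cn[bin_of])
      mu <- tapply(tr$cn[bin_of[ok]], reg_of[ok], mean)
      m[as.integer(names(mu)), id] <- as.numeric(mu)
    }
  }
  structure(list(regions = regions, cn = m), class = "cn_matrix")
}

#' @export
print.cn_matrix <- function(x, ...) {
  cat(sprintf("cn_matrix: %d regions x %d individuals\n",
              nrow(x$regions), ncol(x$cn)))
  invisible(x)
}

#' Call copy-number-variable regions by CN dispersion
#'
#' Regions whose sample standard deviation (n - 1 denominator) of CN across
#' individuals reaches `sd_threshold` (inclusive) are CNVRs; the rest are
#' invariant multi-copy regions. At least two individuals are required for
#' the s.d. to be defined.
#'
#' @param mat a [build_cn_matrix()] result.
#' @param sd_threshold calling threshold on the CN standard deviation.
#' @param min_size minimum region size in bases.
#' @return `cnvr_set` data frame: chrom, start, end, sd, size; attributes
#'   `cn` (the CNVR rows of the CN matrix) and `invariant` (regions not
#'   called).
#' @export
call_cnvrs <- function(mat, sd_threshold = 0.7, min_size = 6000) {
  if (ncol(mat$cn) < 2)
    stop("undefined s.d.: the CN matrix needs at least two individuals",
         call. = FALSE)
  sds <- apply(mat$cn, 1, sd, na.rm = TRUE)
  size <- mat$regions$end - mat$regions$start
  call <- !is.na(sds) & sds >= sd_threshold & size >= min_size
  out <- data.frame(mat$regions[call, , drop = FALSE],
                    sd = sds[call], size = size[call],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "cn") <- mat$cn[call, , drop = FALSE]
  attr(out, "invariant") <- data.frame(mat$regions[!call, , drop = FALSE],
                                       sd = sds[!call], size = size[!call])
  class(out) <- c("cnvr_set", "data.frame")
  out
}

#' @export
print.cnvr_set <- function(x, ...) {
  cat(sprintf("cnvr_set: %d CNVRs, %.2f Mb, mean size %.1f kb\n",
              nrow(x), sum(x$size) / 1e6,
              if (nrow(x)) mean(x$size) / 1e3 else 0))
  invisible(x)
}

#' Catalog statistics for a CNVR set
#'
#' @param cnvrs a `cnvr_set`.
#' @param grid a `bin_grid` (for chromosome lengths).
#' @return list(count, mean_size_kb, total_mb, genome_fraction_pct,
#'   per_chrom) where `per_chrom` gives CNVR bases and density (% of
#'   chromosome length) per chromosome.
#' @export
catalog_stats <- function(cnvrs, grid) {
  cl <- attr(grid, "chrom_lengths")
  bases_by_chrom <- vapply(names(cl), function(ch) {
    sum(cnvrs$size[cnvrs$chrom == ch])
  }, numeric(1))
  per_chrom <- data.frame(chrom = names(cl), cnvr_bases = bases_by_chrom,
                          length = as.numeric(cl),
                          density_pct = 100 * bases_by_chrom / as.numeric(cl),
                          stringsAsFactors = FALSE)
  rownames(per_chrom) <- NULL
  total <- sum(cnvrs$size)
  list(count = nrow(cnvrs),
       mean_size_kb = if (nrow(cnvrs)) mean(cnvrs$size) / 1e3 else 0,
       total_mb = total / 1e6,
       genome_fraction_pct = 100 * total / sum(cl),
       per_chrom = per_chrom)
}
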