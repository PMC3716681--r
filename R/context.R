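# Genomic context of CNVRs: flanking-interval construction, repeat-family
# densities, Fisher enrichment, SD proximity, and GC contrasts.

#' Fixed-width flanking intervals of a region set
#'
#' One interval of `width` bases on each side of each region, clipped at
#' chromosome ends (clipped intervals are kept with reduced width and
#' flagged). Zero-width results are dropped.
#'
#' @param regions BED-like data frame.
#' @param grid a `bin_grid` (for chromosome bounds).
#' @param width flank width in bases.
#' @param label set label carried on the result.
#' @return `flank_set`: list(label, intervals (chrom, start, end, clipped),
#'   width, count).
#' @export
make_flank_intervals <- function(regions, grid, width = 10000,
                                 label = "flank") {
  cl <- attr(grid, "chrom_lengths")
  left <- data.frame(chrom = regions$chrom,
                     start = pmax(0, regions$start - width),
                     end = regions$start, stringsAsFactors = FALSE)
  right <- data.frame(chrom = regions$chrom, start = regions$end,
                      end = pmin(as.numeric(cl[regions$chrom]),
                                 regions$end + width),
                      stringsAsFactors = FALSE)
  iv <- rbind(left, right)
  iv$clipped <- (iv$end - iv$start) < width
  iv <- iv[iv$end > iv$start, , drop = FALSE]
  iv <- sort_regions(iv, names(cl))
  structure(list(label = label, intervals = iv, width = width,
                 count = nrow(iv)), class = "flank_set")
}

#' @export
print.flank_set <- function(x, ...) {
  cat(sprintf("flank_set '%s': %d intervals of %d b (%d clipped)\n",
              x$label, x$count, x$width, sum(x$intervals$clipped)))
  invisible(x)
}

#' Background ("other") intervals tiling the rest of the genome
#'
#' Tiles the genome outside the given region/flank sets into fixed-width
#' intervals; the trailing remainder of each uncovered segment (shorter than
#' `width`) is dropped, so "other" intervals share no base with any excluded
#' set and have constant width.
#'
#' @param exclude list of BED-like data frames (regions and flank interval
#'   sets) to stay clear of; `flank_set` objects are accepted.
#' @param grid a `bin_grid`.
#' @param width interval width in bases.
#' @return `flank_set` labelled `"other"`.
#' @export
other_intervals <- function(exclude, grid, width = 10000) {
  cl <- attr(grid, "chrom_lengths")
  ex <- do.call(rbind, lapply(exclude, function(e) {
    df <- if (inherits(e, "flank_set")) e$intervals else e
    df[, c("chrom", "start", "end"), drop = FALSE]
  }))
  genome <- data.frame(chrom = names(cl), start = 0, end = as.numeric(cl),
                       stringsAsFactors = FALSE)
  free <- if (is.null(ex) || !nrow(ex)) genome
  else as_regions(GenomicRanges::setdiff(as_granges(genome), as_granges(ex)))
  iv <- do.call(rbind, lapply(seq_len(nrow(free)), function(i) {
    n <- floor((free$end[i] - free$start[i]) / width)
    if (n < 1) return(NULL)
    s <- free$start[i] + width * (0:(n - 1))
    data.frame(chrom = free$chrom[i], start = s, end = s + width,
               stringsAsFactors = FALSE)
  }))
  if (is.null(iv))
    iv <- data.frame(chrom = character(0), start = numeric(0),
                     end = numeric(0))
  iv$clipped <- rep(FALSE, nrow(iv))
  iv <- sort_regions(iv, names(cl))
  structure(list(label = "other", intervals = iv, width = width,
                 count = nrow(iv)), class = "flank_set")
}

#' Repeat-family base densities over an interval set
#'
#' Total bases of each repeat family intersecting the set's intervals,
#' divided by the interval count (mean bases per interval). Density is
#' invariant to fragmenting a repeat record into adjacent pieces.
#'
#' @param set a `flank_set`.
#' @param repeats BED-like data frame with a `family` column.
#' @param families families to report (default: all present).
#' @return data frame: family, bases, density.
#' @export
repeat_density <- function(set, repeats, families = NULL) {
  families <- families %||% sort(unique(repeats$family))
  iv <- set$intervals
  bases <- vapply(families, function(f) {
    r <- repeats[repeats$family == f, , drop = FALSE]
    sum(covered_bases(iv, r))
  }, numeric(1))
  data.frame(family = families, bases = as.numeric(bases),
             density = as.numeric(bases) / max(set$count, 1),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value by summation of hypergeometric point
#' probabilities no larger than the observed one (computed through
#' `dhyper`'s log-gamma machinery, so margins in the millions are fine).
#'
#' @param a,b,c,d cell counts: rows are the two classes (e.g. family /
#'   non-family bases), columns the two interval sets.
#' @return p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("cell counts must be non-negative integers", call. = FALSE)
  K <- a + b          # class-1 total
  n1 <- a + c         # column-1 total
  N <- a + b + c + d
  if (K == 0 || K == N || n1 == 0 || n1 == N)
    stop("undefined test: a table margin is empty", call. = FALSE)
  support <- max(0, n1 - (N - K)):min(K, n1)
  dens <- dhyper(support, K, N - K, n1)
  d_obs <- dhyper(a, K, N - K, n1)
  min(1, sum(dens[dens <= d_obs * (1 + 1e-7)]))
}

#' Enrichment of a repeat family in one interval set versus another
#'
#' Builds the 2x2 table of (family bases, non-family bases) by (set, other)
#' and tests it, by default with the exact two-sided Fisher test on base
#' counts; `method = "chisq"` uses the chi-square approximation for speed.
#'
#' @param family repeat family name.
#' @param set,other two `flank_set`s to contrast.
#' @param repeats BED-like repeat data frame with a `family` column.
#' @param method `"fisher"` (exact) or `"chisq"`.
#' @return p-value, with the 2x2 table attached as attribute `table`.
#' @export
enrichment_test <- function(family, set, other, repeats,
                            method = c("fisher", "chisq")) {
  method <- match.arg(method)
  fam_set <- sum(covered_bases(set$intervals,
                               repeats[repeats$family == family, ]))
  fam_oth <- sum(covered_bases(other$intervals,
                               repeats[repeats$family == family, ]))
  tot_set <- sum(set$intervals$end - set$intervals$start)
  tot_oth <- sum(other$intervals$end - other$intervals$start)
  tab <- matrix(c(fam_set, fam_oth, tot_set - fam_set, tot_oth - fam_oth),
                2, 2, byrow = TRUE,
                dimnames = list(c("family", "non_family"),
                                c(set$label, other$label)))
  p <- if (method == "fisher")
    fisher_exact_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
  else stats::chisq.test(tab, correct = FALSE)$p.value
  attr(p, "table") <- tab
  p
}

#' Percentage helper for SD/CNVR proximity
#'
#' `100 * count / total`, truncated (not rounded) to one decimal, matching
#' the "approximately" convention of proximity reports.
#'
#' @param count,total counts.
#' @return truncated percentage.
#' @export
flank_overlap_percent <- function(count, total) {
  floor(1000 * count / total) / 10
}

#' Segmental duplications near CNVRs
#'
#' Counts SDs that intersect any CNVR expanded by `flank` bases on both
#' sides (i.e. SDs overlapping or within `flank` of a CNVR).
#'
#' @param sds,cnvrs BED-like data frames.
#' @param grid a `bin_grid` (for clipping the expansion).
#' @param flank expansion in bases.
#' @return list(count, total, percent (truncated to one decimal),
#'   percent_exact).
#' @export
sd_cnvr_overlap <- function(sds, cnvrs, grid, flank = 10000) {
  cl <- attr(grid, "chrom_lengths")
  exp_ <- data.frame(chrom = cnvrs$chrom,
                     start = pmax(0, cnvrs$start - flank),
                     end = pmin(as.numeric(cl[cnvrs$chrom]),
                                cnvrs$end + flank),
                     stringsAsFactors = FALSE)
  hit <- covered_bases(sds, exp_) > 0
  list(count = sum(hit), total = nrow(sds),
       percent = flank_overlap_percent(sum(hit), nrow(sds)),
       percent_exact = 100 * sum(hit) / nrow(sds))
}

#' GC content of CNVRs, their flanks, and the rest of the genome
#'
#' Mean per-bin GC fraction (bins have constant width, so the plain mean is
#' the base-weighted mean) over CNVR bins, flank bins (excluding CNVR bins),
#' and all remaining bins, with the differences reported in percentage
#' points.
#'
#' @param cnvrs BED-like CNVR data frame.
#' @param grid a `bin_grid`.
#' @param flank flank width in bases.
#' @return list(gc_cnvr, gc_flank, gc_other, diff_cnvr_pct, diff_flank_pct)
#'   where the differences are (other - cnvr) and (other - flank) in
#'   percentage points.
#' @export
gc_contrast <- function(cnvrs, grid, flank = 10000) {
  in_cnvr <- rep(FALSE, nrow(grid))
  in_cnvr[bins_in_regions(grid, cnvrs)] <- TRUE
  fl <- make_flank_intervals(cnvrs, grid, flank, label = "cnvr_flank")
  in_flank <- rep(FALSE, nrow(grid))
  in_flank[bins_in_regions(grid, fl$intervals)] <- TRUE
  in_flank <- in_flank & !in_cnvr
  other <- !in_cnvr & !in_flank
  list(gc_cnvr = mean(grid$gc[in_cnvr]),
       gc_flank = mean(grid$gc[in_flank]),
       gc_other = mean(grid$gc[other]),
       diff_cnvr_pct = 100 * (mean(grid$gc[other]) - mean(grid$gc[in_cnvr])),
       diff_flank_pct = 100 * (mean(grid$gc[other]) - mean(grid$gc[in_flank])))
}
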