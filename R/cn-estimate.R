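# Copy-number estimation: two-stage diploid baseline + per-GC-interval
# correction factors. Depth of an included bin is first normalised to
# "effective depth per mappable base", depth / (1 - masked_frac), so partial
# repeat masking does not depress CN; bins with masked_frac > mask_max are
# excluded from estimation and from calling.

effective_depth <- function(track, grid, mask_max = 0.8) {
  excl <- grid$masked > mask_max | track$excluded
  eff <- track$depth / (1 - pmin(grid$masked, mask_max))
  eff[excl] <- NA_real_
  list(eff = eff, excluded = excl)
}

#' Seed the diploid baseline from 1:1-ortholog regions
#'
#' First-stage estimate of the mean diploid depth D: the mean
#' mappability-normalised depth over non-excluded autosomal bins
#' intersecting the ortholog regions, which are taken as putatively diploid
#' anchors (X orthologs are skipped: they are haploid in males).
#'
#' @param track raw `depth_track`.
#' @param orthologs BED-like data frame of ortholog gene regions.
#' @param grid a `bin_grid`.
#' @param mask_max bins with masked fraction above this are excluded.
#' @param min_bins minimum supporting bin count; fewer is an error
#'   (baseline unstable).
#' @return `diploid_baseline` object: list(D, stage = "ortholog_seed",
#'   bins, n).
#' @export
seed_baseline <- function(track, orthologs, grid, mask_max = 0.8,
                          min_bins = 200) {
  ed <- effective_depth(track, grid, mask_max)
  idx <- bins_in_regions(grid, orthologs)
  idx <- idx[!ed$excluded[idx]]
  # only autosomal anchors: X orthologs are haploid in males
  xch <- attr(grid, "x_chrom")
  if (!is.null(xch) && !is.na(xch))
    idx <- idx[grid$chrom[idx] != xch]
  if (length(idx) < min_bins)
    stop(sprintf(
      "baseline unstable: only %d non-excluded ortholog bins (need >= %d)",
      length(idx), min_bins), call. = FALSE)
  structure(list(D = mean(ed$eff[idx]), stage = "ortholog_seed",
                 bins = idx, n = length(idx)),
            class = "diploid_baseline")
}

#' @export
print.diploid_baseline <- function(x, ...) {
  cat(sprintf("diploid_baseline (%s): D = %.4f from %d bins\n",
              x$stage, x$D, x$n))
  invisible(x)
}

#' Predict genome-wide diploid bins from the seeded baseline
#'
#' Second-stage refinement: every non-excluded bin whose provisional CN
#' `2 * depth / D` falls inside the diploid window is returned. Because the
#' returned set is genome-wide it breaks the elevated-GC composition of the
#' coding-region seed set before GC factors are estimated.
#'
#' @param track raw `depth_track`.
#' @param baseline a stage-`ortholog_seed` [seed_baseline()] result.
#' @param grid a `bin_grid`.
#' @param window provisional-CN window treated as diploid.
#' @param mask_max exclusion threshold on masked fraction.
#' @return integer vector of bin indices.
#' @export
predict_diploid_bins <- function(track, baseline, grid,
                                 window = c(1.5, 2.5), mask_max = 0.8) {
  if (baseline$stage != "ortholog_seed")
    stop("predict_diploid_bins needs the first-stage (ortholog_seed) baseline",
         call. = FALSE)
  ed <- effective_depth(track, grid, mask_max)
  cn <- 2 * ed$eff / baseline$D
  idx <- which(!ed$excluded & cn >= window[1] & cn <= window[2])
  if (!length(idx))
    stop("refinement failed: no bins fall in the diploid window", call. = FALSE)
  idx
}

#' Estimate per-GC-interval depth correction factors
#'
#' Partitions [0, 1] into GC intervals of `width` and, over the predicted
#' diploid bins, sets each interval's factor to
#' (mean depth over all diploid bins) / (mean depth over diploid bins in the
#' interval). Intervals supported by fewer than `min_support` diploid bins
#' are merged into the nearest well-supported interval before factors are
#' computed (and flagged); unpopulated intervals inherit the factor of the
#' nearest populated one so the table covers all of [0, 1].
#'
#' @param track raw `depth_track`.
#' @param diploid_bins integer bin indices from [predict_diploid_bins()].
#' @param grid a `bin_grid`.
#' @param width GC interval width (default 0.01).
#' @param min_support minimum diploid bins per interval before merging.
#' @param mask_max exclusion threshold on masked fraction.
#' @return `gc_correction` data frame: gc_lo, gc_hi, factor, support, merged;
#'   attributes `width` and `mean_depth`.
#' @export
estimate_gc_correction <- function(track, diploid_bins, grid, width = 0.01,
                                   min_support = 50, mask_max = 0.8) {
  if (!length(diploid_bins))
    stop("diploid_bins must be non-empty", call. = FALSE)
  ed <- effective_depth(track, grid, mask_max)
  eff <- ed$eff[diploid_bins]
  gc <- grid$gc[diploid_bins]
  breaks <- seq(0, 1, by = width)
  n_int <- length(breaks) - 1L
  iv <- pmin(pmax(findInterval(gc, breaks, rightmost.closed = TRUE), 1L), n_int)
  support <- tabulate(iv, nbins = n_int)
  sums <- rep(0, n_int)
  agg <- tapply(eff, iv, sum)
  sums[as.integer(names(agg))] <- as.numeric(agg)
  overall <- mean(eff)

  rich <- which(support >= min_support)
  if (length(rich) <= 1L) {
    populated <- which(support > 0)
    if (length(populated) <= 1L)
      warning("degenerate GC table: all diploid bins fall in one interval; factors set to 1")
    if (length(rich) == 0L)
      rich <- populated  # no interval clears min_support: keep populated ones
  }
  # attach every poor/empty interval to the nearest rich interval
  group <- integer(n_int)
  if (length(rich)) {
    for (i in seq_len(n_int))
      group[i] <- rich[which.min(abs(rich - i))]
  } else group <- rep(1L, n_int)
  group[rich] <- rich
  g_sum <- tapply(sums, group, sum)
  g_n <- tapply(support, group, sum)
  g_mean <- as.numeric(g_sum) / pmax(as.numeric(g_n), 1)
  factor_by_group <- ifelse(as.numeric(g_n) > 0 & g_mean > 0,
                            overall / g_mean, 1)
  names(factor_by_group) <- names(g_sum)
  fac <- factor_by_group[as.character(group)]
  fac[!is.finite(fac)] <- 1
  populated <- which(support > 0)
  if (length(populated) <= 1L) fac <- rep(1, n_int)

  tab <- data.frame(gc_lo = breaks[-length(breaks)], gc_hi = breaks[-1],
                    factor = as.numeric(fac), support = support,
                    merged = support < min_support)
  attr(tab, "width") <- width
  attr(tab, "mean_depth") <- overall
  class(tab) <- c("gc_correction", "data.frame")
  tab
}

#' @export
print.gc_correction <- function(x, ...) {
  used <- x$support > 0
  cat(sprintf(
    "gc_correction: %d intervals of width %.3g; %d populated; factors %.3f-%.3f\n",
    nrow(x), attr(x, "width"), sum(used),
    min(x$factor[used]), max(x$factor[used])))
  invisible(x)
}

# factor applicable to each bin of the grid
gc_factor_for_bins <- function(table, grid) {
  width <- attr(table, "width")
  n_int <- nrow(table)
  iv <- pmin(pmax(findInterval(grid$gc, c(table$gc_lo, 1),
                               rightmost.closed = TRUE), 1L), n_int)
  table$factor[iv]
}

#' Apply GC correction factors to a raw depth track
#'
#' `corrected_b = raw_b * factor(interval containing gc_b)`. Exclusion flags
#' propagate unchanged.
#'
#' @param track raw `depth_track`.
#' @param table a [estimate_gc_correction()] table.
#' @param grid a `bin_grid`.
#' @return a GC-corrected `depth_track`.
#' @export
correct_depth <- function(track, table, grid) {
  if (isTRUE(track$corrected))
    stop("track is already GC-corrected", call. = FALSE)
  depth_track(track$id, track$depth * gc_factor_for_bins(table, grid),
              corrected = TRUE, excluded = track$excluded)
}

#' Refine the diploid baseline on corrected depth
#'
#' Final-stage baseline: mean mappability-normalised GC-corrected depth over
#' the predicted diploid bins.
#'
#' @param track GC-corrected `depth_track`.
#' @param diploid_bins integer bin indices.
#' @param grid a `bin_grid`.
#' @param mask_max exclusion threshold on masked fraction.
#' @return `diploid_baseline` with stage `"refined"`.
#' @export
refine_baseline <- function(track, diploid_bins, grid, mask_max = 0.8) {
  if (!isTRUE(track$corrected))
    stop("refine_baseline expects a GC-corrected track", call. = FALSE)
  ed <- effective_depth(track, grid, mask_max)
  idx <- diploid_bins[!ed$excluded[diploid_bins]]
  if (!length(idx))
    stop("baseline unstable: no non-excluded diploid bins", call. = FALSE)
  structure(list(D = mean(ed$eff[idx]), stage = "refined",
                 bins = idx, n = length(idx)),
            class = "diploid_baseline")
}

#' Estimate the per-bin copy-number track
#'
#' `CN_b = 2 * corrected_b / D` on autosomes and on the female X; male X bins
#' outside the pseudo-autosomal region are doubled
#' (`CN_b = 2 * (2 * corrected_b) / D`) so male and female X tracks are
#' comparable; PAR bins follow the autosomal rule. Excluded bins carry `NA`
#' and are flagged, never silently 0.
#'
#' @param track GC-corrected `depth_track`.
#' @param baseline a stage-`refined` [refine_baseline()] result.
#' @param grid a `bin_grid`.
#' @param sex `"M"` or `"F"`.
#' @param par BED-like data frame of pseudo-autosomal regions on X.
#' @param mask_max exclusion threshold on masked fraction.
#' @return `cn_track` object: list(id, cn, excluded).
#' @export
estimate_cn <- function(track, baseline, grid, sex = "F",
                        par = NULL, mask_max = 0.8) {
  if (baseline$stage != "refined")
    stop("estimate_cn needs the refined-stage baseline", call. = FALSE)
  if (!is.finite(baseline$D) || baseline$D <= 0)
    stop("copy-number estimation failed: non-positive diploid baseline",
         call. = FALSE)
  ed <- effective_depth(track, grid, mask_max)
  cn <- 2 * ed$eff / baseline$D
  xch <- attr(grid, "x_chrom")
  if (identical(sex, "M") && !is.na(xch)) {
    on_x <- grid$chrom == xch
    in_par <- rep(FALSE, nrow(grid))
    if (!is.null(par) && nrow(par))
      in_par[bins_in_regions(grid, par)] <- TRUE
    cn[on_x & !in_par] <- 2 * cn[on_x & !in_par]
  }
  structure(list(id = track$id, cn = cn, excluded = ed$excluded),
            class = "cn_track")
}

#' @export
print.cn_track <- function(x, ...) {
  cat(sprintf("cn_track '%s': %d bins (%d excluded), median CN %.2f\n",
              x$id, length(x$cn), sum(x$excluded),
              stats::median(x$cn, na.rm = TRUE)))
  invisible(x)
}

#' Run the full per-individual copy-number estimation
#'
#' Convenience driver for one individual: seed the baseline on ortholog
#' regions, predict genome-wide diploid bins, estimate and apply GC factors,
#' refine the baseline, and estimate the CN track.
#'
#' @param track raw `depth_track`.
#' @param genome a [simulate_genome()] object (or any list with `grid`,
#'   `orthologs`, `par`).
#' @param sex `"M"` or `"F"`.
#' @param gc_width,min_support GC table parameters.
#' @param diploid_window provisional-CN window for refinement.
#' @param mask_max exclusion threshold on masked fraction.
#' @param min_ortholog_bins minimum seed-support bins.
#' @return Object of class `cn_fit`: list(cn (a `cn_track`), corrected,
#'   gc_table, baseline_seed, baseline, diploid_bins).
#' @export
estimate_cn_track <- function(track, genome, sex = "F", gc_width = 0.01,
                              min_support = 50, diploid_window = c(1.5, 2.5),
                              mask_max = 0.8, min_ortholog_bins = 200) {
  grid <- genome$grid
  b0 <- seed_baseline(track, genome$orthologs, grid, mask_max,
                      min_ortholog_bins)
  dip <- predict_diploid_bins(track, b0, grid, diploid_window, mask_max)
  tab <- estimate_gc_correction(track, dip, grid, gc_width, min_support,
                                mask_max)
  corr <- correct_depth(track, tab, grid)
  b1 <- refine_baseline(corr, dip, grid, mask_max)
  cn <- estimate_cn(corr, b1, grid, sex = sex, par = genome$par, mask_max)
  structure(list(cn = cn, corrected = corr, gc_table = tab,
                 baseline_seed = b0, baseline = b1, diploid_bins = dip),
            class = "cn_fit")
}

#' @export
print.cn_fit <- function(x, ...) {
  cat(sprintf("cn_fit '%s': D %.3f -> %.3f (seed -> refined), %d diploid bins\n",
              x$cn$id, x$baseline_seed$D, x$baseline$D, length(x$diploid_bins)))
  print(x$cn)
  invisible(x)
}
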