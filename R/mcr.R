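# Multi-copy region (MCR) detection: chaining of high-CN bins per individual.

#' Chain high-copy-number bins into multi-copy regions
#'
#' Scans each chromosome of a CN track for maximal runs of non-excluded bins
#' whose copy number clears the gain floor and emits runs spanning at least
#' `min_len` bases. In the default integer mode a bin qualifies when its CN
#' rounded half-up reaches `cn_floor` (CN 4 chains, CN 3 never does); with
#' `continuous = TRUE` the raw estimate is compared against `cn_floor - 1`
#' (CN > 3). Bins with estimated CN below `min_cn_keep` are dropped before
#' chaining (they cannot be gains). Up to `max_gap_bins` interior
#' below-threshold bins may be bridged between qualifying bins; the default
#' 0 is strict contiguity for every evidence-bearing bin. Excluded bins (no
#' usable depth, e.g. heavily repeat-masked) carry no evidence for or
#' against a gain and by default never break a chain
#' (`bridge_excluded = TRUE`); regions still start and end on qualifying
#' bins.
#'
#' @param cn a `cn_track` (refined-baseline estimates).
#' @param grid a `bin_grid`.
#' @param min_len minimum region span in bases (multiple of the bin size).
#' @param cn_floor integer gain floor (default 4, i.e. CN > 3).
#' @param max_gap_bins interior gap tolerance in bins.
#' @param min_cn_keep pre-filter: bins with CN below this are discarded
#'   before chaining.
#' @param continuous compare continuous CN > `cn_floor - 1` instead of
#'   rounded CN >= `cn_floor`.
#' @param bridge_excluded treat excluded bins as evidence-free bridges; when
#'   FALSE they count against `max_gap_bins` like below-threshold bins.
#' @return `mcr_set` data frame: chrom, start, end, individual, mean_cn,
#'   n_bins; sorted, non-overlapping within the individual.
#' @export
call_mcrs <- function(cn, grid, min_len = 6000, cn_floor = 4L,
                      max_gap_bins = 0L, min_cn_keep = 1,
                      continuous = FALSE, bridge_excluded = TRUE) {
  bs <- attr(grid, "bin_size")
  if (min_len < bs)
    stop("invalid parameter: min_len must be at least one bin", call. = FALSE)
  if (min_len %% bs != 0)
    stop("invalid parameter: min_len must be a multiple of the bin size",
         call. = FALSE)
  v <- cn$cn
  no_evidence <- cn$excluded | is.na(v)
  usable <- !no_evidence & v >= min_cn_keep
  pass <- usable & if (continuous) v > (cn_floor - 1)
                   else round_half_up(v) >= cn_floor
  # observed bins that argue against a gain; evidence-free bins optionally
  # bridge without counting towards the gap budget
  fail <- !pass & if (bridge_excluded) !no_evidence else TRUE
  cum_fail <- cumsum(fail)
  out <- list()
  for (ch in unique(grid$chrom)) {
    idx <- which(pass & grid$chrom == ch)
    if (!length(idx)) next
    # fails strictly between consecutive passing bins
    gap_fail <- cum_fail[idx[-1]] - cum_fail[idx[-length(idx)]]
    brk <- c(0L, which(gap_fail > max_gap_bins), length(idx))
    for (k in seq_len(length(brk) - 1L)) {
      run <- idx[(brk[k] + 1L):brk[k + 1L]]
      first <- run[1]; last <- run[length(run)]
      span <- grid$end[last] - grid$start[first]
      if (span < min_len) next
      span_bins <- first:last
      keep <- span_bins[!no_evidence[span_bins]]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = grid$start[first], end = grid$end[last],
        individual = cn$id, mean_cn = mean(v[keep]),
        n_bins = length(keep), stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out)
  else data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                  individual = character(0), mean_cn = numeric(0),
                  n_bins = integer(0), stringsAsFactors = FALSE)
  res <- sort_regions(res, unique(grid$chrom))
  class(res) <- c("mcr_set", "data.frame")
  res
}

#' Cohort arithmetic on per-individual MCR counts
#'
#' Total and average MCR count for a cohort given each individual's count;
#' the same arithmetic [summarize_mcrs()] applies to called regions. The
#' average is reported raw and rounded to the nearest integer.
#'
#' @param counts numeric vector of per-individual MCR counts.
#' @return list(total, mean, mean_rounded, n_individuals).
#' @export
cohort_mcr_summary <- function(counts) {
  if (!length(counts)) stop("counts must be non-empty", call. = FALSE)
  list(total = sum(counts), mean = sum(counts) / length(counts),
       mean_rounded = round_half_up(sum(counts) / length(counts)),
       n_individuals = length(counts))
}

#' Summarise MCR calls per individual and cohort-wide
#'
#' @param mcrs a single `mcr_set`, a list of them, or a combined data frame
#'   with an `individual` column.
#' @return list with `per_individual` (data frame: individual, count,
#'   total_mb, min_kb, mean_kb, max_kb) and `cohort`
#'   (from [cohort_mcr_summary()], plus total_mb).
#' @export
summarize_mcrs <- function(mcrs) {
  df <- if (is.data.frame(mcrs)) mcrs else do.call(rbind, mcrs)
  if (is.null(df) || !nrow(df)) {
    per <- data.frame(individual = character(0), count = integer(0),
                      total_mb = numeric(0), min_kb = numeric(0),
                      mean_kb = numeric(0), max_kb = numeric(0))
    return(list(per_individual = per,
                cohort = list(total = 0, mean = NaN, mean_rounded = NaN,
                              n_individuals = 0, total_mb = 0)))
  }
  size <- df$end - df$start
  per <- do.call(rbind, lapply(split(seq_len(nrow(df)), df$individual),
    function(i) data.frame(
      individual = df$individual[i[1]], count = length(i),
      total_mb = sum(size[i]) / 1e6, min_kb = min(size[i]) / 1e3,
      mean_kb = mean(size[i]) / 1e3, max_kb = max(size[i]) / 1e3,
      stringsAsFactors = FALSE)))
  per <- per[order(per$individual), , drop = FALSE]
  rownames(per) <- NULL
  cohort <- cohort_mcr_summary(per$count)
  cohort$total_mb <- sum(per$total_mb)
  list(per_individual = per, cohort = cohort)
}
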