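# Independent brute-force reimplementations used as oracles. These are
# deliberately naive (per-base, per-window, full enumeration) and share no
# code with the package internals they check.

# all maximal qualifying chains by exhaustive window enumeration
oracle_chain <- function(cn_vals, excluded, grid, min_len = 6000,
                         cn_floor = 4, max_gap = 0, bridge_excluded = TRUE) {
  no_ev <- excluded | is.na(cn_vals)
  pass <- !no_ev & cn_vals >= 1 & floor(cn_vals + 0.5) >= cn_floor
  fail <- !pass & (if (bridge_excluded) !no_ev else TRUE)
  gap_ok <- function(i, j) {
    # every adjacent pair of passing bins in [i, j] within the gap budget
    pp <- (i:j)[pass[i:j]]
    if (length(pp) < 2) return(TRUE)
    for (k in seq_len(length(pp) - 1)) {
      if (pp[k + 1] > pp[k] + 1 &&
          sum(fail[(pp[k] + 1):(pp[k + 1] - 1)]) > max_gap)
        return(FALSE)
    }
    TRUE
  }
  res <- NULL
  for (ch in unique(grid$chrom)) {
    ids <- which(grid$chrom == ch)
    for (i in ids) {
      if (!pass[i]) next
      for (j in ids[ids >= i]) {
        if (!pass[j] || !gap_ok(i, j)) next
        # maximal: no extension to the nearest outer passing bin is valid
        prev <- ids[ids < i & pass[ids]]
        if (length(prev) && gap_ok(max(prev), j)) next
        nxt <- ids[ids > j & pass[ids]]
        if (length(nxt) && gap_ok(i, min(nxt))) next
        if (grid$end[j] - grid$start[i] >= min_len)
          res <- rbind(res, data.frame(chrom = ch, start = grid$start[i],
                                       end = grid$end[j],
                                       stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(res))
    res <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE)
  unique(res[order(match(res$chrom, unique(grid$chrom)), res$start), ,
             drop = FALSE])
}

# transitive closure of overlap-or-bookended merging by fixed-point iteration
oracle_merge <- function(df) {
  regs <- lapply(seq_len(nrow(df)), function(i)
    list(chrom = df$chrom[i], start = df$start[i], end = df$end[i]))
  repeat {
    merged_any <- FALSE
    i <- 1
    while (i <= length(regs)) {
      j <- i + 1
      while (j <= length(regs)) {
        a <- regs[[i]]; b <- regs[[j]]
        if (a$chrom == b$chrom && a$start <= b$end && b$start <= a$end) {
          regs[[i]] <- list(chrom = a$chrom, start = min(a$start, b$start),
                            end = max(a$end, b$end))
          regs[[j]] <- NULL
          merged_any <- TRUE
        } else j <- j + 1
      }
      i <- i + 1
    }
    if (!merged_any) break
  }
  out <- do.call(rbind, lapply(regs, as.data.frame))
  out[order(out$chrom, out$start), , drop = FALSE]
}

# two-sided Fisher p by full enumeration of tables with fixed margins
oracle_fisher <- function(a, b, c, d) {
  K <- a + b; N <- a + b + c + d; n1 <- a + c
  xs <- max(0, n1 - (N - K)):min(K, n1)
  probs <- choose(K, xs) * choose(N - K, n1 - xs) / choose(N, n1)
  sum(probs[probs <= probs[xs == a] * (1 + 1e-7)])
}

# per-base coverage of interval `a` by a set of intervals (same chromosome)
oracle_cov_bases <- function(a_start, a_end, regions) {
  covered <- logical(a_end - a_start)
  for (i in seq_len(nrow(regions))) {
    lo <- max(a_start, regions$start[i]); hi <- min(a_end, regions$end[i])
    if (hi > lo) covered[(lo - a_start + 1):(hi - a_start)] <- TRUE
  }
  sum(covered)
}
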