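#' The 16-individual reference cohort
#'
#' Returns the cohort design the simulator emulates: 16 individuals in four
#' groups (Asian/European x wild/domestic; 3+5+3+5), with per-individual
#' sequencing coverage between 7.1x and 11x, and the published per-individual
#' multi-copy-region counts and spans used by [cohort_mcr_summary()]. Sexes
#' are synthetic stand-ins (the source table does not print them) assigned
#' deterministically.
#'
#' @return data frame with columns `id`, `breed`, `group`, `sex`, `coverage`,
#'   `mcr_count`, `mcr_mb`.
#' @export
pig_cohort <- function() {
  path <- system.file("extdata", "cohort_table.tsv", package = "rdcnv",
                      mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Truth CNV event parameters
#'
#' Event sizes are `size_min` plus a geometric excess (a discretised
#' exponential in bins) truncated at `size_max`, giving the right-skewed size
#' spectrum of read-depth gain calls: most events near the minimum, a tail to
#' `size_max`, mean near `size_mean`. Copy numbers are uniform integers in
#' `cn_range`; gains always clear the CN > 3 calling floor.
#'
#' @param n_shared,n_group,n_private event counts by scope: present in all
#'   individuals, in all members of one group, or in a single individual.
#' @param cn_range integer CN range of gains, within [4, 32].
#' @param size_min,size_max,size_mean event size distribution in bases
#'   (bin-aligned; bounded to [6 kb, 122 kb]).
#' @param allow_losses simulate CN-loss events (off by default; the calling
#'   side of this package targets gains only).
#' @param n_loss,loss_cn loss events and their CN, used only when
#'   `allow_losses` is TRUE.
#' @return list of class `cnv_params`.
#' @export
cnv_params <- function(n_shared = 20, n_group = 16, n_private = 20,
                       cn_range = c(4L, 10L),
                       size_min = 6000, size_max = 60000, size_mean = 13000,
                       allow_losses = FALSE, n_loss = 0, loss_cn = 1L) {
  p <- as.list(environment())
  if (p$cn_range[1] < 4 || p$cn_range[2] > 32)
    stop("invalid config: cn_range must lie within [4, 32]", call. = FALSE)
  if (p$size_min < 6000 || p$size_max > 122000 || p$size_min > p$size_max)
    stop("invalid config: event sizes must lie within [6 kb, 122 kb]",
         call. = FALSE)
  if (p$size_mean <= p$size_min)
    stop("invalid config: size_mean must exceed size_min", call. = FALSE)
  class(p) <- "cnv_params"
  p
}

# draw n bin-aligned event sizes: size_min + bin_size * min(G, cap) with
# G ~ Geometric matching the configured mean excess
draw_event_sizes <- function(n, params, bin_size) {
  mean_excess_bins <- (params$size_mean - params$size_min) / bin_size
  p <- 1 / (1 + mean_excess_bins)           # Geometric on 0,1,2,... mean (1-p)/p
  cap <- (params$size_max - params$size_min) / bin_size
  g <- pmin(stats::rgeom(n, p), cap)
  params$size_min + g * bin_size
}

# analytic mean of the truncated event-size distribution (used by tests)
event_size_mean <- function(params, bin_size) {
  mean_excess_bins <- (params$size_mean - params$size_min) / bin_size
  p <- 1 / (1 + mean_excess_bins)
  cap <- (params$size_max - params$size_min) / bin_size
  k <- 0:cap
  pk <- stats::dgeom(k, p)
  pk[length(pk)] <- pk[length(pk)] + stats::pgeom(cap, p, lower.tail = FALSE)
  params$size_min + bin_size * sum(k * pk)
}

#' Simulate ground-truth copy-number profiles for a cohort
#'
#' Places gain events at the genome's pre-declared candidate anchor sites
#' (which never touch 1:1-ortholog regions, the pipeline's diploid anchor)
#' and assigns them to individuals by scope: shared events to everyone, group
#' events to every member of one group (round-robin over groups), private
#' events to single individuals (round-robin). Outside events the baseline is
#' diploid, with CN 1 on the male X outside the pseudo-autosomal region.
#'
#' @param genome a [simulate_genome()] object.
#' @param individuals data frame with `id`, `sex` ("M"/"F"), `group`,
#'   `coverage`; see [pig_cohort()].
#' @param params a [cnv_params()] list.
#' @param seed integer seed.
#' @return Object of class `truth_cn`: list with `cn` (bins x individuals
#'   integer matrix), `events` (data frame: event_id, chrom, start, end, cn,
#'   scope, target), and `individuals`.
#' @export
simulate_truth <- function(genome, individuals, params = cnv_params(),
                           seed = 1L) {
  grid <- genome$grid
  bs <- attr(grid, "bin_size")
  n_total <- params$n_shared + params$n_group + params$n_private +
    if (params$allow_losses) params$n_loss else 0
  with_seed(seed, {
    # baseline profiles
    cn <- matrix(2L, nrow = nrow(grid), ncol = nrow(individuals),
                 dimnames = list(NULL, individuals$id))
    xch <- attr(grid, "x_chrom")
    if (!is.na(xch)) {
      on_x <- grid$chrom == xch
      in_par <- rep(FALSE, nrow(grid))
      if (nrow(genome$par))
        in_par[bins_in_regions(grid, genome$par)] <- TRUE
      for (j in seq_len(nrow(individuals)))
        if (individuals$sex[j] == "M")
          cn[on_x & !in_par, j] <- 1L
    }

    events <- data.frame(event_id = character(0), chrom = character(0),
                         start = numeric(0), end = numeric(0),
                         cn = integer(0), scope = character(0),
                         target = character(0), stringsAsFactors = FALSE)
    if (n_total > 0) {
      sites <- genome$event_sites
      if (nrow(sites) < n_total)
        stop(sprintf(
          "placement error: %d events requested but only %d candidate sites available",
          n_total, nrow(sites)), call. = FALSE)
      sites <- sites[sample.int(nrow(sites), n_total), , drop = FALSE]
      sizes <- draw_event_sizes(n_total, params, bs)
      cn_vals <- sample(seq(params$cn_range[1], params$cn_range[2]),
                        n_total, replace = TRUE)
      scope <- c(rep("shared", params$n_shared),
                 rep("group", params$n_group),
                 rep("private", params$n_private),
                 rep("loss", if (params$allow_losses) params$n_loss else 0))
      groups <- unique(individuals$group)
      target <- character(n_total)
      target[scope == "shared"] <- "all"
      ng <- sum(scope == "group")
      if (ng) target[scope == "group"] <- rep_len(groups, ng)
      np <- sum(scope == "private")
      if (np) target[scope == "private"] <- rep_len(individuals$id, np)
      nl <- sum(scope == "loss")
      if (nl) {
        target[scope == "loss"] <- rep_len(individuals$id, nl)
        cn_vals[scope == "loss"] <- params$loss_cn
      }
      events <- data.frame(
        event_id = sprintf("ev%03d", seq_len(n_total)),
        chrom = sites$chrom, start = sites$start,
        end = sites$start + sizes, cn = as.integer(cn_vals),
        scope = scope, target = target, stringsAsFactors = FALSE)
      # anchors were pre-screened against orthologs at max size, but assert
      if (any(covered_bases(events, genome$orthologs) > 0))
        stop("placement error: an event overlaps an ortholog region",
             call. = FALSE)
      for (i in seq_len(n_total)) {
        ev <- events[i, ]
        carriers <- switch(ev$scope,
          shared = individuals$id,
          group = individuals$id[individuals$group == ev$target],
          private = ev$target,
          loss = ev$target)
        idx <- which(grid$chrom == ev$chrom & grid$start >= ev$start &
                       grid$end <= ev$end)
        cn[idx, carriers] <- ev$cn
      }
      events <- sort_regions(events, unique(grid$chrom))
    }
    structure(list(cn = cn, events = events, individuals = individuals),
              class = "truth_cn")
  })
}

#' @export
print.truth_cn <- function(x, ...) {
  cat(sprintf("truth_cn: %d individuals, %d bins, %d events (%s)\n",
              ncol(x$cn), nrow(x$cn), nrow(x$events),
              paste(names(table(x$events$scope)), table(x$events$scope),
                    sep = ":", collapse = ", ")))
  invisible(x)
}

#' Truth-side polymorphism of simulated events
#'
#' For each event, the across-cohort standard deviation of truth CN inside
#' the event and the number of individuals whose CN differs from the modal
#' value. Events with `sd >= sd_threshold` and `n_diff >= min_diff` are the
#' ones a dispersion-based CNVR caller can detect in principle, and form the
#' denominator of recovery checks.
#'
#' @param truth a [simulate_truth()] object.
#' @param sd_threshold,min_diff polymorphism bounds (defaults match the CNVR
#'   call threshold).
#' @return `truth$events` with added columns `truth_sd`, `n_diff`,
#'   `polymorphic`.
#' @export
polymorphic_events <- function(truth, sd_threshold = 0.7, min_diff = 3) {
  ev <- truth$events
  if (!nrow(ev)) {
    ev$truth_sd <- numeric(0); ev$n_diff <- integer(0)
    ev$polymorphic <- logical(0)
    return(ev)
  }
  stats_ <- t(vapply(seq_len(nrow(ev)), function(i) {
    carriers <- switch(ev$scope[i],
      shared = truth$individuals$id,
      group = truth$individuals$id[truth$individuals$group == ev$target[i]],
      ev$target[i])
    v <- ifelse(truth$individuals$id %in% carriers, ev$cn[i], 2)
    tab <- table(v)
    mode_v <- as.numeric(names(tab)[which.max(tab)])
    c(sd(v), sum(v != mode_v))
  }, numeric(2)))
  ev$truth_sd <- stats_[, 1]
  ev$n_diff <- as.integer(stats_[, 2])
  ev$polymorphic <- ev$truth_sd >= sd_threshold & ev$n_diff >= min_diff
  ev
}

#' Expected per-bin depth before noise
#'
#' The generative mean the depth simulator draws around:
#' `(coverage / 2) * CN * g(gc) * (1 - masked_frac)` per bin.
#'
#' @param genome a [simulate_genome()] object.
#' @param cn integer/numeric per-bin copy number vector.
#' @param coverage mean haploid-pair depth (x).
#' @param gc_bias function g(GC), positive on [0, 1]; `NULL` for flat 1.
#' @return numeric vector of expected depths per bin.
#' @export
expected_depth <- function(genome, cn, coverage, gc_bias = NULL) {
  grid <- genome$grid
  if (length(cn) != nrow(grid))
    stop("cn must have one value per bin", call. = FALSE)
  if (!is.numeric(coverage) || coverage <= 0)
    stop("invalid config: coverage must be positive", call. = FALSE)
  g <- if (is.null(gc_bias)) rep(1, nrow(grid)) else gc_bias(grid$gc)
  if (any(!is.finite(g)) || any(g <= 0))
    stop("invalid config: gc_bias must be positive over the genome's GC range",
         call. = FALSE)
  (coverage / 2) * cn * g * (1 - grid$masked)
}

#' Simulate a raw depth track for one individual
#'
#' Draws per-bin read depth around [expected_depth()] using a negative
#' binomial on per-bin base counts (`variance = mean + dispersion * mean^2`),
#' falling back to Poisson when `dispersion = 0`. Depth is returned in x
#' units (bases of coverage per bin position).
#'
#' @param genome a [simulate_genome()] object.
#' @param cn per-bin truth CN vector for this individual (a column of
#'   `truth$cn`).
#' @param coverage mean haploid-pair depth (x); must be positive.
#' @param gc_bias GC response function g(GC), positive; `NULL` for none.
#' @param dispersion negative-binomial dispersion alpha >= 0.
#' @param seed integer seed.
#' @param id individual id recorded on the track.
#' @return Object of class `depth_track`: list with `id`, `depth` (numeric
#'   per bin), `corrected` (FALSE), `excluded` (logical per bin, here all
#'   FALSE: exclusion is an estimation-stage decision).
#' @export
simulate_depth <- function(genome, cn, coverage, gc_bias = NULL,
                           dispersion = 0.005, seed = 1L, id = "ind") {
  mu <- expected_depth(genome, cn, coverage, gc_bias)
  bs <- attr(genome$grid, "bin_size")
  with_seed(seed, {
    mu_bases <- mu * bs
    counts <- if (dispersion > 0)
      rnbinom(length(mu_bases), mu = mu_bases, size = 1 / dispersion)
    else rpois(length(mu_bases), mu_bases)
    depth_track(id, counts / bs)
  })
}

#' Construct a depth track
#'
#' @param id individual id.
#' @param depth non-negative numeric per-bin mean depth.
#' @param corrected has GC correction been applied.
#' @param excluded optional logical per bin.
#' @return `depth_track` object.
#' @export
depth_track <- function(id, depth, corrected = FALSE, excluded = NULL) {
  if (any(depth < 0, na.rm = TRUE))
    stop("depth values must be non-negative", call. = FALSE)
  structure(list(id = id, depth = as.numeric(depth),
                 corrected = isTRUE(corrected),
                 excluded = excluded %||% rep(FALSE, length(depth))),
            class = "depth_track")
}

#' @export
print.depth_track <- function(x, ...) {
  cat(sprintf("depth_track '%s': %d bins, mean %.2fx%s\n", x$id,
              length(x$depth), mean(x$depth[!x$excluded]),
              if (x$corrected) " (GC-corrected)" else " (raw)"))
  invisible(x)
}

#' Simulate truth and depth for a whole cohort
#'
#' @inheritParams simulate_truth
#' @param gc_bias,dispersion passed to [simulate_depth()].
#' @return list with `truth` (class `truth_cn`) and `depths` (named list of
#'   `depth_track`, one per individual).
#' @export
simulate_cohort <- function(genome, individuals = pig_cohort(),
                            params = cnv_params(), gc_bias = NULL,
                            dispersion = 0.005, seed = 1L) {
  truth <- simulate_truth(genome, individuals, params, seed = seed)
  depths <- lapply(seq_len(nrow(individuals)), function(j) {
    simulate_depth(genome, truth$cn[, j], individuals$coverage[j],
                   gc_bias = gc_bias, dispersion = dispersion,
                   seed = derive_seed(seed, j), id = individuals$id[j])
  })
  names(depths) <- individuals$id
  list(truth = truth, depths = depths)
}
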