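#' Construct a bin grid
#'
#' Builds the non-overlapping, contiguous 1 kb (by default) bin lattice the
#' whole pipeline is indexed on. For real data this is the entry point:
#' supply chromosome lengths (trailing partial bins are dropped) and per-bin
#' GC / masked fractions.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bases).
#' @param bin_size bin width in bases.
#' @param gc,masked per-bin vectors in [0, 1], recycled if length 1.
#' @param x_chrom name of the X chromosome, or `NA`.
#' @return A `bin_grid` data frame (chrom, start, end, gc, masked) with
#'   attributes `bin_size`, `chrom_lengths`, `x_chrom`.
#' @export
bin_grid <- function(chrom_lengths, bin_size = 1000, gc = 0.4, masked = 0,
                     x_chrom = NA_character_) {
  if (is.null(names(chrom_lengths)))
    stop("chrom_lengths must be named", call. = FALSE)
  usable <- floor(chrom_lengths / bin_size) * bin_size
  grid <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    starts <- seq(0, usable[[ch]] - bin_size, by = bin_size)
    data.frame(chrom = ch, start = starts, end = starts + bin_size,
               stringsAsFactors = FALSE)
  }))
  grid$gc <- rep_len(gc, nrow(grid))
  grid$masked <- rep_len(masked, nrow(grid))
  if (any(grid$gc < 0 | grid$gc > 1) || any(grid$masked < 0 | grid$masked > 1))
    stop("gc and masked must lie in [0, 1]", call. = FALSE)
  attr(grid, "bin_size") <- bin_size
  attr(grid, "chrom_lengths") <- chrom_lengths
  attr(grid, "x_chrom") <- x_chrom
  class(grid) <- c("bin_grid", "data.frame")
  grid
}

#' Simulation parameters for a binned genome
#'
#' Builds the parameter list consumed by [simulate_genome()]. Defaults give a
#' ~20 Mb genome (three autosomes plus an X with a pseudo-autosomal region)
#' whose scale keeps a full 16-individual analysis fast while preserving the
#' structure the pipeline needs: autocorrelated GC, repeat-masked bins, genes
#' with exons, a 1:1-ortholog diploid anchor set, segmental duplications and
#' pre-declared candidate CNV event sites.
#'
#' @param chromosomes named numeric vector of chromosome lengths in bases;
#'   each must be a multiple of `bin_size` and at least `10 * bin_size`.
#' @param x_chrom name of the X chromosome (`NA` for none).
#' @param par_end end of the pseudo-autosomal region at the start of X, bases.
#' @param bin_size bin width in bases.
#' @param gc_mean,gc_phi,gc_sd AR(1) GC landscape: marginal mean,
#'   lag-1 autocorrelation, and marginal standard deviation per bin.
#' @param gc_clip two-element numeric, GC values are clipped to this range.
#' @param gc_dip_at_events GC depression (fraction units) applied to bins
#'   around candidate event sites, emulating the lower GC of CNV loci.
#' @param n_genes,gene_len gene count and length range (bases).
#' @param exons_per_gene integer range of exon counts per gene.
#' @param ortholog_frac fraction of genes flagged as 1:1 orthologs (the
#'   diploid anchor; events never overlap them).
#' @param n_sds,sd_len segmental-duplication count and length range.
#' @param sd_near_event_frac fraction of SDs whose midpoint is placed within
#'   10 kb of a candidate event site (makes SD/CNVR association testable).
#' @param n_repeats total repeat-element count.
#' @param repeat_families named numeric of family placement weights.
#' @param repeat_len repeat length range (bases).
#' @param repeat_near_event named numeric, per-family fraction of elements
#'   placed within 10 kb of a candidate event site.
#' @param n_event_sites number of candidate CNV anchor sites (autosomal).
#' @param max_event_size largest event the anchors must accommodate, bases.
#' @return A named list of class `genome_config`.
#' @export
genome_config <- function(chromosomes = c(chr1 = 6e6, chr2 = 5e6,
                                          chr3 = 4e6, chrX = 5e6),
                          x_chrom = "chrX",
                          par_end = 3e5,
                          bin_size = 1000,
                          gc_mean = 0.42, gc_phi = 0.95, gc_sd = 0.05,
                          gc_clip = c(0.2, 0.7),
                          gc_dip_at_events = 0.03,
                          n_genes = 240,
                          gene_len = c(2e3, 2e4),
                          exons_per_gene = c(3L, 8L),
                          ortholog_frac = 0.5,
                          n_sds = 60,
                          sd_len = c(5e3, 2e4),
                          sd_near_event_frac = 0.5,
                          n_repeats = 1200,
                          repeat_families = c("LINE-L1" = 0.4, "SINE" = 0.3,
                                              "LTR-ERV1" = 0.2,
                                              "Satellite" = 0.1),
                          repeat_len = c(200, 6000),
                          repeat_near_event = c("LINE-L1" = 0.3),
                          n_event_sites = 90,
                          max_event_size = 60000) {
  cfg <- as.list(environment())
  class(cfg) <- "genome_config"
  cfg
}

validate_genome_config <- function(cfg) {
  bs <- cfg$bin_size
  if (any(cfg$chromosomes < 10 * bs))
    stop("invalid config: every chromosome length must be >= 10 * bin_size",
         call. = FALSE)
  if (any(cfg$chromosomes %% bs != 0))
    stop("invalid config: chromosome lengths must be multiples of bin_size",
         call. = FALSE)
  if (is.null(names(cfg$chromosomes)))
    stop("invalid config: chromosomes must be named", call. = FALSE)
  invisible(cfg)
}

# AR(1) per chromosome, clipped; stationary initialisation
ar1_track <- function(n, mean, phi, sd_marg, clip) {
  innov_sd <- sd_marg * sqrt(1 - phi^2)
  x <- numeric(n)
  x[1] <- rnorm(1, mean, sd_marg)
  if (n > 1) {
    e <- rnorm(n - 1, 0, innov_sd)
    for (i in 2:n) x[i] <- mean + phi * (x[i - 1] - mean) + e[i - 1]
  }
  pmin(pmax(x, clip[1]), clip[2])
}

# place n non-overlapping intervals with lengths in len_range on the given
# chromosomes by slotting a shuffled candidate lattice; deterministic given
# the RNG state
place_intervals <- function(chrom_lengths, n, len_range, avoid = NULL,
                            what = "interval") {
  slot <- ceiling(len_range[2])
  cand <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    starts <- seq(0, chrom_lengths[[ch]] - slot, by = slot)
    if (!length(starts)) return(NULL)
    data.frame(chrom = ch, start = starts, stringsAsFactors = FALSE)
  }))
  if (is.null(cand) || nrow(cand) < n)
    stop(sprintf("placement error: cannot place %d %ss (only %d candidate slots)",
                 n, what, if (is.null(cand)) 0L else nrow(cand)), call. = FALSE)
  cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
  if (!is.null(avoid) && nrow(avoid)) {
    slots <- data.frame(chrom = cand$chrom, start = cand$start,
                        end = cand$start + slot)
    bad <- covered_bases(slots, avoid) > 0
    cand <- cand[!bad, , drop = FALSE]
  }
  if (nrow(cand) < n)
    stop(sprintf("placement error: cannot place %d %ss without overlap", n, what),
         call. = FALSE)
  cand <- cand[seq_len(n), , drop = FALSE]
  len <- round(runif(n, len_range[1], len_range[2]))
  data.frame(chrom = cand$chrom, start = cand$start,
             end = pmin(cand$start + len, cand$start + slot),
             stringsAsFactors = FALSE)
}

#' Generate a binned genome with annotations
#'
#' Deterministically (per seed) builds the bin lattice with GC and masked
#' fractions plus the annotation set the pipeline consumes: genes with exons,
#' the 1:1-ortholog subset, segmental duplications, repeat elements by family,
#' the pseudo-autosomal region, and candidate CNV event sites that
#' [simulate_truth()] later draws from. SDs and (optionally) repeats are
#' placed near event sites at configurable rates so context-enrichment tests
#' have a known signal.
#'
#' @param config a [genome_config()] list.
#' @param seed integer seed; identical `(config, seed)` give bit-identical
#'   output.
#' @return An object of class `cnv_genome`: list with elements `grid`
#'   (a `bin_grid` data frame: chrom, start, end, gc, masked), `genes`,
#'   `exons`, `orthologs`, `sds`, `repeats` (BED-like data frames), `par`,
#'   `event_sites`, `config`, `seed`.
#' @export
simulate_genome <- function(config = genome_config(), seed = 1L) {
  validate_genome_config(config)
  with_seed(seed, {
    cl <- config$chromosomes
    bs <- config$bin_size
    grid <- do.call(rbind, lapply(names(cl), function(ch) {
      starts <- seq(0, cl[[ch]] - bs, by = bs)
      data.frame(chrom = ch, start = starts, end = starts + bs,
                 stringsAsFactors = FALSE)
    }))

    # genes (with exons), anywhere on the genome, non-overlapping
    genes <- place_intervals(cl, config$n_genes, config$gene_len,
                             what = "gene")
    genes$gene_id <- sprintf("gene%04d", seq_len(nrow(genes)))
    genes <- genes[, c("gene_id", "chrom", "start", "end")]
    exons <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
      g <- genes[i, ]
      k <- sample(seq(config$exons_per_gene[1], config$exons_per_gene[2]), 1)
      # split the gene body into 2k+1 slices; odd slices are exons
      cuts <- sort(c(g$start, g$end,
                     round(runif(2 * k - 1, g$start, g$end))))
      s <- cuts[seq(1, 2 * k, by = 2)]
      e <- cuts[seq(2, 2 * k + 1, by = 2)]
      keep <- e > s
      data.frame(gene_id = g$gene_id, chrom = g$chrom,
                 start = s[keep], end = e[keep], stringsAsFactors = FALSE)
    }))
    n_orth <- round(config$ortholog_frac * nrow(genes))
    orth_ids <- sort(sample(genes$gene_id, n_orth))
    orthologs <- genes[genes$gene_id %in% orth_ids, ]
    rownames(orthologs) <- NULL

    # candidate event anchor sites: autosomal slots wide enough for the
    # largest event, clear of ortholog (diploid-anchor) genes
    autosomes <- cl[names(cl) != config$x_chrom | is.na(config$x_chrom)]
    slot <- config$max_event_size + 2 * bs
    cand <- do.call(rbind, lapply(names(autosomes), function(ch) {
      starts <- seq(bs, autosomes[[ch]] - slot, by = slot)
      data.frame(chrom = ch, start = starts, stringsAsFactors = FALSE)
    }))
    cand$start <- floor(cand$start / bs) * bs
    slots <- data.frame(chrom = cand$chrom, start = cand$start,
                        end = cand$start + slot)
    free <- covered_bases(slots, orthologs) == 0
    cand <- cand[free, , drop = FALSE]
    if (nrow(cand) < config$n_event_sites)
      stop(sprintf(
        "placement error: only %d of %d requested event sites fit clear of ortholog regions",
        nrow(cand), config$n_event_sites), call. = FALSE)
    cand <- cand[sample.int(nrow(cand), config$n_event_sites), , drop = FALSE]
    event_sites <- sort_regions(
      data.frame(chrom = cand$chrom, start = cand$start,
                 end = cand$start + slot, stringsAsFactors = FALSE),
      names(cl))

    # segmental duplications: a fraction anchored near event sites
    n_near <- round(config$sd_near_event_frac * config$n_sds)
    sds_near <- NULL
    if (n_near > 0) {
      anchors <- event_sites[sample.int(nrow(event_sites), n_near,
                                        replace = TRUE), ]
      len <- round(runif(n_near, config$sd_len[1], config$sd_len[2]))
      mid <- anchors$start + round(runif(n_near, -8000, 8000))
      s <- pmax(0, mid - len %/% 2)
      sds_near <- data.frame(chrom = anchors$chrom, start = s,
                             end = pmin(s + len, cl[anchors$chrom]),
                             stringsAsFactors = FALSE)
    }
    n_far <- config$n_sds - n_near
    sds_far <- if (n_far > 0)
      place_intervals(cl, n_far, config$sd_len, what = "segmental duplication")
    else NULL
    sds <- sort_regions(rbind(sds_near, sds_far), names(cl))
    if (nrow(sds)) sds$sd_id <- sprintf("sd%03d", seq_len(nrow(sds)))

    # repeat elements by family; optional per-family pull towards event sites
    repeats <- NULL
    if (config$n_repeats > 0 && length(config$repeat_families)) {
      fam <- sample(names(config$repeat_families), config$n_repeats,
                    replace = TRUE, prob = config$repeat_families)
      len <- round(runif(config$n_repeats,
                         config$repeat_len[1], config$repeat_len[2]))
      near_frac <- config$repeat_near_event[fam]
      near_frac[is.na(near_frac)] <- 0
      near <- runif(config$n_repeats) < near_frac
      chrom <- character(config$n_repeats)
      start <- numeric(config$n_repeats)
      if (any(near)) {
        # enriched elements go in the 10 kb flank upstream of the event
        # anchor (never inside the event: flank density is the signal the
        # context module measures, and interior masking would erase the
        # event's depth evidence)
        a <- event_sites[sample.int(nrow(event_sites), sum(near),
                                    replace = TRUE), ]
        slack <- pmax(10000 - len[near], 0)
        offset <- floor(runif(sum(near), 0, slack + 1))
        chrom[near] <- a$chrom
        start[near] <- pmax(0, a$start - len[near] - offset)
      }
      if (any(!near)) {
        ch <- sample(names(cl), sum(!near), replace = TRUE,
                     prob = cl / sum(cl))
        chrom[!near] <- ch
        start[!near] <- floor(runif(sum(!near), 0, cl[ch] - len[!near]))
      }
      repeats <- data.frame(chrom = chrom, start = start,
                            end = pmin(start + len, cl[chrom]),
                            family = fam, stringsAsFactors = FALSE)
      repeats <- sort_regions(repeats, names(cl))
    } else {
      repeats <- data.frame(chrom = character(0), start = numeric(0),
                            end = numeric(0), family = character(0),
                            stringsAsFactors = FALSE)
    }

    # per-bin masked fraction = repeat-union coverage of the bin
    grid$masked <- covered_bases(grid, repeats) / bs

    # GC landscape: AR(1) per chromosome, clipped; dip near event sites
    grid$gc <- unlist(lapply(names(cl), function(ch) {
      ar1_track(sum(grid$chrom == ch), config$gc_mean, config$gc_phi,
                config$gc_sd, config$gc_clip)
    }), use.names = FALSE)
    if (config$gc_dip_at_events > 0 && nrow(event_sites)) {
      hit <- bins_in_regions(grid, event_sites)
      grid$gc[hit] <- pmax(config$gc_clip[1],
                           grid$gc[hit] - config$gc_dip_at_events)
    }

    grid <- grid[, c("chrom", "start", "end", "gc", "masked")]
    attr(grid, "bin_size") <- bs
    attr(grid, "chrom_lengths") <- cl
    attr(grid, "x_chrom") <- config$x_chrom
    class(grid) <- c("bin_grid", "data.frame")

    par <- if (!is.na(config$x_chrom) && config$par_end > 0)
      data.frame(chrom = config$x_chrom, start = 0, end = config$par_end,
                 stringsAsFactors = FALSE)
    else data.frame(chrom = character(0), start = numeric(0), end = numeric(0))

    structure(list(grid = grid, genes = genes, exons = exons,
                   orthologs = orthologs, sds = sds, repeats = repeats,
                   par = par, event_sites = event_sites,
                   config = config, seed = as.integer(seed)),
              class = "cnv_genome")
  })
}

#' @export
print.cnv_genome <- function(x, ...) {
  cl <- attr(x$grid, "chrom_lengths")
  cat(sprintf("Simulated binned genome: %d chromosomes, %.1f Mb, %d bins of %d b\n",
              length(cl), sum(cl) / 1e6, nrow(x$grid),
              attr(x$grid, "bin_size")))
  cat(sprintf("  genes: %d (%d orthologs)  SDs: %d  repeats: %d  event sites: %d\n",
              nrow(x$genes), nrow(x$orthologs), nrow(x$sds), nrow(x$repeats),
              nrow(x$event_sites)))
  invisible(x)
}

#' @export
print.bin_grid <- function(x, ...) {
  cat(sprintf("bin_grid: %d bins of %d b on %d chromosomes\n", nrow(x),
              attr(x, "bin_size"), length(attr(x, "chrom_lengths"))))
  NextMethod()
}
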