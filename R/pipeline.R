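# End-to-end driver: one configuration object, staged execution with
# per-stage outputs, and a JSON manifest with parameters, seeds and
# checksums. Runs are deterministic for a fixed configuration and seed.

#' Pipeline run configuration
#'
#' Collects every stage parameter with the pipeline's standard defaults:
#' 1 kb bins, MCR minimum 6 kb at CN floor 4 (CN > 3), CNVR s.d. 0.7, gene
#' overlap 0.70, gene CN > 2 with s.d. 0.5, 10 kb flanks, 3 individuals per
#' group. Unknown keys are rejected.
#'
#' @param ... overrides of the defaults listed above; see source for the
#'   full key set (`genome`, `individuals`, `cnv`, `gc_bias`, `dispersion`,
#'   `mcr_min_len`, `cn_floor`, `max_gap_bins`, `cnvr_sd`, `gene_min_frac`,
#'   `gene_cn_gt`, `gene_sd_min`, `flank`, `per_group`, `gc_width`,
#'   `min_support`, `diploid_window`, `mask_max`, `seed`).
#' @return list of class `rdcnv_config`.
#' @export
rdcnv_config <- function(...) {
  defaults <- list(
    genome = genome_config(),
    individuals = pig_cohort(),
    cnv = cnv_params(),
    gc_bias = NULL,
    dispersion = 0.005,
    mcr_min_len = 6000,
    cn_floor = 4L,
    max_gap_bins = 0L,
    cnvr_sd = 0.7,
    gene_min_frac = 0.7,
    gene_cn_gt = 2,
    gene_sd_min = 0.5,
    flank = 10000,
    per_group = 3L,
    gc_width = 0.01,
    min_support = 50L,
    diploid_window = c(1.5, 2.5),
    mask_max = 0.8,
    min_ortholog_bins = 200L,
    seed = 1L)
  override <- list(...)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  cfg <- utils::modifyList(defaults, override, keep.null = TRUE)
  class(cfg) <- "rdcnv_config"
  cfg
}

stage_log <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(paste0("[rdcnv] ", fmt), ...))
}

#' Run the whole read-depth CNV pipeline
#'
#' Simulates (or accepts) a cohort, estimates per-individual CN tracks,
#' calls MCRs and cohort CNVRs, produces the gene, genomic-context and
#' group-comparison reports, and writes every stage's tables into `out_dir`
#' together with a JSON manifest recording parameters, seeds and output
#' checksums. Rerunning with an identical configuration reproduces identical
#' outputs.
#'
#' @param config an [rdcnv_config()] object.
#' @param out_dir output directory (created if missing); `NULL` for no file
#'   output.
#' @param cohort optional precomputed list(truth, depths) to skip
#'   simulation (e.g. ingested real depth tracks).
#' @param genome optional precomputed [simulate_genome()] object.
#' @param quiet suppress stage progress messages.
#' @return list of class `rdcnv_run` with elements `genome`, `truth`,
#'   `fits`, `mcrs`, `mcr_summary`, `cnvrs`, `catalog`, `genes`, `context`,
#'   `groups`, `manifest`.
#' @export
run_rdcnv <- function(config = rdcnv_config(), out_dir = NULL,
                      cohort = NULL, genome = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "rdcnv_config"))
  t0 <- Sys.time()
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  outfile <- function(name) if (is.null(out_dir)) NULL
    else file.path(out_dir, name)

  stage_log(quiet, "simulating genome and cohort (seed %d)", config$seed)
  if (is.null(genome))
    genome <- simulate_genome(config$genome, seed = config$seed)
  grid <- genome$grid
  individuals <- config$individuals
  if (is.null(cohort))
    cohort <- simulate_cohort(genome, individuals, config$cnv,
                              gc_bias = config$gc_bias,
                              dispersion = config$dispersion,
                              seed = config$seed)

  stage_log(quiet, "estimating CN tracks for %d individuals",
            nrow(individuals))
  fits <- lapply(seq_len(nrow(individuals)), function(j) {
    estimate_cn_track(cohort$depths[[individuals$id[j]]], genome,
                      sex = individuals$sex[j], gc_width = config$gc_width,
                      min_support = config$min_support,
                      diploid_window = config$diploid_window,
                      mask_max = config$mask_max,
                      min_ortholog_bins = config$min_ortholog_bins)
  })
  names(fits) <- individuals$id
  cn_tracks <- lapply(fits, function(f) f$cn)

  stage_log(quiet, "calling MCRs")
  mcrs <- do.call(rbind, lapply(cn_tracks, function(tr)
    call_mcrs(tr, grid, min_len = config$mcr_min_len,
              cn_floor = config$cn_floor,
              max_gap_bins = config$max_gap_bins)))
  rownames(mcrs) <- NULL
  mcr_summary <- summarize_mcrs(mcrs)

  stage_log(quiet, "merging MCRs and calling CNVRs")
  regions <- merge_mcrs(mcrs, chrom_levels = unique(grid$chrom))
  mat <- build_cn_matrix(regions, cn_tracks, grid)
  cnvrs <- call_cnvrs(mat, sd_threshold = config$cnvr_sd,
                      min_size = config$mcr_min_len)
  catalog <- catalog_stats(cnvrs, grid)

  stage_log(quiet, "annotating genes")
  genes_rep <- gene_cn_report(cnvrs, genome$genes, genome$exons, cn_tracks,
                              grid, min_frac = config$gene_min_frac,
                              cn_gt = config$gene_cn_gt,
                              sd_min = config$gene_sd_min)
  genic <- genic_cnvrs(cnvrs, genome$genes, config$gene_min_frac)

  stage_log(quiet, "genomic context")
  cn_fl <- make_flank_intervals(cnvrs, grid, config$flank,
                                label = "cnvr_flank")
  sd_fl <- make_flank_intervals(genome$sds, grid, config$flank,
                                label = "sd_flank")
  oth <- other_intervals(list(cnvrs, cn_fl, genome$sds, sd_fl), grid,
                         config$flank)
  fams <- sort(unique(genome$repeats$family))
  dens <- data.frame(family = fams,
                     cnvr_flank = repeat_density(cn_fl, genome$repeats,
                                                 fams)$density,
                     sd_flank = repeat_density(sd_fl, genome$repeats,
                                               fams)$density,
                     other = repeat_density(oth, genome$repeats,
                                            fams)$density)
  dens$p_cnvr_flank <- vapply(fams, function(f)
    tryCatch(as.numeric(enrichment_test(f, cn_fl, oth, genome$repeats)),
             error = function(e) NA_real_),  # empty margin, e.g. no CNVRs
    numeric(1))
  sd_prox <- if (nrow(genome$sds))
    sd_cnvr_overlap(genome$sds, cnvrs, grid, config$flank)
  else list(count = 0L, total = 0L, percent = NaN, percent_exact = NaN)
  gc_ctr <- gc_contrast(cnvrs, grid, config$flank)
  context <- list(densities = dens, sd_overlap = sd_prox, gc = gc_ctr)

  stage_log(quiet, "group comparison (%d per group)", config$per_group)
  subset <- subset_individuals(individuals, per_group = config$per_group,
                               seed = derive_seed(config$seed, 777L))
  gsets <- group_cnvr_sets(subset, mcrs, cn_tracks, grid,
                           sd_threshold = config$cnvr_sd,
                           min_size = config$mcr_min_len)
  partition <- do.call(rbind, lapply(names(gsets), function(g) {
    p <- partition_shared_specific(gsets[[g]], gsets[setdiff(names(gsets), g)])
    data.frame(group = g, total = p$total, shared = p$shared,
               specific = p$specific, ratio = p$ratio,
               stringsAsFactors = FALSE)
  }))
  gene_stats <- group_gene_stats(gsets, subset, genome$genes, genome$exons,
                                 cn_tracks, grid,
                                 min_frac = config$gene_min_frac,
                                 cn_gt = config$gene_cn_gt)
  groups <- list(subset = subset, sets = gsets, partition = partition,
                 gene_stats = gene_stats)

  manifest <- list(
    package = "rdcnv",
    version = as.character(utils::packageVersion("rdcnv")),
    seed = config$seed,
    parameters = config[setdiff(names(config),
                                c("genome", "individuals", "cnv",
                                  "gc_bias"))],
    genome = list(chromosomes = as.list(config$genome$chromosomes),
                  bin_size = config$genome$bin_size),
    n_individuals = nrow(individuals),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  if (!is.null(out_dir)) {
    write_chrom_sizes(attr(grid, "chrom_lengths"),
                      outfile("chrom_sizes.tsv"))
    write_bed(as.data.frame(mcrs)[, c("chrom", "start", "end", "individual",
                                      "mean_cn")],
              outfile("mcrs.bed"))
    write_bed(as.data.frame(cnvrs)[, c("chrom", "start", "end", "sd",
                                       "size")], outfile("cnvrs.bed"))
    write_matrix_tsv(mat, outfile("cn_matrix.tsv"))
    utils::write.table(mcr_summary$per_individual,
                       outfile("mcr_summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(genes_rep), outfile("gene_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(dens, outfile("repeat_density.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(partition, outfile("group_partition.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(catalog$per_chrom, outfile("cnvr_density.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    files <- list.files(out_dir, pattern = "\\.(tsv|bed)$",
                        full.names = TRUE)
    manifest$checksums <- as.list(tools::md5sum(files))
    names(manifest$checksums) <- basename(files)
    jsonlite::write_json(manifest, outfile("manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  structure(list(genome = genome, truth = cohort$truth, fits = fits,
                 mcrs = mcrs, mcr_summary = mcr_summary, cnvrs = cnvrs,
                 cn_matrix = mat, catalog = catalog,
                 genes = list(report = genes_rep, genic = genic),
                 context = context, groups = groups, manifest = manifest),
            class = "rdcnv_run")
}

#' @export
print.rdcnv_run <- function(x, ...) {
  cat("Read-depth CNV pipeline run\n")
  cat(sprintf("  individuals: %d   MCRs: %d (mean %.0f/individual)\n",
              length(x$fits), x$mcr_summary$cohort$total,
              x$mcr_summary$cohort$mean))
  cat(sprintf("  CNVRs: %d, %.2f Mb (%.2f%% of genome), mean %.1f kb\n",
              x$catalog$count, x$catalog$total_mb,
              x$catalog$genome_fraction_pct, x$catalog$mean_size_kb))
  cat(sprintf("  genic CNVRs: %d/%d (%.2f%%); genes passing filters: %d\n",
              x$genes$genic$n_genic, x$genes$genic$n_total,
              x$genes$genic$percent, sum(x$genes$report$final)))
  cat(sprintf("  SDs within 10 kb of a CNVR: %d/%d (%.1f%%)\n",
              x$context$sd_overlap$count, x$context$sd_overlap$total,
              x$context$sd_overlap$percent))
  invisible(x)
}

#' Compare called CNVRs with simulated truth events
#'
#' Matches each polymorphic truth event (truth-side s.d. at or above the
#' calling threshold in at least `min_diff` individuals) to overlapping
#' called CNVRs and reports the recovery rate and per-side boundary errors
#' in bins. An event is *callable* when its non-excluded bins span at least
#' `min_len` bases: a gain whose unmasked extent is shorter cannot satisfy
#' the minimum-span rule whatever the caller does, so the headline recovery
#' rate is computed over callable events (the unrestricted rate is also
#' returned).
#'
#' @param run an [run_rdcnv()] result (or any list with `cnvrs`, `truth`,
#'   `genome`).
#' @param sd_threshold,min_diff polymorphism definition on the truth side.
#' @param min_len minimum region span used by the caller (bases).
#' @param mask_max exclusion threshold on the masked fraction.
#' @return list(n_polymorphic, n_callable, n_recovered, recovery_pct
#'   (callable denominator), recovery_pct_all, median_boundary_error_bins,
#'   events).
#' @export
evaluate_recovery <- function(run, sd_threshold = 0.7, min_diff = 3,
                              min_len = 6000, mask_max = 0.8) {
  ev <- polymorphic_events(run$truth, sd_threshold, min_diff)
  poly <- ev[ev$polymorphic, , drop = FALSE]
  grid <- run$genome$grid
  bs <- attr(grid, "bin_size")
  cnvrs <- as.data.frame(run$cnvrs)
  poly$callable <- vapply(seq_len(nrow(poly)), function(i) {
    idx <- which(grid$chrom == poly$chrom[i] & grid$start >= poly$start[i] &
                   grid$end <= poly$end[i] & grid$masked <= mask_max)
    length(idx) > 0 &&
      (grid$end[idx[length(idx)]] - grid$start[idx[1]]) >= min_len
  }, logical(1))
  hit <- logical(nrow(poly))
  err_start <- rep(NA_real_, nrow(poly))
  err_end <- rep(NA_real_, nrow(poly))
  for (i in seq_len(nrow(poly))) {
    ov <- which(cnvrs$chrom == poly$chrom[i] & cnvrs$start < poly$end[i] &
                  cnvrs$end > poly$start[i])
    if (!length(ov)) next
    hit[i] <- TRUE
    tot <- abs(cnvrs$start[ov] - poly$start[i]) +
      abs(cnvrs$end[ov] - poly$end[i])
    best <- ov[which.min(tot)]
    err_start[i] <- abs(cnvrs$start[best] - poly$start[i]) / bs
    err_end[i] <- abs(cnvrs$end[best] - poly$end[i]) / bs
  }
  poly$recovered <- hit
  poly$err_start_bins <- err_start
  poly$err_end_bins <- err_end
  n_call <- sum(poly$callable)
  list(n_polymorphic = nrow(poly), n_callable = n_call,
       n_recovered = sum(hit),
       recovery_pct = if (n_call) 100 * sum(hit & poly$callable) / n_call
                      else NaN,
       recovery_pct_all = if (nrow(poly)) 100 * sum(hit) / nrow(poly)
                          else NaN,
       median_boundary_error_bins =
         stats::median(c(err_start[hit], err_end[hit])),
       events = poly)
}
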