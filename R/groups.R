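# Population-group comparison: balanced subsetting, per-group CNVR calling,
# shared/specific partition, and per-group gene statistics.

#' Select a balanced subset of individuals
#'
#' Draws `per_group` members from every group, deterministically for a fixed
#' seed, so group comparisons are not biased by unequal group sizes.
#'
#' @param individuals data frame with `id` and `group` columns.
#' @param per_group members to keep per group.
#' @param seed integer seed.
#' @return the selected rows of `individuals`.
#' @export
subset_individuals <- function(individuals, per_group = 3, seed = 1L) {
  groups <- unique(individuals$group)
  sizes <- table(individuals$group)
  small <- names(sizes)[sizes < per_group]
  if (length(small))
    stop(sprintf("group '%s' has only %d member(s), need %d",
                 small[1], sizes[[small[1]]], per_group), call. = FALSE)
  with_seed(seed, {
    keep <- unlist(lapply(groups, function(g) {
      ids <- individuals$id[individuals$group == g]
      sample(ids, per_group)
    }))
    out <- individuals[individuals$id %in% keep, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Call CNVR sets within groups (and group unions)
#'
#' Re-runs the full CNVR pipeline (merge member MCRs, build the member CN
#' matrix, call by s.d.) separately for each group, and for any requested
#' union of groups using the union's members -- not the union of the
#' per-group call sets, which can legitimately differ.
#'
#' @param individuals data frame (usually from [subset_individuals()]).
#' @param mcrs combined `mcr_set` data frame for all individuals.
#' @param cn_tracks named list of `cn_track` objects.
#' @param grid a `bin_grid`.
#' @param sd_threshold CNVR calling threshold within each set.
#' @param min_size minimum CNVR size in bases.
#' @param combinations optional named list of group-label vectors, e.g.
#'   `list(Asian = c("AsianWild", "AsianDomestic"))`.
#' @return named list of `cnvr_set` objects (one per group and combination).
#' @export
group_cnvr_sets <- function(individuals, mcrs, cn_tracks, grid,
                            sd_threshold = 0.7, min_size = 6000,
                            combinations = NULL) {
  sets <- c(as.list(setNames(unique(individuals$group),
                             unique(individuals$group))),
            combinations)
  lapply(sets, function(gl) {
    ids <- individuals$id[individuals$group %in% gl]
    gm <- mcrs[mcrs$individual %in% ids, , drop = FALSE]
    regions <- merge_mcrs(gm, chrom_levels = unique(grid$chrom))
    mat <- build_cn_matrix(regions, cn_tracks[ids], grid)
    call_cnvrs(mat, sd_threshold, min_size)
  })
}

#' Group-specificity ratio
#'
#' `specific / total`, rounded to two decimals -- the definition consistent
#' with published group summaries (277/2289 -> 0.12; 151/2084 -> 0.07).
#'
#' @param specific,total counts.
#' @return ratio rounded to two decimals.
#' @export
group_specific_ratio <- function(specific, total) {
  round(specific / total, 2)
}

#' Partition a group's CNVRs into shared and group-specific
#'
#' A CNVR of the target group is specific when it overlaps (by at least one
#' base) no CNVR of any other group; otherwise it is shared. Always
#' `shared + specific = total`.
#'
#' @param target a `cnvr_set` (or BED-like data frame) for the target group.
#' @param others list of CNVR sets for the remaining groups.
#' @return list(total, shared, specific, ratio, specific_regions).
#' @export
partition_shared_specific <- function(target, others) {
  other_regions <- do.call(rbind, lapply(others, function(s)
    as.data.frame(s)[, c("chrom", "start", "end"), drop = FALSE]))
  specific <- if (is.null(other_regions) || !nrow(other_regions))
    rep(TRUE, nrow(target))
  else covered_bases(target, other_regions) == 0
  list(total = nrow(target), shared = sum(!specific),
       specific = sum(specific),
       ratio = group_specific_ratio(sum(specific), nrow(target)),
       specific_regions = as.data.frame(target)[specific, , drop = FALSE])
}

#' Per-group gene counts in CNVRs
#'
#' For every group: the candidate genes (>= `min_frac` overlap with the
#' group's CNVR set) and, across the group's members, the mean and s.d. of
#' the per-individual count of candidate genes with exonic CN above `cn_gt`.
#'
#' @param group_sets named list of per-group CNVR sets.
#' @param individuals data frame restricted to the compared members.
#' @param genes,exons gene and exon data frames.
#' @param cn_tracks named list of `cn_track` objects.
#' @param grid a `bin_grid`.
#' @param min_frac overlap-fraction threshold for candidacy.
#' @param cn_gt strict CN threshold for counting a gene in an individual.
#' @return data frame: group, n_cnvrs, n_candidate_genes, mean_gene_count,
#'   sd_gene_count.
#' @export
group_gene_stats <- function(group_sets, individuals, genes, exons,
                             cn_tracks, grid, min_frac = 0.7, cn_gt = 2) {
  out <- lapply(names(group_sets), function(g) {
    set <- group_sets[[g]]
    members <- individuals$id[individuals$group %in% g]
    if (!length(members)) members <- individuals$id
    ov <- overlap_genes(as.data.frame(set), genes, min_frac)
    cand <- genes[ov$candidate, , drop = FALSE]
    if (nrow(cand)) {
      ecn <- gene_exon_cn(cand, exons, cn_tracks[members], grid)
      counts <- colSums(ecn > cn_gt, na.rm = TRUE)
    } else counts <- rep(0L, length(members))
    data.frame(group = g, n_cnvrs = nrow(set),
               n_candidate_genes = nrow(cand),
               mean_gene_count = mean(counts),
               sd_gene_count = if (length(counts) > 1) sd(counts) else NA_real_,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
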