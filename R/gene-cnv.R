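# Gene-level copy-number annotation: CNVR-gene overlap fractions, exon-level
# CN per individual, the gain/dispersion filters, and a generic
# hypergeometric enrichment with Benjamini-Hochberg correction.

#' Gene overlap fractions against a CNVR set
#'
#' For each gene, the fraction of its length covered by the union of CNVRs;
#' genes at or above `min_frac` are candidates (the inclusive 70% rule
#' screens out marginal partial duplications).
#'
#' @param cnvrs BED-like data frame of CNVRs.
#' @param genes data frame with gene_id, chrom, start, end.
#' @param min_frac candidacy threshold on the overlap fraction (inclusive).
#' @return data frame: gene_id, fraction, candidate.
#' @export
overlap_genes <- function(cnvrs, genes, min_frac = 0.7) {
  cov <- covered_bases(genes, cnvrs)
  frac <- cov / (genes$end - genes$start)
  data.frame(gene_id = genes$gene_id, fraction = frac,
             candidate = frac >= min_frac, stringsAsFactors = FALSE)
}

#' Count CNVRs that contain candidate genes
#'
#' @param cnvrs BED-like CNVR data frame.
#' @param genes gene data frame.
#' @param min_frac overlap-fraction threshold for gene candidacy.
#' @return list(n_genic, n_total, percent) where percent is
#'   [genic_cnvr_percent()] of the two counts.
#' @export
genic_cnvrs <- function(cnvrs, genes, min_frac = 0.7) {
  ov <- overlap_genes(cnvrs, genes, min_frac)
  cand <- genes[genes$gene_id %in% ov$gene_id[ov$candidate], , drop = FALSE]
  n_genic <- if (nrow(cand)) sum(covered_bases(cnvrs, cand) > 0) else 0L
  list(n_genic = n_genic, n_total = nrow(cnvrs),
       percent = genic_cnvr_percent(n_genic, nrow(cnvrs)))
}

#' Percentage of CNVRs overlapping genes
#'
#' @param n_genic,n_total counts of gene-overlapping and total CNVRs.
#' @return percentage rounded to two decimals.
#' @export
genic_cnvr_percent <- function(n_genic, n_total) {
  round(100 * n_genic / n_total, 2)
}

#' Exon-level copy number of genes, per individual
#'
#' Aggregates the per-bin CN estimates over each gene's exons, weighting each
#' bin by the exon bases it contributes (depth exists at bin resolution, so
#' exon depth is a bin-overlap-weighted mean; a gene exactly tiling whole
#' bins reproduces the plain bin mean). Excluded bins carry no weight.
#'
#' @param genes gene data frame (gene_id, chrom, start, end).
#' @param exons exon data frame (gene_id, chrom, start, end).
#' @param cn_tracks named list of `cn_track` objects.
#' @param grid a `bin_grid`.
#' @return numeric matrix, genes x individuals, of exonic CN.
#' @export
gene_exon_cn <- function(genes, exons, cn_tracks, grid) {
  ids <- vapply(cn_tracks, function(t) t$id, character(1))
  m <- matrix(NA_real_, nrow = nrow(genes), ncol = length(ids),
              dimnames = list(genes$gene_id, ids))
  ex <- exons[exons$gene_id %in% genes$gene_id, , drop = FALSE]
  if (!nrow(ex)) return(m)
  hits <- GenomicRanges::findOverlaps(as_granges(ex), as_granges(grid))
  ei <- S4Vectors::queryHits(hits)
  bi <- S4Vectors::subjectHits(hits)
  w <- pmin(ex$end[ei], grid$end[bi]) - pmax(ex$start[ei], grid$start[bi])
  gene_of <- match(ex$gene_id[ei], genes$gene_id)
  for (k in seq_along(ids)) {
    tr <- cn_tracks[[k]]
    ok <- !tr$excluded[bi] & !is.na(tr$cn[bi])
    num <- tapply(w[ok] * tr$cn[bi[ok]], gene_of[ok], sum)
    den <- tapply(w[ok], gene_of[ok], sum)
    m[as.integer(names(num)), k] <- as.numeric(num) / as.numeric(den)
  }
  m
}

#' Filter genes by exonic copy-number gain and dispersion
#'
#' Keeps genes whose maximum individual exonic CN strictly exceeds `cn_gt`
#' and whose sample s.d. across individuals reaches `sd_min` (inclusive) --
#' the screen against CNVR calls driven by high-copy segments outside the
#' gene's exons.
#'
#' @param exon_cn genes x individuals matrix from [gene_exon_cn()].
#' @param cn_gt strict lower bound on the maximum individual CN.
#' @param sd_min inclusive threshold on the across-individual s.d.
#' @return data frame: gene_id, max_cn, sd, cn_pass, sd_pass, final.
#' @export
filter_cn_genes <- function(exon_cn, cn_gt = 2, sd_min = 0.5) {
  max_cn <- apply(exon_cn, 1, function(x)
    if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
  sds <- apply(exon_cn, 1, sd, na.rm = TRUE)
  cn_pass <- !is.na(max_cn) & max_cn > cn_gt
  sd_pass <- !is.na(sds) & sds >= sd_min
  data.frame(gene_id = rownames(exon_cn), max_cn = max_cn, sd = sds,
             cn_pass = cn_pass, sd_pass = sd_pass,
             final = cn_pass & sd_pass,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Full gene copy-number report for a CNVR set
#'
#' Combines the overlap-fraction candidacy rule with the exonic CN filters
#' into one per-gene report.
#'
#' @param cnvrs BED-like CNVR data frame.
#' @param genes,exons gene and exon data frames.
#' @param cn_tracks named list of `cn_track` objects.
#' @param grid a `bin_grid`.
#' @param min_frac,cn_gt,sd_min thresholds (see [overlap_genes()] and
#'   [filter_cn_genes()]).
#' @return `gene_cn_report` data frame: gene_id, fraction, max_cn, sd,
#'   overlap_pass, cn_pass, sd_pass, final; attribute `exon_cn` holds the
#'   candidate genes x individuals CN matrix.
#' @export
gene_cn_report <- function(cnvrs, genes, exons, cn_tracks, grid,
                           min_frac = 0.7, cn_gt = 2, sd_min = 0.5) {
  ov <- overlap_genes(cnvrs, genes, min_frac)
  cand <- genes[ov$candidate, , drop = FALSE]
  exon_cn <- gene_exon_cn(cand, exons, cn_tracks, grid)
  filt <- if (nrow(cand)) filter_cn_genes(exon_cn, cn_gt, sd_min)
  else data.frame(gene_id = character(0), max_cn = numeric(0),
                  sd = numeric(0), cn_pass = logical(0),
                  sd_pass = logical(0), final = logical(0))
  rep_ <- data.frame(gene_id = ov$gene_id, fraction = ov$fraction,
                     overlap_pass = ov$candidate, stringsAsFactors = FALSE)
  rep_ <- merge(rep_, filt, by = "gene_id", all.x = TRUE, sort = TRUE)
  rep_$cn_pass[is.na(rep_$cn_pass)] <- FALSE
  rep_$sd_pass[is.na(rep_$sd_pass)] <- FALSE
  rep_$final <- rep_$overlap_pass & rep_$cn_pass & rep_$sd_pass
  attr(rep_, "exon_cn") <- exon_cn
  class(rep_) <- c("gene_cn_report", "data.frame")
  rep_
}

#' Hypergeometric term enrichment with Benjamini-Hochberg correction
#'
#' For each annotation term, the upper-tail hypergeometric probability of
#' drawing at least the observed number of term-annotated genes when sampling
#' the gene set from the background, BH-adjusted over all tested terms.
#'
#' @param genes character vector, the test gene set.
#' @param annotation data frame with columns `term_id`, `gene_id`.
#' @param background character vector of background genes; must contain every
#'   test gene.
#' @return `enrichment_result` data frame: term_id, k (set hits), K
#'   (background hits), n (set size), N (background size), p, q; sorted by p.
#' @export
enrich <- function(genes, annotation, background) {
  genes <- unique(genes)
  background <- unique(background)
  missing <- setdiff(genes, background)
  if (length(missing))
    stop(sprintf("background does not contain test gene(s): %s",
                 paste(head(missing, 5), collapse = ", ")), call. = FALSE)
  ann <- annotation[annotation$gene_id %in% background, , drop = FALSE]
  N <- length(background)
  n <- length(genes)
  terms <- unique(ann$term_id)
  res <- do.call(rbind, lapply(terms, function(tm) {
    tg <- unique(ann$gene_id[ann$term_id == tm])
    K <- length(tg)
    k <- length(intersect(tg, genes))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = tm, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  }))
  if (is.null(res))
    res <- data.frame(term_id = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0))
  res$q <- p.adjust(res$p, method = "BH")
  res <- res[order(res$p, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}
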