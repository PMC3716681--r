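# Gene-level annotation: overlap fractions, exon CN, filters, enrichment.

test_that("gene overlap fractions are per-base exact with inclusive 70%", {
  genes <- data.frame(gene_id = c("g1", "g2", "g3"), chrom = "c1",
                      start = c(0, 20000, 40000),
                      end = c(10000, 30000, 50000),
                      stringsAsFactors = FALSE)
  cnvrs <- data.frame(chrom = "c1",
                      start = c(0, 20000, 40000),
                      end = c(10000, 26900, 47000))
  ov <- overlap_genes(cnvrs, genes)
  expect_equal(ov$fraction, c(1, 0.69, 0.7))
  expect_identical(ov$candidate, c(TRUE, FALSE, TRUE))  # >= is inclusive

  # per-base oracle on random inputs, and invariance to book-ended splits
  set.seed(21)
  for (rep_i in 1:10) {
    g1 <- data.frame(gene_id = "g", chrom = "c1", start = 5000, end = 25000)
    n <- 6
    cs <- sample(seq(0, 30000, 500), n)
    cn <- data.frame(chrom = "c1", start = cs, end = cs + 4000)
    frac <- overlap_genes(cn, g1)$fraction
    expect_equal(frac, oracle_cov_bases(5000, 25000, cn) / 20000)
    # split each CNVR into two book-ended halves
    halves <- rbind(data.frame(chrom = "c1", start = cn$start,
                               end = cn$start + 2000),
                    data.frame(chrom = "c1", start = cn$start + 2000,
                               end = cn$end))
    expect_equal(overlap_genes(halves, g1)$fraction, frac)
  }
})

test_that("exonic CN equals the bin mean on exact tilings and tracks truth", {
  grid <- bin_grid(c(c1 = 5e4))
  genes <- data.frame(gene_id = "g1", chrom = "c1", start = 10000,
                      end = 20000, stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = "g1", chrom = "c1", start = 10000,
                      end = 20000, stringsAsFactors = FALSE)  # whole-bin tiling
  set.seed(4)
  cnv <- rnorm(50, 3, 0.5)
  tr <- make_cn_track("a", cnv)
  m <- gene_exon_cn(genes, exons, list(tr), grid)
  expect_equal(unname(m["g1", "a"]), mean(cnv[11:20]), tolerance = 1e-12)

  # partial-bin exons are overlap-weighted
  exons2 <- data.frame(gene_id = "g1", chrom = "c1", start = 10500,
                       end = 11500, stringsAsFactors = FALSE)
  m2 <- gene_exon_cn(genes, exons2, list(tr), grid)
  expect_equal(unname(m2["g1", "a"]), (cnv[11] + cnv[12]) / 2,
               tolerance = 1e-12)
})

test_that("exonic CN recovers simulated gains and flags diploid-exon genes", {
  gen <- simulate_genome(tiny_config(n_repeats = 0), seed = 31)
  co <- tiny_cohort(n_per_group = 1)
  sim <- simulate_cohort(gen, co,
                         cnv_params(n_shared = 2, n_group = 0, n_private = 0,
                                    cn_range = c(6, 6), size_max = 20000),
                         seed = 8)
  tracks <- lapply(co$id, function(id)
    estimate_cn_track(sim$depths[[id]], gen, sex = co$sex[co$id == id],
                      min_ortholog_bins = 50)$cn)

  ev <- sim$truth$events[1, ]
  gene_in <- data.frame(gene_id = "in_event", chrom = ev$chrom,
                        start = ev$start, end = ev$start + 4000,
                        stringsAsFactors = FALSE)
  exon_in <- gene_in
  m <- gene_exon_cn(gene_in, exon_in, tracks, grid = gen$grid)
  expect_true(all(m > 5.5 & m < 6.5))

  # a diploid individual-level screen: gene body overlaps the event but all
  # exons sit outside it -> exonic CN ~2, cn_pass fails
  gene_out <- data.frame(gene_id = "exons_out", chrom = ev$chrom,
                         start = ev$start, end = ev$end + 4000,
                         stringsAsFactors = FALSE)
  exon_out <- data.frame(gene_id = "exons_out", chrom = ev$chrom,
                         start = ev$end + 1000, end = ev$end + 3000,
                         stringsAsFactors = FALSE)
  m2 <- gene_exon_cn(gene_out, exon_out, tracks, grid = gen$grid)
  expect_true(all(m2 > 1.6 & m2 < 2.4))  # exons read diploid
  filt <- filter_cn_genes(m2)
  expect_false(filt$final)  # the CN/s.d. screen rejects the false positive
  expect_false(filt$sd_pass)
})

test_that("gene filters apply strict CN and inclusive s.d. thresholds", {
  mk <- function(v) matrix(v, nrow = 1, dimnames = list("g", NULL))
  # all individuals at exactly CN 2: excluded
  expect_false(filter_cn_genes(mk(rep(2, 16)))$final)
  # constructed vector: fifteen 2s and one 4
  v <- c(rep(2, 15), 4)
  f <- filter_cn_genes(mk(v))
  expect_equal(f$sd, sd(v))
  expect_identical(f$final, sd(v) >= 0.5 && max(v) > 2)

  # toy cohort: brute-force filter agreement, 2 of 10 genes fail
  set.seed(9)
  m <- matrix(2, nrow = 10, ncol = 8,
              dimnames = list(paste0("g", 1:10), paste0("i", 1:8)))
  m[1:8, 1] <- 6  # eight genes gain in one individual
  f2 <- filter_cn_genes(m)
  manual <- vapply(1:10, function(i)
    max(m[i, ]) > 2 && sd(m[i, ]) >= 0.5, logical(1))
  expect_identical(f2$final, manual)
  expect_identical(sum(f2$final), 8L)
})

test_that("hypergeometric enrichment matches exact combinatorics and BH", {
  ann <- data.frame(term_id = rep("t1", 5),
                    gene_id = paste0("g", 1:5), stringsAsFactors = FALSE)
  bg <- paste0("g", 1:20)

  # all five set genes annotated: p = 1 / choose(20, 5)
  res <- enrich(paste0("g", 1:5), ann, bg)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)
  # exhaustive oracle: probability of k = 5 from the hypergeometric support
  k_support <- 0:5
  probs <- choose(5, k_support) * choose(15, 5 - k_support) / choose(20, 5)
  expect_equal(res$p, sum(probs[k_support >= 5]), tolerance = 1e-12)

  # a term annotating every background gene is never enriched
  ann_all <- data.frame(term_id = "t_all", gene_id = bg)
  expect_equal(enrich(paste0("g", 1:5), ann_all, bg)$p, 1)

  expect_error(enrich("nope", ann, bg), "background")

  # BH step-up on (0.01, 0.02, 0.03, 0.04) gives q = 0.04 everywhere
  ann4 <- data.frame(term_id = paste0("t", 1:4),
                     gene_id = c("g1", "g2", "g3", "g4"))
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))

  # BH monotonicity and q <= 1 on random p-vectors, via enrich()
  set.seed(12)
  for (rep_i in 1:5) {
    terms <- paste0("t", 1:15)
    ann_r <- data.frame(
      term_id = rep(terms, each = 4),
      gene_id = sample(bg, 60, replace = TRUE), stringsAsFactors = FALSE)
    res_r <- enrich(sample(bg, 6), ann_r, bg)
    expect_true(all(res_r$q >= res_r$p - 1e-12))
    expect_true(all(res_r$q <= 1))
    expect_true(all(diff(res_r$q) >= -1e-12))  # sorted by p
  }
})

test_that("the combined gene report wires overlap and CN filters together", {
  grid <- bin_grid(c(c1 = 5e4))
  genes <- data.frame(gene_id = c("hit", "miss"), chrom = "c1",
                      start = c(10000, 30000), end = c(16000, 36000),
                      stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = c("hit", "miss"), chrom = "c1",
                      start = c(10000, 30000), end = c(16000, 36000),
                      stringsAsFactors = FALSE)
  cnvrs <- data.frame(chrom = "c1", start = 10000, end = 16000)
  cn <- rep(2, 50); cn[11:16] <- 6
  tracks <- list(make_cn_track("a", cn), make_cn_track("b", rep(2, 50)))
  rep_ <- gene_cn_report(cnvrs, genes, exons, tracks, grid)
  expect_identical(rep_$final[rep_$gene_id == "hit"], TRUE)
  expect_identical(rep_$final[rep_$gene_id == "miss"], FALSE)
  expect_identical(rep_$overlap_pass[rep_$gene_id == "miss"], FALSE)

  g <- genic_cnvrs(cnvrs, genes)
  expect_identical(g$n_genic, 1L)
  expect_equal(genic_cnvr_percent(454, 3118), 14.56)
})
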