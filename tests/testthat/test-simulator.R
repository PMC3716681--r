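# Synthetic genome and cohort generator.

test_that("genome simulation is deterministic and respects its config", {
  g1 <- simulate_genome(tiny_config(), seed = 7)
  g2 <- simulate_genome(tiny_config(), seed = 7)
  expect_identical(g1$grid, g2$grid)
  expect_identical(g1$genes, g2$genes)
  expect_identical(g1$sds, g2$sds)
  expect_identical(g1$repeats, g2$repeats)
  g3 <- simulate_genome(tiny_config(), seed = 8)
  expect_false(identical(g1$grid$gc, g3$grid$gc))

  # bin lattice: contiguous, sorted, within-bounds fractions
  grid <- g1$grid
  expect_true(all(grid$gc >= 0 & grid$gc <= 1))
  expect_true(all(grid$masked >= 0 & grid$masked <= 1))
  for (ch in unique(grid$chrom)) {
    b <- grid[grid$chrom == ch, ]
    expect_identical(b$start, seq(0, by = 1000, length.out = nrow(b)))
    expect_identical(b$end, b$start + 1000)
  }
})

test_that("a repeat-free config yields an unmasked genome", {
  g <- simulate_genome(tiny_config(n_repeats = 0), seed = 2)
  expect_identical(nrow(g$repeats), 0L)
  expect_true(all(g$grid$masked == 0))
})

test_that("invalid genome configs fail loudly", {
  expect_error(simulate_genome(genome_config(chromosomes = c(c1 = 5000)),
                               seed = 1), "10 \\* bin_size")
  expect_error(simulate_genome(genome_config(chromosomes = c(c1 = 1e5 + 1)),
                               seed = 1), "multiple")
})

test_that("with full SD-near-event weight every SD midpoint is within 10 kb of an event", {
  cfg <- tiny_config(sd_near_event_frac = 1, n_event_sites = 12, n_sds = 15)
  g <- simulate_genome(cfg, seed = 5)
  truth <- simulate_truth(g, tiny_cohort(),
                          cnv_params(n_shared = 4, n_group = 4, n_private = 4,
                                     size_max = 20000), seed = 5)
  ev <- truth$events
  # brute-force distance scan from each SD midpoint to every event interval
  for (i in seq_len(nrow(g$sds))) {
    mid <- (g$sds$start[i] + g$sds$end[i]) / 2
    dists <- vapply(seq_len(nrow(ev)), function(j) {
      if (ev$chrom[j] != g$sds$chrom[i]) return(Inf)
      if (mid >= ev$start[j] && mid < ev$end[j]) return(0)
      min(abs(mid - ev$start[j]), abs(mid - ev$end[j]))
    }, numeric(1))
    expect_lte(min(dists), 10000)
  }
})

test_that("truth profiles honour scope, X rules and the diploid anchor", {
  g <- simulate_genome(tiny_config(), seed = 3)
  co <- tiny_cohort()

  flat <- simulate_truth(g, co, cnv_params(n_shared = 0, n_group = 0,
                                           n_private = 0), seed = 1)
  expect_identical(nrow(flat$events), 0L)
  on_x <- g$grid$chrom == "chrX"
  in_par <- g$grid$start < 5e4 & on_x
  for (j in seq_len(nrow(co))) {
    expected <- rep(2L, nrow(g$grid))
    if (co$sex[j] == "M") expected[on_x & !in_par] <- 1L
    expect_identical(flat$cn[, j], expected)
  }

  one <- simulate_truth(g, co, cnv_params(n_shared = 1, n_group = 0,
                                          n_private = 0, cn_range = c(6, 6),
                                          size_max = 20000), seed = 2)
  ev <- one$events
  idx <- which(g$grid$chrom == ev$chrom & g$grid$start >= ev$start &
                 g$grid$end <= ev$end)
  expect_true(all(one$cn[idx, ] == 6L))

  # events never intersect ortholog regions (per-base oracle)
  truth <- simulate_truth(g, co, quick_params(), seed = 9)
  for (i in seq_len(nrow(truth$events))) {
    same <- g$orthologs[g$orthologs$chrom == truth$events$chrom[i], ]
    if (!nrow(same)) next
    expect_identical(oracle_cov_bases(truth$events$start[i],
                                      truth$events$end[i], same), 0L)
  }

  # group events hit all members of exactly one group; private exactly one
  for (i in which(truth$events$scope == "group")) {
    ev <- truth$events[i, ]
    idx <- which(g$grid$chrom == ev$chrom & g$grid$start >= ev$start &
                   g$grid$end <= ev$end)
    carriers <- colnames(truth$cn)[apply(truth$cn[idx, , drop = FALSE], 2,
                                         function(x) all(x == ev$cn))]
    expect_setequal(carriers, co$id[co$group == ev$target])
  }
})

test_that("event sizes follow the configured truncated distribution", {
  p <- cnv_params()
  sizes <- rdcnv:::with_seed(4, rdcnv:::draw_event_sizes(400, p, 1000))
  expect_true(all(sizes >= p$size_min & sizes <= p$size_max))
  expect_true(all(sizes %% 1000 == 0))
  # analytic mean by enumeration of the discrete support
  m <- rdcnv:::event_size_mean(p, 1000)
  se <- sd(sizes) / sqrt(length(sizes))
  expect_lt(abs(mean(sizes) - m), 2 * se + 1e-9)
})

test_that("depth simulation matches its generative expectation", {
  g <- simulate_genome(tiny_config(n_repeats = 0), seed = 6)
  n <- nrow(g$grid)
  cn2 <- rep(2L, n)

  # flat bias, CN 2, coverage 8: genome-wide mean = 8 within 3 s.e.
  tr <- simulate_depth(g, cn2, coverage = 8, gc_bias = NULL,
                       dispersion = 0.005, seed = 1)
  se <- sd(tr$depth) / sqrt(n)
  expect_lt(abs(mean(tr$depth) - 8), 3 * se)

  # CN 4 vs CN 2 at identical GC: depth ratio 2 within sampling error
  cn_mix <- rep(c(2L, 4L), length.out = n)
  gflat <- function(gc) rep(1, length(gc))
  tr2 <- simulate_depth(g, cn_mix, coverage = 8, gc_bias = gflat,
                        dispersion = 0.005, seed = 2)
  m4 <- mean(tr2$depth[cn_mix == 4]); m2 <- mean(tr2$depth[cn_mix == 2])
  expect_lt(abs(m4 / m2 - 2), 0.05)

  # conservation of the expectation, pre-noise
  mu <- expected_depth(g, cn_mix, 8, gflat)
  expect_equal(sum(mu), sum(8 / 2 * cn_mix * gflat(g$grid$gc) *
                              (1 - g$grid$masked)), tolerance = 1e-12)

  # determinism and seed independence
  expect_identical(simulate_depth(g, cn2, 8, seed = 3)$depth,
                   simulate_depth(g, cn2, 8, seed = 3)$depth)
  expect_false(identical(simulate_depth(g, cn2, 8, seed = 3)$depth,
                         simulate_depth(g, cn2, 8, seed = 4)$depth))
})

test_that("depth simulation rejects invalid inputs", {
  g <- simulate_genome(tiny_config(), seed = 1)
  cn <- rep(2L, nrow(g$grid))
  expect_error(simulate_depth(g, cn, coverage = 0), "coverage")
  expect_error(simulate_depth(g, cn, coverage = 8,
                              gc_bias = function(gc) gc - 0.5), "positive")
})

test_that("the reference cohort matches the published design", {
  co <- pig_cohort()
  expect_identical(nrow(co), 16L)
  expect_identical(as.vector(table(co$group)[c("AsianWild", "AsianDomestic",
                                               "EuropeanWild",
                                               "EuropeanDomestic")]),
                   c(3L, 5L, 3L, 5L))
  expect_true(all(co$coverage >= 7.1 & co$coverage <= 11))
})
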