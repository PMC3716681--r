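# GC correction and copy-number estimation.

flat_genome <- function(n_bins = 1000, gc = 0.4) {
  grid <- bin_grid(c(chr1 = n_bins * 1000), gc = gc)
  bare_genome(grid,
              orthologs = data.frame(chrom = "chr1", start = 0,
                                     end = 300 * 1000))
}

test_that("the seeded baseline is the mean over ortholog bins only", {
  g <- flat_genome()
  tr <- depth_track("a", rep(8, 1000))
  expect_equal(seed_baseline(tr, g$orthologs, g$grid)$D, 8)

  # locality: depth 8 on ortholog bins, 16 elsewhere
  d <- rep(16, 1000); d[1:300] <- 8
  expect_equal(seed_baseline(depth_track("a", d), g$orthologs, g$grid)$D, 8)

  expect_error(seed_baseline(tr, g$orthologs[0, ], g$grid),
               "baseline unstable")
})

test_that("the seeded baseline equals a brute-force mean on biased data", {
  gen <- simulate_genome(tiny_config(), seed = 11)
  bias <- function(gc) 1 + 0.5 * (gc - 0.4)
  cn <- rep(2L, nrow(gen$grid))
  tr <- simulate_depth(gen, cn, 8, gc_bias = bias, seed = 1)
  b <- seed_baseline(tr, gen$orthologs, gen$grid, min_bins = 50)
  # direct recomputation over the same bin set
  eff <- tr$depth / (1 - pmin(gen$grid$masked, 0.8))
  expect_equal(b$D, mean(eff[b$bins]), tolerance = 1e-9)
  # X orthologs are excluded from the anchor
  expect_true(all(gen$grid$chrom[b$bins] != "chrX"))
})

test_that("diploid-bin prediction applies the provisional-CN window per bin", {
  g <- flat_genome()
  d <- rep(8, 1000)
  d[501:520] <- 24  # a CN 6 region
  tr <- depth_track("a", d)
  b <- seed_baseline(tr, g$orthologs, g$grid)
  dip <- predict_diploid_bins(tr, b, g$grid)
  expect_false(any(501:520 %in% dip))
  expect_setequal(dip, setdiff(1:1000, 501:520))

  # per-bin oracle on noisy data
  gen <- simulate_genome(tiny_config(), seed = 12)
  tr2 <- simulate_depth(gen, rep(2L, nrow(gen$grid)), 8, seed = 2)
  b2 <- seed_baseline(tr2, gen$orthologs, gen$grid, min_bins = 50)
  dip2 <- predict_diploid_bins(tr2, b2, gen$grid)
  eff <- tr2$depth / (1 - pmin(gen$grid$masked, 0.8))
  cn_prov <- 2 * eff / b2$D
  manual <- which(gen$grid$masked <= 0.8 & cn_prov >= 1.5 & cn_prov <= 2.5)
  expect_identical(dip2, manual)

  expect_error(predict_diploid_bins(tr, b, g$grid, window = c(90, 99)),
               "refinement failed")
  b$stage <- "refined"
  expect_error(predict_diploid_bins(tr, b, g$grid), "ortholog_seed")
})

test_that("GC factors are near 1 without bias and invert an injected bias", {
  gen <- simulate_genome(tiny_config(chromosomes = c(chrA = 8e6),
                                     x_chrom = NA_character_, n_repeats = 0,
                                     n_genes = 150, gc_sd = 0.025),
                         seed = 13)
  cn <- rep(2L, nrow(gen$grid))

  # no bias: factors of well-supported intervals within [0.97, 1.03]
  tr <- simulate_depth(gen, cn, 8, seed = 3)
  b <- seed_baseline(tr, gen$orthologs, gen$grid)
  dip <- predict_diploid_bins(tr, b, gen$grid)
  tab <- estimate_gc_correction(tr, dip, gen$grid)
  rich <- tab$support >= 500
  expect_gt(sum(rich), 5)
  expect_true(all(tab$factor[rich] >= 0.97 & tab$factor[rich] <= 1.03))

  # injected linear bias: factor_i ~ mean(g over diploid bins) / g(mid_i)
  bias <- function(gc) 1 + 0.5 * (gc - 0.4)
  trb <- simulate_depth(gen, cn, 8, gc_bias = bias, seed = 4)
  bb <- seed_baseline(trb, gen$orthologs, gen$grid)
  dipb <- predict_diploid_bins(trb, bb, gen$grid)
  tabb <- estimate_gc_correction(trb, dipb, gen$grid)
  richb <- which(tabb$support >= 500)
  g_mean <- mean(bias(gen$grid$gc[dipb]))
  mids <- (tabb$gc_lo[richb] + tabb$gc_hi[richb]) / 2
  expect_lt(max(abs(tabb$factor[richb] - g_mean / bias(mids))), 0.05)
})

test_that("a single populated GC interval degenerates to unit factors", {
  g <- flat_genome(gc = 0.405)  # constant GC: one populated interval
  tr <- depth_track("a", rep(8, 1000))
  b <- seed_baseline(tr, g$orthologs, g$grid)
  dip <- predict_diploid_bins(tr, b, g$grid)
  expect_warning(tab <- estimate_gc_correction(tr, dip, g$grid),
                 "degenerate")
  expect_true(all(tab$factor == 1))
})

test_that("depth correction is the per-interval factor product", {
  g <- flat_genome()
  tr <- depth_track("a", rep(8, 1000))
  b <- seed_baseline(tr, g$orthologs, g$grid)
  dip <- predict_diploid_bins(tr, b, g$grid)
  tab <- suppressWarnings(estimate_gc_correction(tr, dip, g$grid))

  # identity when all factors are 1
  tab$factor <- rep(1, nrow(tab))
  corr <- correct_depth(tr, tab, g$grid)
  expect_identical(corr$depth, tr$depth)
  expect_true(corr$corrected)

  # exact doubling inside one interval
  tab2 <- tab
  hit <- tab2$gc_lo <= 0.4 & tab2$gc_hi > 0.4
  tab2$factor[hit] <- 2
  corr2 <- correct_depth(tr, tab2, g$grid)
  expect_identical(corr2$depth, tr$depth * 2)  # all bins have GC 0.4
  expect_error(correct_depth(corr2, tab2, g$grid), "already")
})

test_that("GC correction flattens the depth-GC relationship", {
  gen <- simulate_genome(tiny_config(chromosomes = c(chrA = 5e6),
                                     x_chrom = NA_character_, n_repeats = 0,
                                     n_genes = 150),
                         seed = 14)
  cn <- rep(2L, nrow(gen$grid))
  bias <- function(gc) 1 + 0.5 * (gc - 0.4)
  tr <- simulate_depth(gen, cn, 8, gc_bias = bias, seed = 5)
  b <- seed_baseline(tr, gen$orthologs, gen$grid)
  dip <- predict_diploid_bins(tr, b, gen$grid)
  tab <- estimate_gc_correction(tr, dip, gen$grid)
  corr <- correct_depth(tr, tab, gen$grid)

  gc <- gen$grid$gc[dip]
  slope_raw <- coef(lm(tr$depth[dip] ~ gc))[2]
  slope_corr <- coef(lm(corr$depth[dip] ~ gc))[2]
  expect_gt(abs(slope_raw) / abs(slope_corr), 5)
  expect_lt(abs(cor(corr$depth[dip], gc)), 0.05)
})

test_that("CN estimation applies the diploid ratio and male-X doubling", {
  grid <- bin_grid(c(chr1 = 2e5, chrX = 2e5), x_chrom = "chrX")
  par <- data.frame(chrom = "chrX", start = 0, end = 5e4)
  g <- bare_genome(grid, orthologs = data.frame(chrom = "chr1", start = 0,
                                                end = 2e5), par = par)
  on_x <- grid$chrom == "chrX"
  d <- rep(8, nrow(grid))
  d[on_x] <- 4  # haploid X depth
  d[on_x & grid$start < 5e4] <- 8  # PAR is diploid in males
  corr <- depth_track("m", d, corrected = TRUE)
  base <- structure(list(D = 8, stage = "refined", bins = 1:200, n = 200),
                    class = "diploid_baseline")

  cn_m <- estimate_cn(corr, base, grid, sex = "M", par = par)
  expect_equal(unique(cn_m$cn[!on_x]), 2)
  expect_equal(unique(cn_m$cn[on_x & grid$start >= 5e4]), 2)  # doubled
  expect_equal(unique(cn_m$cn[on_x & grid$start < 5e4]), 2)   # PAR as-is

  cn_f <- estimate_cn(corr, base, grid, sex = "F", par = par)
  expect_equal(unique(cn_f$cn[on_x & grid$start >= 5e4]), 1)

  base$stage <- "ortholog_seed"
  expect_error(estimate_cn(corr, base, grid), "refined")
  base$stage <- "refined"; base$D <- 0
  expect_error(estimate_cn(corr, base, grid), "non-positive")
})

test_that("sex parity holds on X after male correction", {
  gen <- simulate_genome(tiny_config(), seed = 15)
  co <- tiny_cohort()
  sim <- simulate_cohort(gen, co, cnv_params(n_shared = 0, n_group = 0,
                                             n_private = 0), seed = 6)
  fit_m <- estimate_cn_track(sim$depths[["AsW1"]], gen, sex = "M",
                             min_ortholog_bins = 50)
  fit_f <- estimate_cn_track(sim$depths[["AsW2"]], gen, sex = "F",
                             min_ortholog_bins = 50)
  on_x <- gen$grid$chrom == "chrX" & gen$grid$start >= 5e4
  ok <- !fit_m$cn$excluded & !fit_f$cn$excluded & on_x
  expect_lt(abs(mean(fit_m$cn$cn[ok]) - mean(fit_f$cn$cn[ok])), 0.1)
})

test_that("estimated CN is unbiased against simulated truth", {
  gen <- simulate_genome(tiny_config(n_event_sites = 16,
                                     max_event_size = 12000), seed = 16)
  co <- tiny_cohort(n_per_group = 1)
  sim <- simulate_cohort(gen, co,
                         cnv_params(n_shared = 8, n_group = 4, n_private = 4,
                                    size_max = 12000), seed = 7)
  est <- NULL; tru <- NULL
  for (id in co$id) {
    fit <- estimate_cn_track(sim$depths[[id]], gen,
                             sex = co$sex[co$id == id],
                             min_ortholog_bins = 50)
    ev_bins <- which(sim$truth$cn[, id] > 2 & !fit$cn$excluded)
    est <- c(est, fit$cn$cn[ev_bins])
    tru <- c(tru, sim$truth$cn[ev_bins, id])
  }
  expect_gt(length(unique(tru)), 3)
  fit_lm <- lm(est ~ tru)
  expect_gt(coef(fit_lm)[2], 0.95)
  expect_lt(coef(fit_lm)[2], 1.05)
  expect_lt(abs(coef(fit_lm)[1]), 0.1)

  # per-region recovery: a CN 4 region at 8x lands within [3.8, 4.2]
  ev <- sim$truth$events[sim$truth$events$scope == "shared" &
                           sim$truth$events$cn == 4, ][1, ]
  if (!is.na(ev$event_id)) {
    fit <- estimate_cn_track(sim$depths[[co$id[1]]], gen, sex = co$sex[1],
                             min_ortholog_bins = 50)
    idx <- which(gen$grid$chrom == ev$chrom & gen$grid$start >= ev$start &
                   gen$grid$end <= ev$end & !fit$cn$excluded)
    expect_gt(mean(fit$cn$cn[idx]), 3.8)
    expect_lt(mean(fit$cn$cn[idx]), 4.2)
  }
})

test_that("refined baseline matches a direct mean and flags excluded bins", {
  g <- flat_genome()
  corr <- depth_track("a", c(rep(9, 500), rep(7, 500)), corrected = TRUE)
  b <- refine_baseline(corr, 1:1000, g$grid)
  expect_equal(b$D, 8)
  expect_identical(b$stage, "refined")
  b2 <- refine_baseline(corr, 1:500, g$grid)
  expect_equal(b2$D, 9)
  expect_error(refine_baseline(depth_track("a", rep(1, 1000)), 1:10,
                               g$grid), "GC-corrected")
})
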