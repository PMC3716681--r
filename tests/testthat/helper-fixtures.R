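# Small fixtures built in code at test time.

# compact genome for fast end-to-end tests
tiny_config <- function(...) {
  base <- list(chromosomes = c(chrA = 8e5, chrB = 6e5, chrX = 4e5),
               par_end = 5e4, n_genes = 40, gene_len = c(2e3, 1e4),
               ortholog_frac = 0.5, n_sds = 12, n_repeats = 80,
               n_event_sites = 16, max_event_size = 20000)
  do.call(genome_config, utils::modifyList(base, list(...)))
}

tiny_cohort <- function(n_per_group = 2, coverage = 8) {
  groups <- c("AsianWild", "AsianDomestic", "EuropeanWild",
              "EuropeanDomestic")
  abbr <- c("AsW", "AsD", "EuW", "EuD")
  data.frame(
    id = paste0(rep(abbr, each = n_per_group), seq_len(n_per_group)),
    group = rep(groups, each = n_per_group),
    sex = rep_len(c("M", "F"), 4 * n_per_group),
    coverage = coverage, stringsAsFactors = FALSE)
}

# minimal genome-like object around a hand-built grid
bare_genome <- function(grid, orthologs = NULL, par = NULL) {
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE)
  list(grid = grid, orthologs = orthologs %||% empty, par = par %||% empty,
       genes = empty, exons = empty, sds = empty,
       repeats = cbind(empty, family = character(0)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# hand-built CN track
make_cn_track <- function(id, cn, excluded = NULL) {
  structure(list(id = id, cn = as.numeric(cn),
                 excluded = excluded %||% rep(FALSE, length(cn))),
            class = "cn_track")
}

# small deterministic event-size parameters used in several tests
quick_params <- function(...) {
  base <- list(n_shared = 4, n_group = 4, n_private = 4, size_max = 20000)
  do.call(cnv_params, utils::modifyList(base, list(...)))
}
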