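# Small fixtures built in code.

rast <- function(m, cs = 100) resistance_raster(m, cell_size_m = cs)

# genotype table with explicit calls; one row per individual,
# two columns per locus
tiny_table <- function(calls, site_id, loci = NULL,
                       sites = NULL) {
  n <- nrow(calls)
  if (is.null(loci)) loci <- sprintf("L%d", seq_len(ncol(calls) / 2))
  if (is.null(sites)) {
    u <- unique(site_id)
    sites <- data.frame(site_id = u, x = seq_along(u) * 1000, y = 0)
  }
  genotype_table(
    individuals = data.frame(individual_id = sprintf("i%d", seq_len(n)),
                             site_id = site_id, stringsAsFactors = FALSE),
    loci = loci, calls = calls, sites = sites)
}

# genotypes for n sites with site-specific allele frequencies; no landscape
freq_table <- function(freqs, n_per_site = 10, n_loci = 5, seed = 1) {
  ns <- nrow(freqs)  # freqs: sites x alleles
  withr::with_seed(seed, {
    calls <- NULL
    site <- rep(sprintf("S%d", seq_len(ns)), each = n_per_site)
    for (l in seq_len(n_loci)) {
      a1 <- a2 <- integer(0)
      for (s in seq_len(ns)) {
        a1 <- c(a1, sample.int(ncol(freqs), n_per_site, TRUE, prob = freqs[s, ]))
        a2 <- c(a2, sample.int(ncol(freqs), n_per_site, TRUE, prob = freqs[s, ]))
      }
      calls <- cbind(calls, a1, a2)
    }
    tiny_table(calls, site)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# records table with arbitrary covariates, bypassing the raster stack
fake_records <- function(X, y = NULL, species = "sp", n = NULL, seed = 1) {
  stopifnot(ncol(X) == 12)
  cols <- as.vector(outer(c("mean_cost_r", "sd_cost_r", "mean_cur_r", "sd_cur_r"),
                          1:3, paste0))
  colnames(X) <- cols
  recs <- withr::with_seed(seed, data.frame(
    site_id = sprintf("S%d", seq_len(nrow(X))),
    species = species,
    n = n %||% sample(10:40, nrow(X), TRUE),
    x = runif(nrow(X), 0, 1e5), y = runif(nrow(X), 0, 1e5),
    degree = 2L, mean_weight = 1,
    mean_inv_weight = y %||% runif(nrow(X)),
    z_mean_inv_weight = 0, stringsAsFactors = FALSE))
  recs <- cbind(recs, as.data.frame(X))
  attr(recs, "covariate_cols") <- cols
  recs
}
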