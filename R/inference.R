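#' PCA of the landscape covariates
#'
#' Correlation-matrix principal component analysis of the buffered landscape
#' covariates (the covariates are z-scored, so this is PCA of their
#' correlation structure). Retention is either a fixed number of components
#' or the smallest number whose cumulative variance share reaches a target.
#' Each loading column's sign is fixed so its largest-magnitude element is
#' positive.
#'
#' @param records an [assemble_records()] table.
#' @param k_rule `"fixed"` (default) or `"cumulative"`.
#' @param k number of PCs under `k_rule = "fixed"` (default 4).
#' @param cum_target cumulative variance target under `"cumulative"`
#'   (default 0.85).
#' @param loading_threshold absolute loading above which a covariate is
#'   flagged as a major contributor (default 0.25).
#' @return a `pca_result`: list with `loadings` (p x k), `all_loadings`,
#'   `variance_explained`, `cumulative`, `scores` (n x k), `k`,
#'   `major_contributors` (logical p x k).
#' @export
run_pca <- function(records, k_rule = c("fixed", "cumulative"), k = 4L,
                    cum_target = 0.85, loading_threshold = 0.25) {
  k_rule <- match.arg(k_rule)
  cov_cols <- attr(records, "covariate_cols")
  if (is.null(cov_cols)) stopf("records lack covariate metadata; use assemble_records()")
  X <- as.matrix(records[, cov_cols])
  Z <- scale(X)
  Z[, apply(X, 2, sd) == 0] <- 0
  if (nrow(Z) <= ncol(Z))
    log_msg("inference", "fewer nodes (%d) than covariates (%d): rank-deficient PCA",
            nrow(Z), ncol(Z))
  eig <- eigen(cor(X), symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  prop <- vals / sum(vals)
  load <- eig$vectors
  # sign convention: largest-|.| element of each column positive
  for (j in seq_len(ncol(load))) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  dimnames(load) <- list(cov_cols, paste0("PC", seq_len(ncol(load))))
  k_used <- if (k_rule == "fixed") min(k, ncol(load)) else
    which(cumsum(prop) >= cum_target)[1]
  scores <- Z %*% load
  structure(list(loadings = load[, seq_len(k_used), drop = FALSE],
                 all_loadings = load,
                 variance_explained = prop, cumulative = cumsum(prop),
                 scores = scores[, seq_len(k_used), drop = FALSE],
                 all_scores = scores, k = k_used,
                 major_contributors = abs(load[, seq_len(k_used), drop = FALSE]) >
                   loading_threshold),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d PCs retained; cumulative variance %.1f%%\n",
              x$k, 100 * x$cumulative[x$k]))
  print(round(rbind(proportion = x$variance_explained[seq_len(x$k)],
                    cumulative = x$cumulative[seq_len(x$k)]), 3))
  invisible(x)
}

#' OLS regression of node genetic connectivity on landscape structure
#'
#' Models the within-species z-scored average inverse edge weight against
#' projected x, y coordinates, sample size, and the retained PC scores, for
#' the full node set or a species-defined subset (e.g. northern or southern
#' species groups). Predictors are z-scored within the modeled subset and
#' the response is re-standardized within species over the subset's nodes,
#' so slopes are standardized effects.
#'
#' @param records an [assemble_records()] table.
#' @param pca a [run_pca()] result computed on the same records.
#' @param subset `"full"`, `"north"`, or `"south"`.
#' @param north_species,south_species character vectors of species labels
#'   defining the subsets.
#' @param conf_level confidence level for slope CIs (default 0.95, via the
#'   t distribution at the residual degrees of freedom).
#' @param standardize_response re-standardize the response within species
#'   over the subset's nodes (default TRUE). Set FALSE when
#'   `mean_inv_weight` already carries the response on the scale to model.
#' @return a `regression_result`: list with `coefficients` (term, slope, se,
#'   ci_lo, ci_hi, excludes_zero), `r_squared`, `adj_r_squared`,
#'   `f_statistic`, `df`, `p_value`, `subset`, `n`.
#' @export
fit_ols <- function(records, pca, subset = c("full", "north", "south"),
                    north_species = NULL, south_species = NULL,
                    conf_level = 0.95, standardize_response = TRUE) {
  subset <- match.arg(subset)
  rows <- switch(subset,
    full = seq_len(nrow(records)),
    north = which(records$species %in% north_species),
    south = which(records$species %in% south_species))
  if (subset != "full" && length(rows) == 0L)
    stopf("subset '%s' matches no nodes; check species lists", subset)
  kcols <- seq_len(pca$k)
  df <- data.frame(y = records$mean_inv_weight[rows],
                   species = records$species[rows],
                   x = records$x[rows], y_coord = records$y[rows],
                   n = records$n[rows])
  sc <- pca$scores[rows, kcols, drop = FALSE]
  # response: within-species z over the subset's nodes
  resp <- df$y
  if (standardize_response) {
    for (sp in unique(df$species)) {
      idx <- df$species == sp
      if (sum(idx) < 2L) stopf("species '%s' has < 2 nodes in subset '%s'", sp, subset)
      resp[idx] <- zscore(df$y[idx])
    }
  }
  zsafe <- function(v) { s <- sd(v); if (is.na(s) || s == 0) v - mean(v) else (v - mean(v)) / s }
  X <- cbind(X = zsafe(df$x), Y = zsafe(df$y_coord), n = zsafe(df$n),
             apply(sc, 2, zsafe))
  colnames(X)[-(1:3)] <- colnames(pca$scores)[kcols]
  n_obs <- nrow(X)
  if (n_obs <= ncol(X) + 1L)
    stopf("subset '%s' has %d nodes for %d predictors; too few", subset, n_obs, ncol(X))
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1L) {
    bad <- colnames(cbind(`(Intercept)` = 1, X))[qrX$pivot[-seq_len(qrX$rank)]]
    stopf("rank-deficient design in subset '%s'; collinear column(s): %s",
          subset, paste(bad, collapse = ", "))
  }
  fit <- lm(resp ~ X)
  sm <- summary(fit)
  co <- sm$coefficients
  dfree <- fit$df.residual
  tcrit <- qt(1 - (1 - conf_level) / 2, dfree)
  terms <- c("(Intercept)", colnames(X))
  coefs <- data.frame(term = terms, slope = co[, 1], se = co[, 2],
                      ci_lo = co[, 1] - tcrit * co[, 2],
                      ci_hi = co[, 1] + tcrit * co[, 2],
                      row.names = NULL, stringsAsFactors = FALSE)
  coefs$excludes_zero <- coefs$ci_lo > 0 | coefs$ci_hi < 0
  fstat <- sm$fstatistic
  structure(list(coefficients = coefs,
                 r_squared = sm$r.squared, adj_r_squared = sm$adj.r.squared,
                 f_statistic = unname(fstat[1]),
                 df = unname(fstat[2:3]),
                 p_value = unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)),
                 subset = subset, n = n_obs, fit = fit, design = X,
                 response = resp),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> %s model: n = %d, F = %.2f (df %d, %d), p = %.3g\n",
              x$subset, x$n, x$f_statistic, x$df[1], x$df[2], x$p_value))
  cat(sprintf("  R2 = %.3f, adjusted R2 = %.3f\n", x$r_squared, x$adj_r_squared))
  print(transform(x$coefficients, slope = round(slope, 3), se = round(se, 3),
                  ci_lo = round(ci_lo, 3), ci_hi = round(ci_hi, 3)))
  invisible(x)
}

# which retained PC loads most heavily (summed |loading|) on a covariate group
dominant_pc <- function(pca, pattern) {
  rows <- grepl(pattern, rownames(pca$loadings))
  sums <- colSums(abs(pca$loadings[rows, , drop = FALSE]))
  names(sums)[which.max(sums)]
}

#' Single-replicate synthetic pipeline
#'
#' Generates a landscape and genotypes, runs genetics -> population graph ->
#' omnidirectional current map -> covariates -> PCA -> OLS, and returns the
#' fitted pieces. The workhorse behind [recovery_experiment()].
#'
#' @param habitat_fraction habitat proportion of the simulated landscape.
#' @param seed integer seed for the whole replicate.
#' @param grid_rows,grid_cols landscape size in cells.
#' @param n_sites,n_per_site,n_loci,alleles_per_locus,drift_scale,missing_rate
#'   genotype simulation settings (see [sim_spec()]).
#' @param clustering landscape autocorrelation scale (cells).
#' @param radii_m covariate buffer radii (m).
#' @param n_pairs,buffer_cells omnidirectional map settings.
#' @param alpha population-graph pruning level.
#' @param k_pcs retained principal components.
#' @return list with `records`, `pca`, `fit`, `graph`, `current_map`,
#'   `raster`, `sites`.
#' @export
synthetic_pipeline <- function(habitat_fraction, seed,
                               grid_rows = 40, grid_cols = 40,
                               n_sites = 12, n_per_site = c(12, 30), n_loci = 10,
                               alleles_per_locus = 6, drift_scale = 5e-4,
                               missing_rate = 0.02, clustering = 3,
                               radii_m = c(400, 800, 1600),
                               n_pairs = 32, buffer_cells = 5,
                               alpha = 0.05, k_pcs = 4) {
  lspec <- landscape_spec(grid_rows, grid_cols, habitat_fraction = habitat_fraction,
                          clustering = clustering, seed = seed)
  raster <- generate_landscape(lspec)
  # a length-2 n_per_site is a range: per-site sizes drawn uniformly from it,
  # mirroring the uneven site sizes of field datasets
  if (length(n_per_site) == 2L && n_sites != 2L) {
    n_per_site <- with_seed(seed + 3L,
      sample(seq(n_per_site[1], n_per_site[2]), n_sites, replace = TRUE))
  }
  sspec <- sim_spec(n_sites = n_sites, n_loci = n_loci,
                    alleles_per_locus = alleles_per_locus,
                    n_per_site = n_per_site, drift_scale = drift_scale,
                    missing_rate = missing_rate,
                    min_site_separation_m = 2 * raster$cell_size_m,
                    seed = seed + 1L)
  sites <- place_sites(raster, sspec)
  tab <- simulate_genotypes(raster, sites, sspec)
  tab <- filter_individuals(tab)
  enc <- encode_multivariate(tab)
  mats <- population_covariance(enc)
  meta <- sites[, c("site_id", "x", "y")]
  meta$species <- "sim"
  graph <- saturated_graph(mats, meta = meta)
  graph <- prune_edges(graph, mats$C, alpha = alpha)
  conn <- node_connectivity(graph)
  cmap <- omnidirectional_map(raster, n_pairs = n_pairs,
                              buffer_cells = buffer_cells, seed = seed + 2L)
  recs <- assemble_records(conn, raster, cmap, radii_m = radii_m)
  pca <- run_pca(recs, k = k_pcs)
  fit <- fit_ols(recs, pca, subset = "full")
  list(records = recs, pca = pca, fit = fit, graph = graph,
       current_map = cmap, raster = raster, sites = sites)
}

#' Replicated recovery experiment
#'
#' Simulates landscapes across a grid of habitat fractions, runs the full
#' pipeline per replicate, and summarizes the sign and CI behavior of the
#' current-density-loaded and cost-loaded principal components in low- vs
#' high-habitat strata. With `drift_scale = 0` this doubles as a type-I
#' error check: no predictor should exclude zero much more often than
#' alpha. Replicate-level pipeline failures are recorded, not fatal.
#'
#' @param n_replicates replicates per habitat fraction.
#' @param habitat_fractions habitat proportions to span.
#' @param drift_scale drift coupling (0 for the null experiment).
#' @param seed master seed.
#' @param low_cut habitat fraction at or below which a replicate belongs to
#'   the low-habitat stratum (default 0.35).
#' @param ... forwarded to [synthetic_pipeline()].
#' @return list with `replicates` (one row each: habitat fraction, stratum,
#'   current-PC and cost-PC slopes and CI flags, per-predictor CI flags)
#'   and `summary` (per stratum: n, fraction of negative current-PC slopes,
#'   CI-exclusion rates).
#' @export
recovery_experiment <- function(n_replicates = 10,
                                habitat_fractions = c(0.2, 0.8),
                                drift_scale = 1e-3, seed = 1L,
                                low_cut = 0.35, ...) {
  rows <- list(); fails <- 0L
  for (hf in habitat_fractions) for (r in seq_len(n_replicates)) {
    rep_seed <- seed + 1000L * match(hf, habitat_fractions) + 10L * r
    res <- tryCatch(
      synthetic_pipeline(hf, seed = rep_seed, drift_scale = drift_scale, ...),
      error = function(e) e)
    if (inherits(res, "error")) {
      fails <- fails + 1L
      log_msg("inference", "replicate (hf=%g, r=%d) failed: %s", hf, r,
              conditionMessage(res))
      next
    }
    cur_pc <- dominant_pc(res$pca, "_cur_")
    cost_pc <- dominant_pc(res$pca, "_cost_")
    co <- res$fit$coefficients
    pick <- function(term, f) co[[f]][co$term == term]
    # orient each PC slope by the sign of its mean loading on the relevant
    # covariate group, so "current effect" means d(connectivity)/d(current)
    orient <- function(pc, pattern) {
      ld <- res$pca$loadings[grepl(pattern, rownames(res$pca$loadings)), pc]
      sign(mean(ld))
    }
    excl <- co$excludes_zero[co$term != "(Intercept)"]
    names(excl) <- co$term[co$term != "(Intercept)"]
    rows[[length(rows) + 1L]] <- data.frame(
      habitat_fraction = hf, replicate = r,
      stratum = if (hf <= low_cut) "low" else "high",
      current_pc = cur_pc, cost_pc = cost_pc,
      current_slope = pick(cur_pc, "slope") * orient(cur_pc, "mean_cur_"),
      current_excludes_zero = pick(cur_pc, "excludes_zero"),
      cost_slope = pick(cost_pc, "slope") * orient(cost_pc, "mean_cost_"),
      cost_excludes_zero = pick(cost_pc, "excludes_zero"),
      any_excludes_zero_rate = mean(excl),
      stringsAsFactors = FALSE)
  }
  reps <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(reps, reps$stratum), function(d)
    data.frame(stratum = d$stratum[1], n = nrow(d),
               frac_current_slope_negative = mean(d$current_slope < 0),
               frac_current_ci_excludes_zero = mean(d$current_excludes_zero),
               frac_cost_slope_negative = mean(d$cost_slope < 0),
               mean_predictor_exclusion_rate = mean(d$any_excludes_zero_rate),
               stringsAsFactors = FALSE)))
  rownames(summ) <- NULL
  list(replicates = reps, summary = summ, n_failed = fails)
}
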