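#!/usr/bin/env Rscript
# Inference stage: PCA of the 12 buffered covariates, then OLS of the
# standardized node connectivity on x, y, sample size and the retained PCs,
# for the full node set and the two species subsets.

source("analysis/00_config.R")

recs <- read.csv(file.path(OUT_DIR, "node_records.csv"), stringsAsFactors = FALSE)
cols <- as.vector(outer(c("mean_cost_r", "sd_cost_r", "mean_cur_r", "sd_cur_r"),
                        1:3, paste0))
attr(recs, "covariate_cols") <- cols

pca <- run_pca(recs, k = 4)
write.csv(data.frame(covariate = rownames(pca$all_loadings),
                     round(pca$all_loadings[, 1:4], 3)),
          file.path(OUT_DIR, "pca_loadings.csv"), row.names = FALSE)
write.csv(data.frame(pc = seq_along(pca$variance_explained),
                     proportion = round(pca$variance_explained, 4),
                     cumulative = round(pca$cumulative, 4)),
          file.path(OUT_DIR, "pca_variance.csv"), row.names = FALSE)
cat(sprintf("PCA: first 4 PCs explain %s%% (cumulative %.1f%%)\n",
            paste(round(100 * pca$variance_explained[1:4], 1), collapse = "/"),
            100 * pca$cumulative[4]))

fits <- list(
  full = fit_ols(recs, pca, "full"),
  north = fit_ols(recs, pca, "north", north_species = "north_sp"),
  south = fit_ols(recs, pca, "south", south_species = "south_sp"))
reg <- do.call(rbind, lapply(names(fits), function(nm) {
  f <- fits[[nm]]
  cbind(model = nm, f$coefficients,
        r_squared = round(f$r_squared, 3),
        adj_r_squared = round(f$adj_r_squared, 3))
}))
write.csv(reg, file.path(OUT_DIR, "regression.csv"), row.names = FALSE)
for (nm in names(fits)) {
  f <- fits[[nm]]
  sig <- f$coefficients$term[f$coefficients$excludes_zero &
                             f$coefficients$term != "(Intercept)"]
  cat(sprintf("%s model: n=%d, F=%.2f (df %d,%d), adj R2=%.3f; CI excludes 0: %s\n",
              nm, f$n, f$f_statistic, f$df[1], f$df[2], f$adj_r_squared,
              if (length(sig)) paste(sig, collapse = ", ") else "none"))
}
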