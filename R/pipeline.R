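pipeline_defaults <- function() {
  list(
    genotypes = NULL, sites = NULL, genotype_format = "csv",
    resistance_raster = NULL, landcover = NULL, cost_table = NULL,
    output_dir = "pipeline_out",
    max_missing = 0.35, alpha = 0.05,
    radii_km = c(6, 20, 120), as_diameter = FALSE, inset_m = 300,
    n_pairs = 64, buffer_cells = 8, connectivity = "four",
    k_rule = "fixed", k_pcs = 4,
    north_species = character(0), south_species = character(0),
    neighborhoods = TRUE, seed = 1L
  )
}

#' Validate a pipeline configuration
#'
#' Reads a YAML config (or takes a list), rejects unknown keys, fills
#' defaults (pruning alpha 0.05, buffer radii 6/20/120 km, focal-node inset
#' 300 m), and checks ranges and input paths.
#'
#' @param config path to a YAML file or a named list.
#' @return normalized config list of class `run_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  errs <- character(0)
  if (is.null(cfg$genotypes)) errs <- c(errs, "genotypes path is required")
  else if (!file.exists(cfg$genotypes)) errs <- c(errs, sprintf("genotypes file missing: %s", cfg$genotypes))
  has_res <- !is.null(cfg$resistance_raster); has_lc <- !is.null(cfg$landcover)
  if (has_res && has_lc) errs <- c(errs, "give either resistance_raster or landcover, not both")
  if (!has_res && !has_lc) errs <- c(errs, "one of resistance_raster or landcover is required")
  if (has_res && !file.exists(cfg$resistance_raster))
    errs <- c(errs, sprintf("resistance raster missing: %s", cfg$resistance_raster))
  if (has_lc && !file.exists(cfg$landcover))
    errs <- c(errs, sprintf("landcover raster missing: %s", cfg$landcover))
  if (has_lc && is.null(cfg$cost_table)) errs <- c(errs, "landcover needs a cost_table")
  if (any(cfg$radii_km <= 0)) errs <- c(errs, "radii_km must all be > 0")
  if (cfg$alpha <= 0 || cfg$alpha > 1) errs <- c(errs, "alpha must be in (0, 1]")
  if (cfg$inset_m < 0) errs <- c(errs, "inset_m must be >= 0")
  if (cfg$n_pairs < 1) errs <- c(errs, "n_pairs must be >= 1")
  if (cfg$seed < 0) errs <- c(errs, "seed must be a nonnegative integer")
  if (!cfg$connectivity %in% c("four", "eight")) errs <- c(errs, "connectivity must be 'four' or 'eight'")
  if (length(errs)) stopf("invalid config:\n  - %s", paste(errs, collapse = "\n  - "))
  structure(cfg, class = "run_config")
}

#' Run the full connectivity pipeline
#'
#' Orchestrates genotype reading and filtering, population-graph
#' construction and pruning, conditional genetic distance, the
#' omnidirectional current-density map, buffered covariates, PCA, OLS
#' models (full plus north/south subsets when species lists are given), the
#' circular-neighborhood diagnostic, and a provenance manifest. A stage
#' error aborts with the stage name; artifacts written before the failure
#' are preserved.
#'
#' @param config a [validate_config()] result (or something it accepts).
#' @return (invisibly) the output directory; side effect: artifacts under it.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  out <- cfg$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  counts <- list()

  tab <- stage("genetics", {
    t0 <- read_genotypes(cfg$genotypes, format = cfg$genotype_format,
                         sites_path = cfg$sites)
    filter_individuals(t0, max_missing = cfg$max_missing)
  })
  counts$individuals <- nrow(tab$individuals); counts$sites <- nrow(tab$sites)

  mats <- stage("genetics", population_covariance(encode_multivariate(tab)))

  raster <- stage("raster", {
    if (!is.null(cfg$resistance_raster)) read_ascii_grid(cfg$resistance_raster)
    else classify_landcover(read_ascii_grid(cfg$landcover),
                            unlist(cfg$cost_table))
  })

  graph <- stage("popgraph", {
    meta <- tab$sites
    if (is.null(meta$species)) meta$species <- "all"
    g <- saturated_graph(mats, meta = meta)
    prune_edges(g, mats$C, alpha = cfg$alpha)
  })
  counts$edges_kept <- sum(graph$edges$kept)
  cgd <- stage("popgraph", conditional_genetic_distance(graph))
  conn <- stage("popgraph", node_connectivity(graph))
  write_popgraph_graphml(graph, file.path(out, "popgraph.graphml"))
  write_popgraph_csv(graph, file.path(out, "popgraph"))
  write.csv(data.frame(site_id = cgd$site_order, cgd$cgd),
            file.path(out, "cgd_matrix.csv"), row.names = FALSE)

  cmap <- stage("circuit", omnidirectional_map(
    raster, n_pairs = cfg$n_pairs, buffer_cells = cfg$buffer_cells,
    seed = cfg$seed))
  write_ascii_grid(cmap, file.path(out, "current_density.asc"))

  radii_m <- cfg$radii_km * 1000 / if (isTRUE(cfg$as_diameter)) 2 else 1
  recs <- stage("covariates", assemble_records(conn, raster, cmap,
                                               radii_m = radii_m))
  write.csv(recs, file.path(out, "node_records.csv"), row.names = FALSE)
  write.csv(attr(recs, "covariate_correlation"),
            file.path(out, "covariate_correlation.csv"))

  pca <- stage("inference", run_pca(recs, k_rule = cfg$k_rule, k = cfg$k_pcs))
  write.csv(data.frame(covariate = rownames(pca$loadings),
                       round(pca$loadings, 4)),
            file.path(out, "pca_loadings.csv"), row.names = FALSE)
  write.csv(data.frame(pc = seq_along(pca$variance_explained),
                       proportion = pca$variance_explained,
                       cumulative = pca$cumulative),
            file.path(out, "pca_variance.csv"), row.names = FALSE)

  fits <- list(full = stage("inference", fit_ols(recs, pca, "full")))
  if (length(cfg$north_species) && any(recs$species %in% cfg$north_species))
    fits$north <- stage("inference", fit_ols(recs, pca, "north",
                                             north_species = cfg$north_species))
  if (length(cfg$south_species) && any(recs$species %in% cfg$south_species))
    fits$south <- stage("inference", fit_ols(recs, pca, "south",
                                             south_species = cfg$south_species))
  reg <- do.call(rbind, lapply(names(fits), function(nm)
    cbind(model = nm, fits[[nm]]$coefficients,
          r_squared = fits[[nm]]$r_squared,
          adj_r_squared = fits[[nm]]$adj_r_squared)))
  write.csv(reg, file.path(out, "regression.csv"), row.names = FALSE)

  if (isTRUE(cfg$neighborhoods)) {
    nb <- stage("circuit", {
      do.call(rbind, lapply(seq_len(nrow(recs)), function(i)
        do.call(rbind, lapply(radii_m, function(r) {
          res <- neighborhood_analysis(raster,
                                       c(x = recs$x[i], y = recs$y[i]),
                                       radius_m = r, inset_m = cfg$inset_m,
                                       seed = cfg$seed + i)
          data.frame(site_id = recs$site_id[i], radius_m = r,
                     mean_effective_resistance = res$mean_effective_resistance,
                     mean_current_density = res$mean_current_density,
                     n_cells = res$n_cells)
        }))))
    })
    write.csv(nb, file.path(out, "neighborhoods.csv"), row.names = FALSE)
  }

  manifest <- list(
    config = unclass(cfg), seed = cfg$seed,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("landconnect")),
    counts = counts,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_msg("pipeline", "run complete; artifacts in %s", out)
  invisible(out)
}
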