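#' Buffered zonal statistics
#'
#' Mean and population standard deviation of a surface over the non-NoData
#' cells whose centers lie within `radius_m` of a point. Buffers truncated
#' by the raster edge are flagged.
#'
#' @param raster a [resistance_raster()] or [omnidirectional_map()] output.
#' @param center `c(x = , y = )` projected coordinates (m).
#' @param radius_m buffer radius (m), > 0.
#' @return list `mean`, `sd` (population), `n_cells`, `truncated`.
#' @export
buffer_stats <- function(raster, center, radius_m) {
  if (radius_m <= 0) stopf("radius_m must be > 0")
  v <- raster$values
  nr <- nrow(v); nc <- ncol(v); cs <- raster$cell_size_m
  cx <- center[["x"]]; cy <- center[["y"]]
  if (cx < raster$xll || cx > raster$xll + nc * cs ||
      cy < raster$yll || cy > raster$yll + nr * cs)
    stopf("center (%g, %g) outside raster extent", cx, cy)
  # candidate window, then exact center-in-circle test
  rc0 <- nearest_cell(raster, cx, cy)
  span <- ceiling(radius_m / cs) + 1L
  rows <- max(1L, rc0[1, 1] - span):min(nr, rc0[1, 1] + span)
  cols <- max(1L, rc0[1, 2] - span):min(nc, rc0[1, 2] + span)
  grid <- as.matrix(expand.grid(row = rows, col = cols))
  xy <- cell_center(raster, grid[, 1], grid[, 2])
  inside <- (xy[, 1] - cx)^2 + (xy[, 2] - cy)^2 <= radius_m^2
  vals <- v[grid[inside, , drop = FALSE]]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) stopf("no eligible cells within %g m of (%g, %g)",
                                radius_m, cx, cy)
  truncated <- cx - radius_m < raster$xll || cx + radius_m > raster$xll + nc * cs ||
    cy - radius_m < raster$yll || cy + radius_m > raster$yll + nr * cs
  list(mean = mean(vals), sd = pop_sd(vals), n_cells = length(vals),
       truncated = truncated)
}

#' Assemble the node covariate table
#'
#' One record per genetic node: the connectivity response plus mean and SD
#' of cost and of current density in buffers at each radius (12 landscape
#' covariates with three radii), with z-scored copies computed over the
#' assembled node set. The covariate correlation matrix is attached as the
#' `covariate_correlation` attribute.
#'
#' @param connectivity a [node_connectivity()] data frame.
#' @param cost_raster the resistance surface.
#' @param current_map an [omnidirectional_map()] output.
#' @param radii_m buffer radii in meters (default `c(6, 20, 120) * 1000`).
#' @param drop_isolated drop nodes with undefined connectivity (default TRUE).
#' @return data frame of node records; covariate columns are named
#'   `mean_cost_r<k>`, `sd_cost_r<k>`, `mean_cur_r<k>`, `sd_cur_r<k>` with
#'   z-scored copies prefixed `z_`.
#' @export
assemble_records <- function(connectivity, cost_raster, current_map,
                             radii_m = c(6, 20, 120) * 1000,
                             drop_isolated = TRUE) {
  if (any(radii_m <= 0)) stopf("radii must be > 0")
  recs <- connectivity
  if (drop_isolated && any(is.na(recs$mean_inv_weight))) {
    log_msg("covariates", "dropping %d isolated node(s) from the record table",
            sum(is.na(recs$mean_inv_weight)))
    recs <- recs[!is.na(recs$mean_inv_weight), , drop = FALSE]
  }
  cov_cols <- character(0)
  for (k in seq_along(radii_m)) {
    r <- radii_m[k]
    cost_stats <- lapply(seq_len(nrow(recs)), function(i)
      buffer_stats(cost_raster, c(x = recs$x[i], y = recs$y[i]), r))
    cur_stats <- lapply(seq_len(nrow(recs)), function(i)
      buffer_stats(current_map, c(x = recs$x[i], y = recs$y[i]), r))
    nm <- sprintf(c("mean_cost_r%d", "sd_cost_r%d", "mean_cur_r%d", "sd_cur_r%d"), k)
    recs[[nm[1]]] <- vapply(cost_stats, `[[`, 0, "mean")
    recs[[nm[2]]] <- vapply(cost_stats, `[[`, 0, "sd")
    recs[[nm[3]]] <- vapply(cur_stats, `[[`, 0, "mean")
    recs[[nm[4]]] <- vapply(cur_stats, `[[`, 0, "sd")
    cov_cols <- c(cov_cols, nm)
  }
  for (nm in cov_cols) {
    z <- recs[[nm]] - mean(recs[[nm]])
    s <- sd(recs[[nm]])
    recs[[paste0("z_", nm)]] <- if (is.na(s) || s == 0) z else z / s
  }
  attr(recs, "covariate_cols") <- cov_cols
  attr(recs, "radii_m") <- radii_m
  attr(recs, "covariate_correlation") <- cor(as.matrix(recs[, cov_cols]))
  recs
}
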