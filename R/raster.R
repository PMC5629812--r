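#' Resistance raster
#'
#' A georeferenced grid of per-cell movement costs, the substrate for the
#' circuit model. Stored as a numeric matrix whose first row is the
#' northernmost (top) row, with the ESRI convention of a lower-left corner
#' anchor. `NA` cells are NoData and carry no circuit node.
#'
#' @param values numeric matrix of per-cell costs (> 0) or `NA` for NoData;
#'   row 1 is the top (maximum y) row.
#' @param cell_size_m cell edge length in meters (default 100, the working
#'   resolution of the cost surfaces this package targets).
#' @param xll,yll projected coordinates (m) of the grid's lower-left corner.
#' @param crs free-form CRS tag carried through I/O (not interpreted).
#' @param check_positive require all cells > 0 (TRUE for cost surfaces;
#'   derived surfaces such as mean-zero current maps set FALSE).
#' @return an object of class `resistance_raster`.
#' @export
resistance_raster <- function(values, cell_size_m = 100, xll = 0, yll = 0,
                              crs = "", check_positive = TRUE) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (cell_size_m <= 0) stopf("cell_size_m must be > 0")
  if (check_positive && any(values[!is.na(values)] <= 0))
    stopf("raster costs must be > 0")
  structure(
    list(values = values, cell_size_m = cell_size_m, xll = xll, yll = yll,
         crs = crs),
    class = "resistance_raster"
  )
}

#' @export
print.resistance_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<resistance_raster> %d x %d cells @ %g m, %d NoData\n",
              nrow(v), ncol(v), x$cell_size_m, sum(is.na(v))))
  cat(sprintf("  origin (xll, yll) = (%g, %g); cost range [%g, %g]\n",
              x$xll, x$yll, min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
  invisible(x)
}

#' @export
dim.resistance_raster <- function(x) dim(x$values)

#' Cell-center coordinates
#'
#' Projected coordinates of cell centers for (row, col) indices, or the
#' (row, col) of the cell whose center is nearest a projected point.
#'
#' @param raster a [resistance_raster()].
#' @param row,col cell indices (row 1 = top).
#' @return `cell_center`: two-column matrix of x, y (m).
#' @export
cell_center <- function(raster, row, col) {
  nr <- nrow(raster$values)
  cs <- raster$cell_size_m
  cbind(x = raster$xll + (col - 0.5) * cs,
        y = raster$yll + (nr - row + 0.5) * cs)
}

#' @rdname cell_center
#' @param x,y projected coordinates (m).
#' @export
nearest_cell <- function(raster, x, y) {
  nr <- nrow(raster$values)
  nc <- ncol(raster$values)
  cs <- raster$cell_size_m
  col <- pmin(pmax(ceiling((x - raster$xll) / cs), 1L), nc)
  row <- pmin(pmax(nr - ceiling((y - raster$yll) / cs) + 1L, 1L), nr)
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Read / write ESRI ASCII grids
#'
#' Plain-text raster exchange format (Circuitscape-compatible). NoData cells
#' are honored. `cellsize` maps to `cell_size_m`; an optional sidecar `.prj`
#' is neither read nor written — use the `crs` field for bookkeeping.
#'
#' @param path file path.
#' @return `read_ascii_grid`: a [resistance_raster()].
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+-?[0-9.eE+-]+\\s*$", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  miss <- setdiff(need, names(hdr))
  if (length(miss)) stopf("ASCII grid header missing: %s", paste(miss, collapse = ", "))
  nodata <- hdr[["nodata_value"]] %||% -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stopf("ASCII grid body has %d values, expected %d", length(vals),
          hdr$ncols * hdr$nrows)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA
  resistance_raster(m, cell_size_m = hdr$cellsize, xll = hdr$xllcorner,
                    yll = hdr$yllcorner, check_positive = FALSE)
}

#' @rdname read_ascii_grid
#' @param raster a [resistance_raster()] (or any object with the same fields,
#'   e.g. a current-density map).
#' @param nodata_value numeric code written for `NA` cells.
#' @export
write_ascii_grid <- function(raster, path, nodata_value = -9999) {
  v <- raster$values
  v[is.na(v)] <- nodata_value
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", raster$xll),
    sprintf("yllcorner %.10g", raster$yll),
    sprintf("cellsize %.10g", raster$cell_size_m),
    sprintf("NODATA_value %.10g", nodata_value)
  )
  body <- apply(v, 1L, function(r) paste(format(r, trim = TRUE, digits = 15),
                                         collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Reclassify a categorical land-cover raster to costs
#'
#' Maps land-cover classes to movement costs via a lookup table, e.g. the
#' three-class scheme where 10 is low-cost natural cover, 100 semi-permeable
#' cover, and 1000 high-cost (mostly anthropogenic) cover.
#'
#' @param landcover a [resistance_raster()]-shaped object whose cell values
#'   are integer class codes, or a character matrix of class names wrapped in
#'   the same structure.
#' @param cost_table named numeric vector mapping class (as character) to cost.
#' @param default cost for unmapped classes; if `NULL`, unmapped classes are
#'   an error.
#' @return a [resistance_raster()] of costs.
#' @export
classify_landcover <- function(landcover, cost_table, default = NULL) {
  cls <- as.character(landcover$values)
  known <- cls %in% names(cost_table) | is.na(landcover$values)
  if (any(!known) && is.null(default)) {
    stopf("unmapped land-cover classes: %s",
          paste(sort(unique(cls[!known])), collapse = ", "))
  }
  cost <- rep(NA_real_, length(cls))
  hit <- cls %in% names(cost_table)
  cost[hit] <- unname(cost_table[cls[hit]])
  cost[!hit & !is.na(landcover$values)] <- default %||% NA_real_
  m <- matrix(cost, nrow = nrow(landcover$values))
  resistance_raster(m, cell_size_m = landcover$cell_size_m,
                    xll = landcover$xll, yll = landcover$yll,
                    crs = landcover$crs %||% "")
}
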