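#' Build a lattice circuit from a resistance raster
#'
#' Converts the raster to an electrical network: every non-NoData cell is a
#' node, adjacent cells are joined by a resistor whose resistance is the
#' arithmetic mean of the two cell costs (diagonal edges, when 8-neighbor
#' connectivity is enabled, are scaled by sqrt(2) for the longer span).
#' The graph Laplacian is assembled in sparse form; connected components are
#' labeled so that solves can be restricted to the component holding the
#' terminals.
#'
#' @param raster a [resistance_raster()].
#' @param connectivity `"four"` (default) or `"eight"`.
#' @param max_cells guard against accidental huge solves; rasters with more
#'   cells than this are rejected.
#' @return an object of class `lattice_circuit` with fields `nodes` (two
#'   column row/col matrix, one row per node), `node_of` (matrix mapping
#'   cells to node ids), `edges` (data frame `from`, `to`, `conductance`),
#'   `laplacian` (sparse dgCMatrix), `component` (integer label per node),
#'   and `raster`.
#' @export
build_circuit <- function(raster, connectivity = c("four", "eight"),
                          max_cells = 4e6) {
  connectivity <- match.arg(connectivity)
  v <- raster$values
  if (length(v) > max_cells)
    stopf("raster has %d cells, above the max_cells guard (%g)", length(v), max_cells)
  if (any(v[!is.na(v)] <= 0)) stopf("circuit costs must be > 0")
  ok <- !is.na(v)
  n_nodes <- sum(ok)
  if (n_nodes < 2L) stopf("need at least 2 non-NoData cells to build a circuit")
  node_of <- matrix(NA_integer_, nrow(v), ncol(v))
  node_of[ok] <- seq_len(n_nodes)
  cells <- which(ok, arr.ind = TRUE)
  colnames(cells) <- c("row", "col")

  nr <- nrow(v); nc <- ncol(v)
  offs <- list(c(0L, 1L), c(1L, 0L))
  scale <- c(1, 1)
  if (connectivity == "eight") {
    offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
    scale <- c(scale, sqrt(2), sqrt(2))
  }
  from <- integer(0); to <- integer(0); cond <- numeric(0)
  for (k in seq_along(offs)) {
    dr <- offs[[k]][1]; dc <- offs[[k]][2]
    r1 <- seq_len(nr - dr)
    c1 <- if (dc >= 0) seq_len(nc - dc) else seq.int(1L - dc, nc)
    a <- as.matrix(expand.grid(row = r1, col = c1))
    b <- cbind(a[, 1] + dr, a[, 2] + dc)
    ia <- node_of[a]; ib <- node_of[b]
    keep <- !is.na(ia) & !is.na(ib)
    if (!any(keep)) next
    res <- (v[a[keep, , drop = FALSE]] + v[b[keep, , drop = FALSE]]) / 2 * scale[k]
    from <- c(from, ia[keep]); to <- c(to, ib[keep]); cond <- c(cond, 1 / res)
  }
  if (length(from) == 0L) stopf("no adjacent non-NoData cells: circuit has no edges")

  A <- Matrix::sparseMatrix(i = c(from, to), j = c(to, from),
                            x = c(cond, cond), dims = c(n_nodes, n_nodes))
  L <- Matrix::Diagonal(x = Matrix::rowSums(A)) - A
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  if (igraph::vcount(g) < n_nodes) g <- igraph::add_vertices(g, n_nodes - igraph::vcount(g))
  comp <- igraph::components(g)$membership

  structure(
    list(nodes = cells, node_of = node_of,
         edges = data.frame(from = from, to = to, conductance = cond),
         laplacian = methods::as(L, "CsparseMatrix"),
         component = comp, raster = raster),
    class = "lattice_circuit"
  )
}

#' @export
print.lattice_circuit <- function(x, ...) {
  cat(sprintf("<lattice_circuit> %d nodes, %d edges, %d component(s)\n",
              nrow(x$nodes), nrow(x$edges), max(x$component)))
  invisible(x)
}

# Resolve a terminal given as node id, (row, col) pair, or c(x = , y = ).
resolve_node <- function(circuit, cell) {
  if (length(cell) == 1L) {
    id <- as.integer(cell)
    if (is.na(id) || id < 1L || id > nrow(circuit$nodes)) stopf("bad node id %s", cell)
    return(id)
  }
  if (!is.null(names(cell)) && all(c("x", "y") %in% names(cell))) {
    rc <- nearest_cell(circuit$raster, cell[["x"]], cell[["y"]])
    cell <- rc[1, ]
  }
  id <- circuit$node_of[cell[[1]], cell[[2]]]
  if (is.na(id)) stopf("cell (%d, %d) is NoData; no circuit node", cell[[1]], cell[[2]])
  id
}

#' Reusable solver for one circuit component
#'
#' Grounds the Laplacian at a reference node of the requested component and
#' computes its sparse Cholesky factorization once; the factor is reused for
#' every source/ground pair in that component (as in omnidirectional mapping,
#' where dozens of pairs share one landscape).
#'
#' @param circuit a [build_circuit()] result.
#' @param component component label to solve in (default: largest).
#' @return a `circuit_solver` object.
#' @export
circuit_solver <- function(circuit, component = NULL) {
  comp <- circuit$component
  if (is.null(component)) component <- as.integer(names(which.max(table(comp))))
  in_comp <- which(comp == component)
  if (length(in_comp) < 2L) stopf("component %d has fewer than 2 nodes", component)
  ref <- in_comp[1L]
  keep <- setdiff(in_comp, ref)
  Lg <- circuit$laplacian[keep, keep, drop = FALSE]
  fac <- Matrix::Cholesky(Lg, LDL = FALSE, perm = TRUE)
  structure(list(circuit = circuit, component = component, ref = ref,
                 keep = keep, pos = match(seq_len(nrow(circuit$nodes)), keep),
                 factor = fac, Lg = Lg),
            class = "circuit_solver")
}

# Voltages for unit current injected at `source`, extracted at `ground`,
# referenced so v[ground] = 0. NA outside the solver's component.
pair_voltages <- function(solver, source, ground, current = 1) {
  circuit <- solver$circuit
  s <- resolve_node(circuit, source)
  g <- resolve_node(circuit, ground)
  if (s == g) stopf("source and ground are the same node")
  if (circuit$component[s] != solver$component ||
      circuit$component[g] != solver$component)
    stopf("terminals not both in solver component %d", solver$component)
  b <- numeric(length(solver$keep))
  ps <- solver$pos[s]; pg <- solver$pos[g]
  if (!is.na(ps)) b[ps] <- current
  if (!is.na(pg)) b[pg] <- b[pg] - current
  x <- as.numeric(Matrix::solve(solver$factor, b, system = "A"))
  # relative residual check on the reduced system
  if (sum(b^2) > 0) {
    res <- sqrt(sum((as.numeric(solver$Lg %*% x) - b)^2) / sum(b^2))
    if (res > 1e-8) stopf("solver residual %.3g exceeds 1e-8", res)
  }
  v <- rep(NA_real_, nrow(circuit$nodes))
  v[solver$keep] <- x
  v[solver$ref] <- 0
  v - v[g]
}

#' Solve a source/ground pair
#'
#' Fixes the ground node at 0 V, injects `current` amperes at the source,
#' and solves the grounded Laplacian system.
#'
#' @param circuit a [build_circuit()] result.
#' @param source,ground terminals as node id, `c(row, col)`, or `c(x=, y=)`.
#' @param current injected current (A), default 1.
#' @return numeric voltage per node (`NA` outside the terminals' component).
#' @export
solve_pair <- function(circuit, source, ground, current = 1) {
  s <- resolve_node(circuit, source)
  g <- resolve_node(circuit, ground)
  if (s == g) stopf("source and ground are the same node")
  if (circuit$component[s] != circuit$component[g])
    stopf("terminals are in different components; no current path")
  solver <- circuit_solver(circuit, component = circuit$component[s])
  pair_voltages(solver, s, g, current = current)
}

#' Effective resistance between two terminals
#'
#' The voltage difference per injected ampere, `(v_s - v_g) / I`; a pairwise
#' isolation measure in ohms. Symmetric in terminal exchange.
#'
#' @inheritParams solve_pair
#' @param solver optional [circuit_solver()] to reuse across pairs.
#' @return effective resistance (ohms).
#' @export
effective_resistance <- function(circuit, source, ground, solver = NULL) {
  s <- resolve_node(circuit, source)
  g <- resolve_node(circuit, ground)
  v <- if (is.null(solver)) solve_pair(circuit, s, g) else pair_voltages(solver, s, g)
  v[s] - v[g]
}

#' Per-cell current density from a voltage solution
#'
#' Edge current is conductance times the voltage difference; a cell's
#' current density is half the sum of absolute currents on its incident
#' edges (terminal cells included), the standard raster-circuit convention.
#'
#' @param circuit a [build_circuit()] result.
#' @param voltages node voltages from [solve_pair()].
#' @return numeric density per node (`NA` where voltages are `NA`).
#' @export
cell_current_density <- function(circuit, voltages) {
  e <- circuit$edges
  dv <- voltages[e$from] - voltages[e$to]
  I <- abs(e$conductance * dv)
  dens <- rep(0, nrow(circuit$nodes))
  ok <- !is.na(I)
  dens <- dens + tapply_sum(e$from[ok], I[ok], nrow(circuit$nodes)) +
    tapply_sum(e$to[ok], I[ok], nrow(circuit$nodes))
  dens <- dens / 2
  dens[is.na(voltages)] <- NA_real_
  dens
}

tapply_sum <- function(idx, val, n) {
  out <- numeric(n)
  agg <- rowsum(val, group = idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

# Net (signed) current at each node; ~0 everywhere except terminals.
node_net_current <- function(circuit, voltages) {
  e <- circuit$edges
  I <- e$conductance * (voltages[e$from] - voltages[e$to])
  ok <- !is.na(I)
  tapply_sum(e$from[ok], I[ok], nrow(circuit$nodes)) -
    tapply_sum(e$to[ok], I[ok], nrow(circuit$nodes))
}

#' Omnidirectional current-density map
#'
#' Pads the raster with a uniform-cost buffer, draws random source/ground
#' pairs on the outer perimeter ring of the padded grid (pair members forced
#' at least `min_pair_angle` degrees apart around the perimeter), solves each
#' pair, averages the per-cell current densities, clips the buffer, and
#' standardizes the study-area densities to mean zero. Perimeter placement
#' keeps terminal build-up ("node placement bias") outside the study area;
#' averaging many random pairs makes the map direction-free.
#'
#' @param raster a [resistance_raster()].
#' @param n_pairs number of random perimeter pairs (default 64).
#' @param buffer_cells width of the uniform pad, in cells.
#' @param buffer_cost pad cost; default the mean non-NoData study-area cost
#'   (a neutral medium).
#' @param seed integer seed controlling pair placement.
#' @param min_pair_angle minimum angular separation (degrees) of a pair's
#'   terminals around the perimeter.
#' @param standardize subtract the study-area mean (default TRUE); the raw
#'   mean is kept in the `raw_mean` field either way.
#' @return a `current_density_map`: raster-shaped object with fields
#'   `values` (standardized densities, NoData where the input was NoData),
#'   `n_pairs`, `buffer_cells`, `buffer_cost`, `raw_mean`, `pairs`.
#' @export
omnidirectional_map <- function(raster, n_pairs = 64, buffer_cells = 8,
                                buffer_cost = NULL, seed = NULL,
                                min_pair_angle = 90, standardize = TRUE) {
  if (n_pairs < 1L) stopf("n_pairs must be >= 1")
  if (buffer_cells < 1L) stopf("buffer_cells must be >= 1")
  v <- raster$values
  if (is.null(buffer_cost)) buffer_cost <- mean(v, na.rm = TRUE)
  nr <- nrow(v); nc <- ncol(v); b <- as.integer(buffer_cells)
  padded <- matrix(buffer_cost, nr + 2L * b, nc + 2L * b)
  padded[(b + 1L):(b + nr), (b + 1L):(b + nc)] <- v
  pad_raster <- resistance_raster(padded, cell_size_m = raster$cell_size_m,
                                  xll = raster$xll - b * raster$cell_size_m,
                                  yll = raster$yll - b * raster$cell_size_m,
                                  crs = raster$crs %||% "")
  circuit <- build_circuit(pad_raster)
  solver <- circuit_solver(circuit)

  # perimeter ring of the padded grid, parameterized by angle about the center
  NR <- nrow(padded); NC <- ncol(padded)
  ring <- rbind(cbind(1L, seq_len(NC)), cbind(NR, seq_len(NC)),
                cbind(seq.int(2L, NR - 1L), 1L), cbind(seq.int(2L, NR - 1L), NC))
  ctr <- c((NR + 1) / 2, (NC + 1) / 2)
  ang <- atan2(ring[, 1] - ctr[1], ring[, 2] - ctr[2])
  if (2L * n_pairs > nrow(ring))
    stopf("perimeter has %d cells; too small for %d pairs", nrow(ring), n_pairs)

  pairs <- with_seed(seed, {
    avail <- seq_len(nrow(ring))
    out <- matrix(NA_integer_, n_pairs, 2)
    for (p in seq_len(n_pairs)) {
      src <- sample(avail, 1L)
      avail <- setdiff(avail, src)
      dang <- abs(ang[avail] - ang[src])
      dang <- pmin(dang, 2 * pi - dang)
      far <- avail[dang >= min_pair_angle * pi / 180]
      if (length(far) == 0L)
        stopf("cannot place pair %d with %g degree separation", p, min_pair_angle)
      gnd <- if (length(far) == 1L) far else sample(far, 1L)
      avail <- setdiff(avail, gnd)
      out[p, ] <- c(src, gnd)
    }
    out
  })

  acc <- numeric(nrow(circuit$nodes))
  for (p in seq_len(n_pairs)) {
    s <- circuit$node_of[ring[pairs[p, 1], 1], ring[pairs[p, 1], 2]]
    g <- circuit$node_of[ring[pairs[p, 2], 1], ring[pairs[p, 2], 2]]
    volt <- pair_voltages(solver, s, g)
    acc <- acc + cell_current_density(circuit, volt)
  }
  acc <- acc / n_pairs

  dens_pad <- matrix(NA_real_, NR, NC)
  dens_pad[circuit$nodes] <- acc
  dens <- dens_pad[(b + 1L):(b + nr), (b + 1L):(b + nc), drop = FALSE]
  dens[is.na(v)] <- NA_real_
  raw_mean <- mean(dens, na.rm = TRUE)
  if (standardize) dens <- dens - raw_mean

  structure(
    list(values = dens, cell_size_m = raster$cell_size_m, xll = raster$xll,
         yll = raster$yll, crs = raster$crs %||% "",
         n_pairs = n_pairs, buffer_cells = b, buffer_cost = buffer_cost,
         raw_mean = raw_mean,
         pairs = data.frame(src_row = ring[pairs[, 1], 1], src_col = ring[pairs[, 1], 2],
                            gnd_row = ring[pairs[, 2], 1], gnd_col = ring[pairs[, 2], 2])),
    class = c("current_density_map", "resistance_raster")
  )
}

#' @export
print.current_density_map <- function(x, ...) {
  cat(sprintf("<current_density_map> %d x %d cells @ %g m, %d pairs, study-area mean %.3g\n",
              nrow(x$values), ncol(x$values), x$cell_size_m, x$n_pairs,
              mean(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Circular-neighborhood current vs. effective-resistance diagnostic
#'
#' Clips a circular window of the given radius around a site, places 5 focal
#' nodes equidistant (72 degrees apart) on the circle inset `inset_m` from
#' the boundary, computes effective resistance for the 5 next-nearest pairs
#' (i with i+2 mod 5), and the mean current density over the window from the
#' same 5 pairwise solves (or from a precomputed omnidirectional map).
#'
#' @param raster a [resistance_raster()].
#' @param site `c(x = , y = )` projected site coordinates (m).
#' @param radius_m neighborhood radius (m).
#' @param inset_m focal-node inset from the circular boundary (default 300).
#' @param seed seed for the focal-ring starting angle.
#' @param n_focal number of focal nodes (default 5).
#' @param current_map optional [omnidirectional_map()] output; if supplied,
#'   mean current density is sampled from it over the window instead of
#'   accumulated from the 5 pairwise runs.
#' @return list with `mean_effective_resistance`, `mean_current_density`,
#'   `pair_resistances`, `focal_cells`, `radius_m`, `start_angle`, `n_cells`,
#'   `clipped`.
#' @export
neighborhood_analysis <- function(raster, site, radius_m, inset_m = 300,
                                  seed = NULL, n_focal = 5L,
                                  current_map = NULL) {
  if (radius_m <= 0) stopf("radius_m must be > 0")
  if (inset_m < 0 || inset_m >= radius_m) stopf("inset_m must be in [0, radius_m)")
  v <- raster$values
  nr <- nrow(v); nc <- ncol(v)
  rc <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  xy <- cell_center(raster, rc$row, rc$col)
  d2 <- (xy[, 1] - site[["x"]])^2 + (xy[, 2] - site[["y"]])^2
  inside <- d2 <= radius_m^2
  clipped <- site[["x"]] - radius_m < raster$xll ||
    site[["y"]] - radius_m < raster$yll ||
    site[["x"]] + radius_m > raster$xll + nc * raster$cell_size_m ||
    site[["y"]] + radius_m > raster$yll + nr * raster$cell_size_m
  if (clipped) warnf("neighborhood of radius %g m extends beyond the raster; clipped", radius_m)
  mask <- matrix(NA_real_, nr, nc)
  keep <- inside & !is.na(v[cbind(rc$row, rc$col)])
  mask[cbind(rc$row[keep], rc$col[keep])] <- v[cbind(rc$row[keep], rc$col[keep])]
  if (sum(keep) < 2L) stopf("neighborhood contains fewer than 2 valid cells")
  sub <- resistance_raster(mask, cell_size_m = raster$cell_size_m,
                           xll = raster$xll, yll = raster$yll,
                           crs = raster$crs %||% "")
  circuit <- build_circuit(sub)
  solver <- circuit_solver(circuit)

  start_angle <- with_seed(seed, runif(1, 0, 2 * pi))
  angles <- start_angle + (seq_len(n_focal) - 1L) * 2 * pi / n_focal
  fx <- site[["x"]] + (radius_m - inset_m) * cos(angles)
  fy <- site[["y"]] + (radius_m - inset_m) * sin(angles)
  focal <- matrix(NA_integer_, n_focal, 2)
  comp_nodes <- which(circuit$component == solver$component)
  comp_xy <- cell_center(sub, circuit$nodes[comp_nodes, 1], circuit$nodes[comp_nodes, 2])
  for (k in seq_len(n_focal)) {
    rck <- nearest_cell(sub, fx[k], fy[k])
    id <- circuit$node_of[rck[1, 1], rck[1, 2]]
    if (is.na(id) || circuit$component[id] != solver$component) {
      # nudge to the nearest valid cell of the solvable component
      dd <- (comp_xy[, 1] - fx[k])^2 + (comp_xy[, 2] - fy[k])^2
      id <- comp_nodes[which.min(dd)]
      log_msg("circuit", "focal node %d nudged to nearest valid cell", k)
    }
    focal[k, ] <- circuit$nodes[id, ]
  }
  focal_ids <- circuit$node_of[focal]
  pairs <- cbind(seq_len(n_focal), (seq_len(n_focal) + 1L) %% n_focal + 1L)

  reff <- numeric(nrow(pairs))
  acc <- numeric(nrow(circuit$nodes))
  for (p in seq_len(nrow(pairs))) {
    s <- focal_ids[pairs[p, 1]]; g <- focal_ids[pairs[p, 2]]
    if (s == g) stopf("focal nodes %d and %d collapsed to the same cell; radius too small",
                      pairs[p, 1], pairs[p, 2])
    volt <- pair_voltages(solver, s, g)
    reff[p] <- volt[s] - volt[g]
    acc <- acc + cell_current_density(circuit, volt)
  }
  acc <- acc / nrow(pairs)

  mean_current <- if (is.null(current_map)) {
    mean(acc, na.rm = TRUE)
  } else {
    cm <- current_map$values
    mean(cm[!is.na(mask)], na.rm = TRUE)
  }

  list(mean_effective_resistance = mean(reff),
       mean_current_density = mean_current,
       pair_resistances = reff,
       focal_cells = focal,
       radius_m = radius_m, start_angle = start_angle,
       n_cells = sum(keep), clipped = clipped)
}
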