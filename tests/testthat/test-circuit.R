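test_that("lattice construction: edge counts and resistances", {
  # 1x2: one edge with the mean of the two cell costs
  c1 <- build_circuit(rast(matrix(c(10, 10), 1, 2)))
  expect_equal(nrow(c1$edges), 1L)
  expect_equal(1 / c1$edges$conductance, 10)
  c2 <- build_circuit(rast(matrix(c(10, 1000), 1, 2)))
  expect_equal(1 / c2$edges$conductance, 505)
  # 3x3 four-neighbor lattice: 12 edges
  c3 <- build_circuit(rast(matrix(10, 3, 3)))
  expect_equal(nrow(c3$edges), 12L)
  # eight-neighbor adds sqrt(2)-scaled diagonals
  c8 <- build_circuit(rast(matrix(10, 3, 3)), connectivity = "eight")
  expect_equal(nrow(c8$edges), 20L)
  diag_edges <- c8$edges$conductance[13:20]
  expect_equal(unique(round(1 / diag_edges, 9)), round(10 * sqrt(2), 9))
  # NoData cells carry no node
  cn <- build_circuit(rast(matrix(c(10, NA, 10, 10), 2, 2)))
  expect_equal(nrow(cn$nodes), 3L)
  expect_error(build_circuit(rast(matrix(c(10, NA), 1, 2))), "2 non-NoData")
})

test_that("series circuit voltages and effective resistance are exact", {
  ck <- build_circuit(rast(matrix(10, 1, 3)))
  v <- solve_pair(ck, c(1, 1), c(1, 3))
  expect_equal(v, c(20, 10, 0))
  expect_equal(effective_resistance(ck, c(1, 1), c(1, 3)), 20)
  # terminal swap reflects the solution
  v2 <- solve_pair(ck, c(1, 3), c(1, 1))
  expect_equal(v2, max(v) - v)
  # symmetry of effective resistance
  expect_equal(effective_resistance(ck, c(1, 3), c(1, 1)), 20)
})

test_that("sparse solves match the dense pseudoinverse oracle", {
  for (seed in 1:4) {
    m <- withr::with_seed(seed, matrix(sample(c(10, 100, 1000), 36, TRUE), 6, 6))
    ck <- build_circuit(rast(m))
    s <- 2L; g <- 31L
    v <- solve_pair(ck, s, g)
    expect_equal(v, oracle_voltages(ck, s, g), tolerance = 1e-8)
    expect_equal(effective_resistance(ck, s, g), oracle_reff(ck, s, g),
                 tolerance = 1e-8)
  }
  # parallel paths on a 2x2 ring: dense oracle agreement
  ring <- build_circuit(rast(matrix(10, 2, 2)))
  expect_equal(effective_resistance(ring, 1L, 4L), oracle_reff(ring, 1L, 4L),
               tolerance = 1e-10)
})

test_that("effective resistance is a metric and Rayleigh-monotone", {
  m <- withr::with_seed(7, matrix(sample(c(10, 100, 1000), 25, TRUE), 5, 5))
  ck <- build_circuit(rast(m))
  sol <- circuit_solver(ck)
  trip <- c(1L, 13L, 25L)
  r <- function(a, b) effective_resistance(ck, a, b, solver = sol)
  expect_lte(r(trip[1], trip[3]), r(trip[1], trip[2]) + r(trip[2], trip[3]) + 1e-10)
  # lowering any single cell cost never increases R_eff
  base <- r(1L, 25L)
  for (cell in c(7L, 13L, 19L)) {
    m2 <- m
    m2[ck$nodes[cell, 1], ck$nodes[cell, 2]] <- m2[ck$nodes[cell, 1], ck$nodes[cell, 2]] / 10
    ck2 <- build_circuit(rast(m2))
    expect_lte(effective_resistance(ck2, 1L, 25L), base + 1e-10)
  }
})

test_that("current density follows Kirchhoff's laws", {
  ck <- build_circuit(rast(matrix(10, 1, 3)))
  v <- solve_pair(ck, c(1, 1), c(1, 3))
  dens <- cell_current_density(ck, v)
  expect_equal(dens, c(0.5, 1, 0.5))  # pass-through middle, terminal halves
  # random raster: conservation at interior nodes, terminals carry +-1
  m <- withr::with_seed(11, matrix(sample(c(10, 100, 1000), 49, TRUE), 7, 7))
  ck2 <- build_circuit(rast(m))
  s <- 3L; g <- 47L
  v2 <- solve_pair(ck2, s, g)
  net <- landconnect:::node_net_current(ck2, v2)
  expect_equal(net[s], 1, tolerance = 1e-8)
  expect_equal(net[g], -1, tolerance = 1e-8)
  expect_lt(max(abs(net[-c(s, g)])), 1e-8)
  # cut current equals injected current: columns left vs right of a cut
  cut_col <- 4L
  e <- ck2$edges
  lhs <- ck2$nodes[e$from, "col"] <= cut_col & ck2$nodes[e$to, "col"] > cut_col
  rhs <- ck2$nodes[e$to, "col"] <= cut_col & ck2$nodes[e$from, "col"] > cut_col
  I <- e$conductance * (v2[e$from] - v2[e$to])
  expect_equal(sum(I[lhs]) - sum(I[rhs]), 1, tolerance = 1e-8)
})

test_that("omnidirectional maps are flat on uniform rasters and mean-zero", {
  r <- rast(matrix(10, 28, 28))
  om <- omnidirectional_map(r, n_pairs = 64, buffer_cells = 6, seed = 5)
  expect_equal(mean(om$values), 0, tolerance = 1e-9)
  # interior (inner 50%) coefficient of variation below 0.2 before centering
  raw <- om$values + om$raw_mean
  inner <- raw[8:21, 8:21]
  expect_lt(sd(inner) / mean(inner), 0.2)
  # determinism
  om2b <- omnidirectional_map(r, n_pairs = 64, buffer_cells = 6, seed = 5)
  expect_identical(om$values, om2b$values)
})

test_that("a corridor between high-cost blocks is a current pinch point", {
  m <- matrix(1000, 21, 21)
  m[11, ] <- 10  # single low-cost corridor row
  om <- omnidirectional_map(rast(m), n_pairs = 64, buffer_cells = 8, seed = 9)
  corridor <- om$values[11, 11]
  expect_gt(corridor, quantile(om$values, 0.95))
})

test_that("omnidirectional maps respect rotational symmetry", {
  # rotationally symmetric raster: concentric cost rings
  n <- 15
  d <- as.matrix(dist(expand.grid(1:n, 1:n)))[, (n * n + 1) / 2]
  m <- matrix(ifelse(d > 5, 1000, 10), n, n)
  om1 <- omnidirectional_map(rast(m), n_pairs = 40, buffer_cells = 5, seed = 3)
  om2 <- omnidirectional_map(rast(t(m[n:1, ])), n_pairs = 40, buffer_cells = 5,
                             seed = 4)
  # rotate the second map back and compare within Monte-Carlo tolerance
  rot_back <- t(om2$values)[, n:1]
  expect_equal(mean(abs(om1$values - rot_back)),
               0, tolerance = 0.2 * sd(om1$values))
})

test_that("neighborhood analysis pairs next-nearest focal nodes", {
  n_focal <- 5L
  pairs <- cbind(seq_len(n_focal), (seq_len(n_focal) + 1L) %% n_focal + 1L)
  key <- apply(pairs, 1, function(p) paste(sort(p), collapse = "-"))
  expect_setequal(key, c("1-3", "2-4", "3-5", "1-4", "2-5"))
  expect_equal(length(unique(key)), 5L)
})

test_that("uniform circular landscapes give rotation-invariant pair resistances", {
  r <- rast(matrix(10, 41, 41))
  nb <- neighborhood_analysis(r, c(x = 2050, y = 2050), radius_m = 1800,
                              inset_m = 300, seed = 2)
  expect_equal(length(nb$pair_resistances), 5L)
  # nearest-cell snapping of the focal ring perturbs chord lengths by about
  # half a cell over an 18-cell radius, so allow ~3% asymmetry
  spread <- diff(range(nb$pair_resistances)) / mean(nb$pair_resistances)
  expect_lt(spread, 0.03)
  expect_gt(nb$mean_current_density, 0)
})

test_that("neighborhood windows clip and focal nodes nudge off NoData", {
  m <- matrix(10, 25, 25)
  m[10:16, 10:16] <- NA  # NoData hole near the center ring
  expect_warning(
    nb <- neighborhood_analysis(rast(m), c(x = 1250, y = 1250),
                                radius_m = 1400, inset_m = 300, seed = 6),
    "clipped")
  expect_equal(nrow(nb$focal_cells), 5L)
  vals <- rast(m)$values[nb$focal_cells]
  expect_true(all(!is.na(vals)))
})

test_that("pair solving rejects cross-component terminals", {
  m <- matrix(10, 2, 3)
  m[, 2] <- NA  # NoData column splits the lattice
  ck <- build_circuit(rast(m))
  left <- ck$node_of[1, 1]; right <- ck$node_of[1, 3]
  expect_error(solve_pair(ck, left, right), "different components")
})
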