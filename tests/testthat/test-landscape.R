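test_that("landscape class fractions hit their targets", {
  # degenerate fractions
  all_hab <- generate_landscape(landscape_spec(5, 5, habitat_fraction = 1, seed = 1))
  expect_true(all(all_hab$values == 10))
  all_high <- generate_landscape(landscape_spec(5, 5, habitat_fraction = 0,
                                                class_split = c(0, 1), seed = 1))
  expect_true(all(all_high$values == 1000))
  # 100x100 at 0.5: low-cost fraction within +-0.05
  r <- generate_landscape(landscape_spec(100, 100, habitat_fraction = 0.5, seed = 1))
  expect_true(all(r$values %in% c(10, 100, 1000)))
  frac <- mean(r$values == 10)
  expect_gte(frac, 0.45)
  expect_lte(frac, 0.55)
  # non-habitat split honors class_split
  r2 <- generate_landscape(landscape_spec(60, 60, habitat_fraction = 0.4,
                                          class_split = c(0.25, 0.75), seed = 2))
  expect_equal(mean(r2$values == 100), 0.6 * 0.25, tolerance = 0.1)
})

test_that("landscape generation is deterministic and clustering raises Moran's I", {
  s <- landscape_spec(40, 40, habitat_fraction = 0.5, clustering = 2, seed = 9)
  expect_identical(generate_landscape(s)$values, generate_landscape(s)$values)
  mi <- vapply(c(0, 2, 5), function(cl) {
    r <- generate_landscape(landscape_spec(50, 50, habitat_fraction = 0.5,
                                           clustering = cl, seed = 11))
    oracle_morans_i(r$values)
  }, 0)
  expect_true(all(diff(mi) > 0))
  expect_lt(abs(mi[1]), 0.1)  # white noise ~ uncorrelated
})

test_that("site placement respects separation constraints and determinism", {
  r <- generate_landscape(landscape_spec(100, 100, habitat_fraction = 0.5, seed = 3))
  one <- place_sites(r, sim_spec(n_sites = 1, seed = 4))
  expect_equal(nrow(one), 1L)
  five <- place_sites(r, sim_spec(n_sites = 5, min_site_separation_m = 0, seed = 4))
  expect_equal(nrow(unique(five[, c("row", "col")])), 5L)
  s8 <- sim_spec(n_sites = 8, min_site_separation_m = 2000, seed = 7)
  sites <- place_sites(r, s8)
  d <- as.matrix(dist(sites[, c("x", "y")]))
  expect_true(all(d[upper.tri(d)] >= 2000))
  expect_identical(place_sites(r, s8), sites)
  # infeasible separation errors, naming the constraint
  tiny <- generate_landscape(landscape_spec(5, 5, seed = 1))
  expect_error(place_sites(tiny, sim_spec(n_sites = 10,
                                          min_site_separation_m = 10000, seed = 1),
                           max_attempts = 200),
               "separation")
})

test_that("genotype simulation: no-drift limit, simplex, determinism", {
  r <- generate_landscape(landscape_spec(20, 20, habitat_fraction = 0.7, seed = 5))
  sites <- place_sites(r, sim_spec(n_sites = 4, min_site_separation_m = 300, seed = 6))
  sp0 <- sim_spec(n_sites = 4, n_loci = 4, alleles_per_locus = 5,
                  n_per_site = 8, drift_scale = 0, missing_rate = 0, seed = 8)
  tab0 <- simulate_genotypes(r, sites, sp0)
  sf <- attr(tab0, "site_freq")
  # drift 0: all sites share the ancestral frequencies
  for (s in 2:4) expect_equal(sf[, , s], sf[, , 1])
  # simplex at every locus and site
  expect_equal(apply(sf, c(2, 3), sum), matrix(1, 4, 4), tolerance = 1e-12)
  sp1 <- sim_spec(n_sites = 4, n_loci = 4, alleles_per_locus = 5,
                  n_per_site = 8, drift_scale = 1e-3, missing_rate = 0, seed = 8)
  t1 <- simulate_genotypes(r, sites, sp1)
  t2 <- simulate_genotypes(r, sites, sp1)
  expect_identical(t1$calls, t2$calls)
  expect_error(sim_spec(n_sites = 4, drift_scale = -1), "drift_scale")
})

test_that("a high-cost barrier increases cross-barrier genetic divergence", {
  open <- matrix(10, 21, 21)
  barrier <- open
  barrier[, 10:12] <- 1000  # wall bisecting the grid left/right
  sites <- data.frame(site_id = c("W1", "W2", "E1", "E2"),
                      row = c(5, 16, 5, 16), col = c(4, 4, 18, 18))
  xy <- cell_center(rast(open), sites$row, sites$col)
  sites$x <- xy[, 1]; sites$y <- xy[, 2]
  spc <- sim_spec(n_sites = 4, n_loci = 12, alleles_per_locus = 6,
                  n_per_site = 30, drift_scale = 2e-3, missing_rate = 0, seed = 21)
  d_of <- function(m) {
    tab <- simulate_genotypes(rast(m), sites, spc)
    mats <- population_covariance(encode_multivariate(tab))
    mean(mats$D[c("W1", "W2"), c("E1", "E2")])
  }
  expect_gt(d_of(barrier), d_of(open))
})

test_that("missing-call injection hits its rate and preserves the original", {
  r <- generate_landscape(landscape_spec(15, 15, seed = 1))
  sites <- place_sites(r, sim_spec(n_sites = 3, seed = 2))
  tab <- simulate_genotypes(r, sites, sim_spec(n_sites = 3, n_loci = 20,
                                               n_per_site = 40, drift_scale = 0,
                                               missing_rate = 0, seed = 3))
  expect_identical(inject_missing(tab, 0), tab)
  m5 <- inject_missing(tab, 0.5, seed = 10)
  expect_equal(mean(m5$calls == 0L), 0.5, tolerance = 0.03)
  expect_true(all(tab$calls > 0L))  # original untouched
  expect_identical(inject_missing(tab, 0.5, seed = 10)$calls, m5$calls)
  expect_error(inject_missing(tab, 1), "missing_rate")
})

test_that("genetic distance grows with landscape effective resistance", {
  # replicate landscapes spanning habitat fractions: pooled correlation
  # between inter-site R_eff and genetic distance is positive under drift
  hfs <- rep(c(0.2, 0.4, 0.6, 0.8), each = 5)
  pairs <- NULL
  for (k in seq_along(hfs)) {
    r <- generate_landscape(landscape_spec(18, 18, habitat_fraction = hfs[k],
                                           clustering = 2, seed = 400 + k))
    sites <- place_sites(r, sim_spec(n_sites = 4, min_site_separation_m = 300,
                                     seed = 500 + k))
    spc <- sim_spec(n_sites = 4, n_loci = 8, alleles_per_locus = 6,
                    n_per_site = 25, drift_scale = 1e-3, missing_rate = 0,
                    seed = 600 + k)
    tab <- simulate_genotypes(r, sites, spc)
    mats <- population_covariance(encode_multivariate(tab))
    ck <- build_circuit(r)
    sol <- circuit_solver(ck)
    ids <- ck$node_of[cbind(sites$row, sites$col)]
    for (i in 1:3) for (j in (i + 1):4) {
      pairs <- rbind(pairs, c(
        reff = effective_resistance(ck, ids[i], ids[j], solver = sol),
        gd = mats$D[i, j]))
    }
  }
  expect_gt(cor(pairs[, "reff"], pairs[, "gd"]), 0)
})
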