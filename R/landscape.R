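#' Specification of a synthetic cost landscape
#'
#' Parameters for a clustered three-class resistance landscape: thresholded
#' smoothed Gaussian noise cut at quantiles so the lowest-cost (habitat)
#' class covers `habitat_fraction` of cells, with the remaining mass split
#' between the semi-permeable and high-cost classes.
#'
#' @param grid_rows,grid_cols grid dimensions (>= 3 each).
#' @param cell_size_m cell size (m), default 100.
#' @param habitat_fraction proportion of cells in the lowest-cost class.
#' @param clustering spatial autocorrelation scale in cells (Gaussian
#'   smoothing length); 0 gives white noise.
#' @param cost_classes strictly increasing positive cost triple
#'   (default 10, 100, 1000: permeable / semi-permeable / high-cost cover).
#' @param class_split how the non-habitat mass divides between the middle
#'   and high cost classes (default 50/50).
#' @param seed integer seed.
#' @return a `landscape_spec` list.
#' @export
landscape_spec <- function(grid_rows, grid_cols, cell_size_m = 100,
                           habitat_fraction = 0.5, clustering = 3,
                           cost_classes = c(10, 100, 1000),
                           class_split = c(0.5, 0.5), seed = 1L) {
  if (grid_rows < 3 || grid_cols < 3) stopf("grid must be at least 3 x 3")
  if (habitat_fraction < 0 || habitat_fraction > 1)
    stopf("habitat_fraction must be in [0, 1]")
  if (clustering < 0) stopf("clustering must be >= 0")
  if (length(cost_classes) != 3 || any(diff(cost_classes) <= 0) ||
      any(cost_classes <= 0))
    stopf("cost_classes must be a strictly increasing positive triple")
  if (length(class_split) != 2 || any(class_split < 0) || sum(class_split) == 0)
    stopf("class_split must be two nonnegative weights")
  structure(list(grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols),
                 cell_size_m = cell_size_m,
                 habitat_fraction = habitat_fraction,
                 clustering = clustering, cost_classes = cost_classes,
                 class_split = class_split / sum(class_split),
                 seed = as.integer(seed)),
            class = "landscape_spec")
}

#' Specification of a synthetic genotype study
#'
#' @param n_sites number of sampling sites (>= 3 for downstream graphs).
#' @param n_loci microsatellite loci (default 12).
#' @param alleles_per_locus alleles per locus (>= 2, default 8).
#' @param n_per_site individuals per site; scalar or length-`n_sites`.
#' @param drift_scale nonnegative factor mapping a site's mean landscape
#'   effective resistance to Dirichlet drift away from the ancestral allele
#'   frequencies; drift_scale times mean effective resistance approximates the
#'   expected among-site FST, so the default 5e-4 yields FST of roughly
#'   0.05-0.3 at the package's synthetic landscape scales. 0 means no drift.
#' @param missing_rate proportion of allele calls set to missing (in [0, 1);
#'   default below the 35% filter threshold so sites survive filtering).
#' @param min_site_separation_m minimum pairwise site distance (m).
#' @param seed integer seed.
#' @return a `sim_spec` list.
#' @export
sim_spec <- function(n_sites, n_loci = 12L, alleles_per_locus = 8L,
                     n_per_site = 20L, drift_scale = 5e-4,
                     missing_rate = 0.02, min_site_separation_m = 0,
                     seed = 1L) {
  if (n_sites < 1) stopf("n_sites must be >= 1")
  if (alleles_per_locus < 2) stopf("alleles_per_locus must be >= 2")
  if (drift_scale < 0) stopf("drift_scale must be >= 0")
  if (missing_rate < 0 || missing_rate >= 1) stopf("missing_rate must be in [0, 1)")
  n_per_site <- as.integer(n_per_site)
  if (length(n_per_site) == 1L) n_per_site <- rep(n_per_site, n_sites)
  if (length(n_per_site) != n_sites || any(n_per_site < 1))
    stopf("n_per_site must be a positive scalar or one positive count per site")
  structure(list(n_sites = as.integer(n_sites), n_loci = as.integer(n_loci),
                 alleles_per_locus = as.integer(alleles_per_locus),
                 n_per_site = n_per_site, drift_scale = drift_scale,
                 missing_rate = missing_rate,
                 min_site_separation_m = min_site_separation_m,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

# 2-D Gaussian smoothing by FFT convolution with periodic wrap; sigma in cells.
smooth_field <- function(m, sigma) {
  if (sigma <= 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(0:floor(nr / 2), -((ceiling(nr / 2) - 1):1))
  ci <- c(0:floor(nc / 2), -((ceiling(nc / 2) - 1):1))
  k <- outer(exp(-ri^2 / (2 * sigma^2)), exp(-ci^2 / (2 * sigma^2)))
  k <- k / sum(k)
  Re(fft(fft(m) * fft(k), inverse = TRUE)) / (nr * nc)
}

#' Generate a synthetic resistance landscape
#'
#' Draws a Gaussian random field (white noise smoothed at the clustering
#' scale) and cuts it at quantiles so the class fractions match the spec:
#' cells below the `habitat_fraction` quantile get the lowest cost, and the
#' remainder is split between the middle and highest classes per
#' `class_split`.
#'
#' @param spec a [landscape_spec()].
#' @return a [resistance_raster()] whose cells take exactly the three costs.
#' @export
generate_landscape <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  m <- with_seed(spec$seed, {
    field <- matrix(rnorm(spec$grid_rows * spec$grid_cols),
                    spec$grid_rows, spec$grid_cols)
    smooth_field(field, spec$clustering)
  })
  hf <- spec$habitat_fraction
  q2 <- hf + (1 - hf) * spec$class_split[1]
  # empirical-quantile cuts hit the target fractions exactly (up to ties,
  # which are measure-zero for a continuous field)
  cuts <- quantile(m, probs = c(hf, q2), names = FALSE, type = 1)
  cls <- matrix(spec$cost_classes[3], nrow(m), ncol(m))
  cls[m <= cuts[2]] <- spec$cost_classes[2]
  cls[m <= cuts[1]] <- spec$cost_classes[1]
  if (hf >= 1) cls[] <- spec$cost_classes[1]
  if (hf <= 0 && spec$class_split[1] == 0) cls[] <- spec$cost_classes[3]
  resistance_raster(cls, cell_size_m = spec$cell_size_m)
}

#' Place sampling sites on a landscape
#'
#' Uniform rejection sampling over non-NoData cells with a minimum pairwise
#' separation constraint and a bounded number of attempts.
#'
#' @param raster a [resistance_raster()].
#' @param spec a [sim_spec()] (uses `n_sites`, `min_site_separation_m`, `seed`).
#' @param max_attempts rejection-sampling cap (default 10000).
#' @return data frame `site_id`, `x`, `y`, `row`, `col`.
#' @export
place_sites <- function(raster, spec, max_attempts = 10000L) {
  stopifnot(inherits(spec, "sim_spec"))
  ok <- which(!is.na(raster$values), arr.ind = TRUE)
  if (nrow(ok) < spec$n_sites) stopf("fewer valid cells than sites")
  sep <- spec$min_site_separation_m
  with_seed(spec$seed, {
    chosen <- matrix(NA_integer_, 0, 2)
    attempts <- 0L
    while (nrow(chosen) < spec$n_sites) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stopf(paste0("could not place %d sites with min separation %g m in ",
                     "%d attempts; relax min_site_separation_m or enlarge the grid"),
              spec$n_sites, sep, max_attempts)
      cand <- ok[sample.int(nrow(ok), 1L), , drop = FALSE]
      if (nrow(chosen) > 0L) {
        if (any(chosen[, 1] == cand[1] & chosen[, 2] == cand[2])) next
        if (sep > 0) {
          xy0 <- cell_center(raster, chosen[, 1], chosen[, 2])
          xy1 <- cell_center(raster, cand[1], cand[2])
          d <- sqrt((xy0[, 1] - xy1[1])^2 + (xy0[, 2] - xy1[2])^2)
          if (any(d < sep)) next
        }
      }
      chosen <- rbind(chosen, cand)
    }
    xy <- cell_center(raster, chosen[, 1], chosen[, 2])
    data.frame(site_id = sprintf("S%02d", seq_len(spec$n_sites)),
               x = xy[, 1], y = xy[, 2],
               row = chosen[, 1], col = chosen[, 2],
               stringsAsFactors = FALSE)
  })
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = pmax(alpha, 1e-8), rate = 1)
  if (sum(g) == 0) g <- rep(1, length(alpha))
  g / sum(g)
}

#' Simulate microsatellite genotypes structured by landscape resistance
#'
#' Ancestral allele frequencies per locus are drawn from a flat Dirichlet.
#' Each site's frequencies are then drawn from a Dirichlet centered on the
#' ancestral frequencies with concentration inversely proportional to
#' `drift_scale` times the site's mean effective resistance to all other
#' sites (computed on the supplied landscape), so isolated sites drift
#' further. Diploid genotypes are sampled multinomially from site
#' frequencies. With `drift_scale = 0` every site keeps the ancestral
#' frequencies exactly.
#'
#' @param raster a [resistance_raster()].
#' @param sites a [place_sites()] data frame.
#' @param spec a [sim_spec()].
#' @return a [genotype_table()].
#' @export
simulate_genotypes <- function(raster, sites, spec) {
  stopifnot(inherits(spec, "sim_spec"))
  if (spec$drift_scale < 0) stopf("drift_scale must be >= 0")
  ns <- nrow(sites)
  mean_reff <- rep(0, ns)
  if (spec$drift_scale > 0 && ns > 1L) {
    circuit <- build_circuit(raster)
    ids <- circuit$node_of[cbind(sites$row, sites$col)]
    if (anyNA(ids)) stopf("site on a NoData cell")
    comp <- unique(circuit$component[ids])
    if (length(comp) > 1L) stopf("sites span disconnected landscape components")
    solver <- circuit_solver(circuit, component = comp)
    R <- matrix(0, ns, ns)
    for (i in seq_len(ns - 1L)) for (j in seq.int(i + 1L, ns)) {
      R[i, j] <- R[j, i] <- effective_resistance(circuit, ids[i], ids[j],
                                                 solver = solver)
    }
    mean_reff <- rowSums(R) / (ns - 1L)
  }

  A <- spec$alleles_per_locus
  with_seed(spec$seed + 1L, {
    anc <- replicate(spec$n_loci, rdirichlet1(rep(1, A)))  # A x n_loci
    site_freq <- array(NA_real_, c(A, spec$n_loci, ns))
    for (s in seq_len(ns)) {
      drift <- spec$drift_scale * mean_reff[s]
      for (l in seq_len(spec$n_loci)) {
        site_freq[, l, s] <- if (drift == 0) anc[, l] else
          rdirichlet1(anc[, l] / drift)
      }
    }
    n_tot <- sum(spec$n_per_site)
    calls <- matrix(0L, n_tot, 2L * spec$n_loci)
    ind_site <- rep(seq_len(ns), spec$n_per_site)
    for (i in seq_len(n_tot)) {
      s <- ind_site[i]
      for (l in seq_len(spec$n_loci)) {
        calls[i, c(2L * l - 1L, 2L * l)] <-
          sample.int(A, 2L, replace = TRUE, prob = site_freq[, l, s])
      }
    }
    loci <- sprintf("L%02d", seq_len(spec$n_loci))
    colnames(calls) <- paste0(rep(loci, each = 2L), c("_1", "_2"))
    tab <- genotype_table(
      individuals = data.frame(
        individual_id = sprintf("I%04d", seq_len(n_tot)),
        site_id = sites$site_id[ind_site], stringsAsFactors = FALSE),
      loci = loci, calls = calls,
      sites = sites[, c("site_id", "x", "y")])
    attr(tab, "site_freq") <- site_freq
    attr(tab, "mean_reff") <- mean_reff
    if (spec$missing_rate > 0) {
      tab <- inject_missing(tab, spec$missing_rate, seed = spec$seed + 2L)
    }
    tab
  })
}

#' Inject missing allele calls
#'
#' Sets each allele call independently to the missing code (0) with the
#' given probability; the input table is untouched.
#'
#' @param table a [genotype_table()].
#' @param missing_rate probability an allele call is missing, in [0, 1).
#' @param seed integer seed.
#' @return a new [genotype_table()].
#' @export
inject_missing <- function(table, missing_rate, seed = NULL) {
  stopifnot(inherits(table, "genotype_table"))
  if (missing_rate < 0 || missing_rate >= 1) stopf("missing_rate must be in [0, 1)")
  if (missing_rate == 0) return(table)
  with_seed(seed, {
    mask <- matrix(runif(length(table$calls)) < missing_rate,
                   nrow(table$calls), ncol(table$calls))
    calls <- table$calls
    calls[mask] <- 0L
    table$calls <- calls
    table
  })
}
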