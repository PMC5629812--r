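#' Saturated genetic network
#'
#' The complete graph on sampled sites with edge weights equal to the
#' among-population genetic distances D. Zero distances between distinct
#' sites (genetically identical populations) are clamped to a small epsilon
#' with a warning, since downstream shortest paths need positive weights.
#'
#' @param mats a [population_covariance()] result.
#' @param meta optional data frame with `site_id` plus any of `x`, `y`,
#'   `species` to attach to nodes.
#' @return a `population_graph`: list with `nodes` (site_id, n, x, y,
#'   species), `edges` (site_a, site_b, weight, eed, kept), `alpha`
#'   (NA until pruned).
#' @export
saturated_graph <- function(mats, meta = NULL) {
  stopifnot(inherits(mats, "population_matrix_set"))
  sites <- mats$site_order
  nodes <- data.frame(site_id = sites, n = mats$n_per_site,
                      x = NA_real_, y = NA_real_, species = "all",
                      stringsAsFactors = FALSE)
  if (!is.null(meta)) {
    m <- meta[match(sites, meta$site_id), , drop = FALSE]
    for (f in intersect(c("x", "y", "species"), names(meta))) nodes[[f]] <- m[[f]]
  }
  idx <- which(upper.tri(mats$D), arr.ind = TRUE)
  w <- mats$D[idx]
  eps <- 1e-9 * max(mats$D)
  if (eps <= 0) eps <- 1e-12
  if (any(w <= 0)) {
    warnf("%d zero genetic distance(s) between distinct sites; clamped to %g",
          sum(w <= 0), eps)
    w[w <= 0] <- eps
  }
  edges <- data.frame(site_a = sites[idx[, 1]], site_b = sites[idx[, 2]],
                      weight = w, eed = NA_real_, kept = TRUE,
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, alpha = NA_real_),
            class = "population_graph")
}

#' @export
print.population_graph <- function(x, ...) {
  cat(sprintf("<population_graph> %d nodes, %d/%d edges kept%s\n",
              nrow(x$nodes), sum(x$edges$kept), nrow(x$edges),
              if (is.na(x$alpha)) " (unpruned)" else sprintf(" (alpha = %g)", x$alpha)))
  invisible(x)
}

#' Prune edges by edge-exclusion deviance
#'
#' Conditional-independence pruning of the saturated network: the
#' among-population covariance is converted to a correlation matrix and
#' inverted to a precision matrix, and each edge's partial correlation given
#' all other nodes is tested with the edge-exclusion deviance
#' EED = -N log(1 - r^2), compared to the chi-square(1) critical value at
#' `alpha`. Edges whose removal would not degrade the Gaussian graphical
#' model's fit (EED below the critical value) are dropped; every pair's
#' statistic and decision is recorded.
#'
#' A grand-centered among-population covariance is rank-deficient by one, so
#' the precision matrix is taken as the eigen-pseudoinverse of the
#' correlation matrix (null directions excluded); the detected rank is
#' logged.
#'
#' @param graph a [saturated_graph()].
#' @param C among-population covariance matrix (sites x sites, ordered as
#'   the graph nodes).
#' @param alpha significance level (default 0.05; critical value 3.841).
#' @param n_total total individuals after filtering (defaults to the sum of
#'   node sample sizes).
#' @return the graph with `eed` and `kept` filled and `alpha` set.
#' @export
prune_edges <- function(graph, C, alpha = 0.05,
                        n_total = sum(graph$nodes$n)) {
  stopifnot(inherits(graph, "population_graph"))
  if (alpha <= 0 || alpha > 1) stopf("alpha must be in (0, 1]")
  sites <- graph$nodes$site_id
  if (!all(dim(C) == length(sites))) stopf("C does not match the graph's node set")
  R <- stats::cov2cor(C)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  rank <- sum(ev > 1e-10 * max(ev))
  if (rank < nrow(R))
    log_msg("popgraph", "correlation matrix has rank %d of %d; pseudoinverse precision",
            rank, nrow(R))
  P <- sym_pinv(R)
  d <- sqrt(pmax(diag(P), .Machine$double.eps))
  partial <- -P / outer(d, d)
  r2 <- pmin(partial^2, 1 - 1e-15)
  eed <- -n_total * log(1 - r2)
  crit <- qchisq(1 - alpha, df = 1)
  ia <- match(graph$edges$site_a, sites)
  ib <- match(graph$edges$site_b, sites)
  graph$edges$eed <- eed[cbind(ia, ib)]
  graph$edges$kept <- graph$edges$eed > crit
  graph$alpha <- alpha
  log_msg("popgraph", "pruning at alpha = %g: kept %d of %d edges",
          alpha, sum(graph$edges$kept), nrow(graph$edges))
  graph
}

as_igraph <- function(graph, kept_only = TRUE) {
  e <- graph$edges
  if (kept_only) e <- e[e$kept, , drop = FALSE]
  igraph::graph_from_data_frame(
    d = data.frame(from = e$site_a, to = e$site_b, weight = e$weight,
                   eed = e$eed),
    directed = FALSE,
    vertices = graph$nodes[, c("site_id", "n", "x", "y", "species")])
}

#' Conditional genetic distance (cGD)
#'
#' All-pairs shortest-path lengths along the pruned network, with retained
#' genetic distances as edge lengths. Pairs in different components are
#' flagged unreachable (`Inf` in the matrix, `FALSE` in the mask), never
#' fabricated.
#'
#' @param graph a pruned [population_graph()].
#' @return a `cgd_matrix`: list with `site_order`, `cgd`, `reachable`.
#' @export
conditional_genetic_distance <- function(graph) {
  stopifnot(inherits(graph, "population_graph"))
  g <- as_igraph(graph, kept_only = TRUE)
  cgd <- igraph::distances(g, weights = igraph::E(g)$weight)
  ord <- graph$nodes$site_id
  cgd <- cgd[ord, ord]
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    warnf("pruned graph has %d components: %s", comp$no,
          paste(vapply(seq_len(comp$no), function(k)
            paste(names(comp$membership)[comp$membership == k], collapse = "+"),
            ""), collapse = " | "))
  }
  structure(list(site_order = ord, cgd = cgd, reachable = is.finite(cgd)),
            class = "cgd_matrix")
}

#' Node-based genetic connectivity
#'
#' For each node, the mean and mean inverse of its retained incident edge
#' weights (the inverse mean is the gene-flow proxy: shorter edges mean
#' stronger genetic connectivity), plus a within-species z-score putting
#' species on a common scale. An all-pairs variant using 1/cGD to every
#' reachable node is available via `method = "allpairs"`.
#'
#' @param graph a pruned [population_graph()].
#' @param method `"incident"` (default; retained incident edges) or
#'   `"allpairs"` (inverse cGD to all reachable nodes).
#' @param cgd a [conditional_genetic_distance()] result, required for
#'   `method = "allpairs"`.
#' @return data frame: site_id, species, n, x, y, degree, mean_weight,
#'   mean_inv_weight, z_mean_inv_weight (NA for isolated nodes).
#' @export
node_connectivity <- function(graph, method = c("incident", "allpairs"),
                              cgd = NULL) {
  stopifnot(inherits(graph, "population_graph"))
  method <- match.arg(method)
  nodes <- graph$nodes
  e <- graph$edges[graph$edges$kept, , drop = FALSE]
  mw <- miw <- deg <- rep(NA_real_, nrow(nodes))
  for (i in seq_len(nrow(nodes))) {
    s <- nodes$site_id[i]
    if (method == "incident") {
      w <- c(e$weight[e$site_a == s], e$weight[e$site_b == s])
    } else {
      if (is.null(cgd)) stopf("method 'allpairs' needs a cgd matrix")
      w <- cgd$cgd[s, ]
      w <- w[names(w) != s & is.finite(w)]
    }
    deg[i] <- length(w)
    if (length(w) > 0L) {
      mw[i] <- mean(w)
      miw[i] <- mean(1 / w)
    }
  }
  if (any(deg == 0L))
    log_msg("popgraph", "isolated node(s), connectivity undefined: %s",
            paste(nodes$site_id[deg == 0L], collapse = ", "))
  out <- data.frame(site_id = nodes$site_id, species = nodes$species,
                    n = nodes$n, x = nodes$x, y = nodes$y, degree = deg,
                    mean_weight = mw, mean_inv_weight = miw,
                    z_mean_inv_weight = NA_real_, stringsAsFactors = FALSE)
  for (sp in unique(out$species)) {
    rows <- which(out$species == sp & !is.na(out$mean_inv_weight))
    if (length(rows) < 2L)
      stopf("species '%s' has < 2 connected nodes; z-score undefined", sp)
    out$z_mean_inv_weight[rows] <- zscore(out$mean_inv_weight[rows])
  }
  out
}

#' Export / import a population graph as GraphML
#'
#' Round-trips nodes, kept edges, weights and deviance statistics through
#' igraph's GraphML writer.
#'
#' @param graph a [population_graph()].
#' @param path file path.
#' @export
write_popgraph_graphml <- function(graph, path) {
  igraph::write_graph(as_igraph(graph, kept_only = TRUE), path,
                      format = "graphml")
  invisible(path)
}

#' @rdname write_popgraph_graphml
#' @return `read_popgraph_graphml`: a `population_graph` (all edges kept).
#' @export
read_popgraph_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  vl <- igraph::vertex_attr(g)
  el <- igraph::as_data_frame(g, what = "edges")
  nodes <- data.frame(site_id = vl$name, n = vl$n, x = vl$x, y = vl$y,
                      species = vl$species, stringsAsFactors = FALSE)
  edges <- data.frame(site_a = el$from, site_b = el$to, weight = el$weight,
                      eed = if ("eed" %in% names(el)) el$eed else NA_real_,
                      kept = TRUE, stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, alpha = NA_real_),
            class = "population_graph")
}

#' Write the population graph as edge-list and node-table CSVs
#'
#' @param graph a [population_graph()].
#' @param prefix output path prefix; writes `<prefix>_edges.csv` (all pairs
#'   with weight, eed, kept) and `<prefix>_nodes.csv`.
#' @export
write_popgraph_csv <- function(graph, prefix) {
  write.csv(graph$edges, paste0(prefix, "_edges.csv"), row.names = FALSE)
  write.csv(graph$nodes, paste0(prefix, "_nodes.csv"), row.names = FALSE)
  invisible(prefix)
}
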