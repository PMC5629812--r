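# handmade population_graph from an edge list
graph_from_edges <- function(edges, nodes = NULL, species = "all") {
  ids <- sort(unique(c(edges$site_a, edges$site_b)))
  if (is.null(nodes))
    nodes <- data.frame(site_id = ids, n = 10L, x = seq_along(ids),
                        y = 0, species = species, stringsAsFactors = FALSE)
  edges$eed <- edges$eed %||% NA_real_
  edges$kept <- edges$kept %||% TRUE
  structure(list(nodes = nodes, edges = edges, alpha = 0.05),
            class = "population_graph")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("saturated graph is complete with D as weights", {
  fr <- rbind(c(0.8, 0.1, 0.1), c(0.1, 0.8, 0.1), c(0.1, 0.1, 0.8), c(0.4, 0.3, 0.3))
  mats <- population_covariance(encode_multivariate(
    freq_table(fr, n_per_site = 10, n_loci = 5, seed = 5)))
  g <- saturated_graph(mats)
  expect_equal(nrow(g$edges), choose(4, 2))
  for (k in seq_len(nrow(g$edges))) {
    expect_equal(g$edges$weight[k],
                 mats$D[g$edges$site_a[k], g$edges$site_b[k]])
  }
  # genetically identical populations: weights clamped with a warning
  same <- tiny_table(rbind(c(1L, 2L), c(2L, 1L))[rep(1:2, 3), ],
                     rep(c("A", "B", "C"), each = 2))
  mats0 <- population_covariance(encode_multivariate(same))
  expect_warning(g0 <- saturated_graph(mats0), "clamped")
  expect_true(all(g0$edges$weight > 0))
})

test_that("pruning with an identity covariance empties the edge set", {
  mats <- structure(list(site_order = c("A", "B", "C", "D"),
                         C = diag(4), D = outer(rep(1, 4), rep(1, 4)) * 2 - 2 * diag(4),
                         n_per_site = rep(10L, 4)),
                    class = "population_matrix_set")
  dimnames(mats$C) <- dimnames(mats$D) <- list(mats$site_order, mats$site_order)
  g <- prune_edges(saturated_graph(mats), mats$C, alpha = 0.05)
  expect_equal(sum(g$edges$kept), 0L)
  expect_true(all(is.finite(g$edges$eed)))
  expect_equal(max(g$edges$eed), 0, tolerance = 1e-10)
})

test_that("pruning decisions match a dense precision-matrix oracle", {
  # site 3's centroid ~ average of sites 1 and 2: edge (1,2) should carry
  # little partial covariance given 3 and be pruned
  fr <- rbind(c(0.9, 0.05, 0.05), c(0.05, 0.9, 0.05), c(0.475, 0.475, 0.05),
              c(0.05, 0.05, 0.9))
  tab <- freq_table(fr, n_per_site = 30, n_loci = 12, seed = 13)
  mats <- population_covariance(encode_multivariate(tab))
  N <- sum(mats$n_per_site)
  g <- prune_edges(saturated_graph(mats), mats$C, alpha = 0.05, n_total = N)
  # oracle: explicit correlation -> pseudoinverse precision -> partial r -> deviance
  R <- stats::cov2cor(mats$C)
  P <- pinv_sym(R)
  for (k in seq_len(nrow(g$edges))) {
    i <- match(g$edges$site_a[k], mats$site_order)
    j <- match(g$edges$site_b[k], mats$site_order)
    pr <- -P[i, j] / sqrt(P[i, i] * P[j, j])
    eed <- -N * log(1 - pr^2)
    expect_equal(g$edges$eed[k], eed, tolerance = 1e-8)
    expect_equal(g$edges$kept[k], eed > qchisq(0.95, 1))
  }
})

test_that("pruning is monotone in alpha and keeps everything as alpha -> 1", {
  fr <- withr::with_seed(17, matrix(runif(5 * 4), 5)); fr <- fr / rowSums(fr)
  mats <- population_covariance(encode_multivariate(
    freq_table(fr, n_per_site = 15, n_loci = 8, seed = 19)))
  sat <- saturated_graph(mats)
  kept <- function(alpha) {
    g <- prune_edges(sat, mats$C, alpha = alpha)
    which(g$edges$kept)
  }
  k01 <- kept(0.01); k05 <- kept(0.05); k999 <- kept(0.999999)
  expect_true(all(k01 %in% k05))
  expect_equal(k999, seq_len(nrow(sat$edges)))  # critical value -> 0
})

test_that("cGD is the shortest-path metric on the pruned graph", {
  g <- graph_from_edges(data.frame(
    site_a = c("A", "B"), site_b = c("B", "C"), weight = c(2, 3)))
  cgd <- conditional_genetic_distance(g)
  expect_equal(cgd$cgd["A", "C"], 5)
  expect_equal(diag(cgd$cgd), setNames(rep(0, 3), c("A", "B", "C")))
  expect_true(all(cgd$reachable))
})

test_that("cGD matches an independent Dijkstra oracle on random graphs", {
  for (seed in 1:3) {
    ed <- withr::with_seed(seed, {
      nodes <- sprintf("N%d", 1:10)
      all_pairs <- t(combn(nodes, 2))
      pick <- sample(nrow(all_pairs), 18)
      data.frame(site_a = all_pairs[pick, 1], site_b = all_pairs[pick, 2],
                 weight = round(runif(18, 0.5, 5), 2),
                 stringsAsFactors = FALSE)
    })
    g <- graph_from_edges(ed)
    cgd <- conditional_genetic_distance(g)
    for (src in g$nodes$site_id[c(1, 5, 9)]) {
      oracle <- oracle_dijkstra(ed, g$nodes$site_id, src)
      expect_equal(cgd$cgd[src, names(oracle)], oracle, tolerance = 1e-12)
    }
  }
})

test_that("disconnected pruned graphs flag unreachable pairs", {
  g <- graph_from_edges(data.frame(site_a = c("A", "C"), site_b = c("B", "D"),
                                   weight = c(1, 1)))
  expect_warning(cgd <- conditional_genetic_distance(g), "2 components")
  expect_false(cgd$reachable["A", "C"])
  expect_true(is.infinite(cgd$cgd["A", "C"]))
})

test_that("node connectivity matches recomputation from the edge list", {
  ed <- withr::with_seed(31, {
    nodes <- sprintf("N%d", 1:8)
    all_pairs <- t(combn(nodes, 2))
    pick <- sample(nrow(all_pairs), 14)
    data.frame(site_a = all_pairs[pick, 1], site_b = all_pairs[pick, 2],
               weight = round(runif(14, 1, 6), 2), stringsAsFactors = FALSE)
  })
  g <- graph_from_edges(ed)
  conn <- node_connectivity(g)
  for (i in seq_len(nrow(conn))) {
    s <- conn$site_id[i]
    w <- c(ed$weight[ed$site_a == s], ed$weight[ed$site_b == s])
    expect_equal(conn$degree[i], length(w))
    expect_equal(conn$mean_weight[i], mean(w))
    expect_equal(conn$mean_inv_weight[i], mean(1 / w))
  }
  # z-scores standardized within species
  expect_equal(mean(conn$z_mean_inv_weight), 0, tolerance = 1e-12)
  expect_equal(sd(conn$z_mean_inv_weight), 1, tolerance = 1e-12)
  # direct arithmetic: weights {2, 4} -> mean inverse 0.375
  g2 <- graph_from_edges(data.frame(site_a = c("A", "A", "B"),
                                    site_b = c("B", "C", "C"),
                                    weight = c(2, 4, 8)))
  conn2 <- node_connectivity(g2)
  expect_equal(conn2$mean_inv_weight[conn2$site_id == "A"], 0.375)
})

test_that("species mean inverse edge weight obeys Jensen's inequality", {
  fr <- withr::with_seed(23, matrix(runif(6 * 5), 6)); fr <- fr / rowSums(fr)
  mats <- population_covariance(encode_multivariate(
    freq_table(fr, n_per_site = 12, n_loci = 6, seed = 29)))
  g <- prune_edges(saturated_graph(mats), mats$C, alpha = 0.5)
  conn <- node_connectivity(g)
  expect_gte(mean(conn$mean_inv_weight), 1 / mean(conn$mean_weight))
})

test_that("pruned cGD never undercuts the saturated-graph cGD", {
  fr <- withr::with_seed(37, matrix(runif(5 * 4), 5)); fr <- fr / rowSums(fr)
  mats <- population_covariance(encode_multivariate(
    freq_table(fr, n_per_site = 10, n_loci = 6, seed = 41)))
  sat <- saturated_graph(mats)
  pruned <- prune_edges(sat, mats$C, alpha = 0.05)
  if (sum(pruned$edges$kept) >= 1 &&
      igraph::is_connected(landconnect:::as_igraph(pruned))) {
    c_sat <- conditional_genetic_distance(sat)$cgd
    c_pru <- conditional_genetic_distance(pruned)$cgd
    expect_true(all(c_pru + 1e-12 >= c_sat[rownames(c_pru), colnames(c_pru)]))
  } else {
    succeed("pruned graph disconnected; dominance vacuous")
  }
})

test_that("GraphML export round-trips nodes, edges and weights", {
  ed <- data.frame(site_a = c("A", "B", "C"), site_b = c("B", "C", "A"),
                   weight = c(1.25, 2.5, 3.75), eed = c(5, 6, 7), kept = TRUE)
  g <- graph_from_edges(ed)
  path <- withr::local_tempfile(fileext = ".graphml")
  write_popgraph_graphml(g, path)
  back <- read_popgraph_graphml(path)
  expect_setequal(back$nodes$site_id, g$nodes$site_id)
  key <- function(e) paste(pmin(e$site_a, e$site_b), pmax(e$site_a, e$site_b))
  expect_equal(back$edges$weight[order(key(back$edges))],
               g$edges$weight[order(key(g$edges))])
})
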