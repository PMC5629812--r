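# Independent oracles used across the suite. These deliberately avoid the
# package's own solver paths: dense pseudoinverse algebra for circuits, a
# from-scratch Dijkstra for shortest paths, normal equations for OLS.

# Moore-Penrose pseudoinverse via eigendecomposition (Laplacians are
# symmetric PSD with a known null space).
pinv_sym <- function(L, tol = 1e-10) {
  e <- eigen(L, symmetric = TRUE)
  keep <- e$values > tol * max(e$values)
  e$vectors[, keep, drop = FALSE] %*%
    diag(1 / e$values[keep], sum(keep)) %*%
    t(e$vectors[, keep, drop = FALSE])
}

# Effective resistance from the pseudoinverse: R = L+_ss + L+_gg - 2 L+_sg
oracle_reff <- function(circuit, s, g) {
  Lp <- pinv_sym(as.matrix(circuit$laplacian))
  Lp[s, s] + Lp[g, g] - 2 * Lp[s, g]
}

# Voltages for unit current s -> g, referenced so v[g] = 0
oracle_voltages <- function(circuit, s, g) {
  Lp <- pinv_sym(as.matrix(circuit$laplacian))
  v <- Lp[, s] - Lp[, g]
  v - v[g]
}

# Textbook Dijkstra on an undirected weighted edge list (site_a, site_b, weight)
oracle_dijkstra <- function(edges, nodes, source) {
  dist <- setNames(rep(Inf, length(nodes)), nodes)
  dist[source] <- 0
  visited <- setNames(rep(FALSE, length(nodes)), nodes)
  repeat {
    unv <- names(dist)[!visited]
    if (length(unv) == 0 || all(is.infinite(dist[unv]))) break
    u <- unv[which.min(dist[unv])]
    visited[u] <- TRUE
    nb <- rbind(
      data.frame(v = edges$site_b[edges$site_a == u], w = edges$weight[edges$site_a == u]),
      data.frame(v = edges$site_a[edges$site_b == u], w = edges$weight[edges$site_b == u]))
    for (k in seq_len(nrow(nb))) {
      alt <- dist[u] + nb$w[k]
      if (alt < dist[nb$v[k]]) dist[nb$v[k]] <- alt
    }
  }
  dist
}

# OLS slopes and SEs by explicit normal equations
oracle_ols <- function(X, y) {
  Xd <- cbind(1, X)
  XtXi <- solve(t(Xd) %*% Xd)
  beta <- XtXi %*% t(Xd) %*% y
  res <- y - Xd %*% beta
  s2 <- sum(res^2) / (nrow(Xd) - ncol(Xd))
  list(beta = as.numeric(beta), se = sqrt(diag(XtXi) * s2))
}

# Moran's I with a binary rook-adjacency weight matrix, computed directly
oracle_morans_i <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  z <- as.vector(m) - mean(m)
  num <- 0; wsum <- 0
  idx <- function(r, c) (c - 1L) * nr + r
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (r < nr) { num <- num + 2 * z[idx(r, c)] * z[idx(r + 1, c)]; wsum <- wsum + 2 }
    if (c < nc) { num <- num + 2 * z[idx(r, c)] * z[idx(r, c + 1)]; wsum <- wsum + 2 }
  }
  (length(z) / wsum) * num / sum(z^2)
}
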