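library(igraph)

# chain a -> b -> c (resource -> consumer)
chain_graph <- function(nodes = c("a", "b", "c")) {
  graph_from_data_frame(
    data.frame(from = nodes[-length(nodes)], to = nodes[-1]),
    directed = TRUE, vertices = nodes)
}

chain_abundances <- function(rows, nodes = c("a", "b", "c")) {
  m <- do.call(rbind, rows)
  dimnames(m) <- list(names(rows), nodes)
  m
}

# random weakly connected digraph (for oracle sweeps)
random_connected_digraph <- function(n, p = NULL) {
  if (is.null(p)) p <- min(1, max(2 / n, 0.08))
  repeat {
    g <- sample_gnp(n, p, directed = TRUE)
    g <- delete_edges(g, E(g)[which_loop(g)])
    if (vcount(g) >= 2 && ecount(g) >= 1 &&
        is_connected(g, mode = "weak")) {
      V(g)$name <- paste0("v", seq_len(n))
      return(g)
    }
  }
}

# reduced-system oracle for Lx = v: pin coordinate 1 to zero and solve the
# nonsingular remainder -- independent of the minimum-norm route used by
# solve_trophic_levels()
tl_oracle <- function(g) {
  L <- laplacian_sym(g)
  v <- imbalance_vector(g)
  n <- nrow(L)
  if (n == 1) return(stats::setNames(0, rownames(L)))
  x <- c(0, solve(L[-1, -1, drop = FALSE], v[-1]))
  stats::setNames(x - min(x), rownames(L))
}

# brute-force double-loop Moran oracle
moran_oracle <- function(y, g) {
  A <- as_adjacency_matrix(g, sparse = FALSE)
  A <- (A > 0) * 1
  W <- A + t(A)
  n <- length(y)
  yc <- y - mean(y)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- num + W[i, j] * yc[i] * yc[j]
  }
  (n / sum(W)) * num / sum(yc^2)
}

# strip dimnames/attributes off a kernel for plain numeric comparison
kmat <- function(K) {
  attr(K, "beta") <- NULL
  unname(unclass(K))
}

# canonical representation of a graph for equality checks
canonical_graph <- function(g) {
  el <- as_edgelist(g)
  w <- if ("weight" %in% edge_attr_names(g)) E(g)$weight else
    rep(1, ecount(g))
  ord <- order(el[, 1], el[, 2])
  list(nodes = sort(V(g)$name),
       ab = if (!is.null(V(g)$ab))
         V(g)$ab[order(V(g)$name)] else NULL,
       edges = data.frame(from = el[ord, 1], to = el[ord, 2],
                          w = w[ord]))
}

mean_branch_contrast <- function(M, a_nodes, b_nodes) {
  within <- c(M[a_nodes, a_nodes][upper.tri(diag(length(a_nodes)))],
              M[b_nodes, b_nodes][upper.tri(diag(length(b_nodes)))])
  mean(within) - mean(M[a_nodes, b_nodes])
}
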