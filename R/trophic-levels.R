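#' Laplacian of the symmetrised network
#'
#' \eqn{L = D - A - A^T}, where \eqn{A} is the adjacency matrix (binary by
#' default) and \eqn{D} the diagonal matrix of row sums of \eqn{A + A^T}.
#' \eqn{L} is symmetric positive semi-definite with zero row sums; its rank
#' is \eqn{n} minus the number of weakly connected components. Self-loops
#' cancel out of \eqn{L} by construction.
#'
#' @param graph an `igraph` graph
#' @param weighted use the `weight` edge attribute instead of binary
#'   adjacency (default `FALSE`: trophic levels are defined on degrees)
#' @return a dense symmetric matrix with dimnames = node names
#' @export
laplacian_sym <- function(graph, weighted = FALSE) {
  stopifnot(inherits(graph, "igraph"))
  if (vcount(graph) == 0) stop("graph is empty")
  A <- adjacency_of(graph, weighted)
  S <- A + t(A)
  diag_S <- diag(S)
  L <- diag(rowSums(S), nrow = nrow(S)) - S
  dimnames(L) <- dimnames(A)
  L
}

adjacency_of <- function(graph, weighted = FALSE) {
  A <- as_adjacency_matrix(graph,
                           attr = if (weighted) edge_weight_attr(graph),
                           sparse = FALSE)
  if (!weighted) A <- (A > 0) * 1
  A
}

#' Trophic imbalance vector
#'
#' Per-node in-degree minus out-degree under the resource-to-consumer edge
#' orientation: basal species have negative imbalance, apex consumers
#' positive, and the entries sum to zero.
#'
#' @inheritParams laplacian_sym
#' @return named numeric vector
#' @export
imbalance_vector <- function(graph, weighted = FALSE) {
  A <- adjacency_of(graph, weighted)
  stats::setNames(colSums(A) - rowSums(A), colnames(A))
}

#' Solve the trophic-level linear system for one connected component
#'
#' Solves \eqn{L x = v} for the trophic levels \eqn{x}. On a connected
#' network the solution is unique up to translation; the minimum-norm
#' least-squares solution is taken and translated so that its minimal entry
#' is 0 (basal species).
#'
#' @param L symmetric Laplacian of one weakly connected graph
#'   ([laplacian_sym()])
#' @param v its imbalance vector ([imbalance_vector()])
#' @param tol residual tolerance on \eqn{\|Lx - v\|_\infty}
#' @return named numeric vector of trophic levels, minimum 0
#' @export
solve_trophic_levels <- function(L, v, tol = 1e-8) {
  stopifnot(is.matrix(L), nrow(L) == ncol(L), length(v) == nrow(L))
  if (nrow(L) == 1) {
    return(stats::setNames(0, rownames(L)))
  }
  x <- as.vector(MASS::ginv(L) %*% v)
  resid <- max(abs(L %*% x - v))
  if (!is.finite(resid) || resid > tol) {
    stop("trophic-level system inconsistent: residual ", format(resid),
         " exceeds ", format(tol),
         " (is the graph a single weakly connected component?)")
  }
  stats::setNames(x - min(x), rownames(L))
}

trophic_levels_of <- function(graph, weighted = FALSE) {
  solve_trophic_levels(laplacian_sym(graph, weighted),
                       imbalance_vector(graph, weighted))
}

#' Compute trophic levels across a metanetwork
#'
#' Trophic levels solve \eqn{L x = v} with \eqn{L} the Laplacian of the
#' symmetrised web and \eqn{v} the in-minus-out degree imbalance. The
#' metaweb is connected, so its solution is anchored by fixing the minimal
#' level to 0. Local (and aggregated) networks may be disconnected: each
#' weakly connected component is solved independently and translated so that
#' its minimal-level node takes that node's trophic level in the
#' corresponding metaweb. When several nodes tie for the component minimum,
#' the anchor is the one with the smallest metaweb trophic level, ties broken
#' by node name.
#'
#' Levels are stored as the `TL` vertex attribute on every network at every
#' resolution present, and are the x-axis of the TL-tsne layouts.
#'
#' @param metanet a `metanetwork`
#' @param weighted solve on edge-weighted degrees instead of binary (the
#'   definition is stated on degrees; weighted solves are opt-in)
#' @return the `metanetwork` with `TL` vertex attributes filled in.
#' @export
compute_TL <- function(metanet, weighted = FALSE) {
  stopifnot(inherits(metanet, "metanetwork"))
  if (weighted_edges_present(metanet$metaweb) && !weighted) {
    message("metaweb has edge weights; trophic levels use binary degrees ",
            "(set weighted = TRUE to change)")
  }
  metanet$metaweb <- set_TL_anchored(metanet$metaweb, ref = NULL, weighted)
  ref <- stats::setNames(V(metanet$metaweb)$TL, V(metanet$metaweb)$name)
  metanet$locals <- lapply(metanet$locals, set_TL_anchored, ref = ref,
                           weighted = weighted)
  for (res in names(metanet$aggregated)) {
    agg <- metanet$aggregated[[res]]
    agg$metaweb <- set_TL_anchored(agg$metaweb, ref = NULL, weighted)
    aref <- stats::setNames(V(agg$metaweb)$TL, V(agg$metaweb)$name)
    agg$locals <- lapply(agg$locals, set_TL_anchored, ref = aref,
                         weighted = weighted)
    metanet$aggregated[[res]] <- agg
  }
  metanet
}

weighted_edges_present <- function(graph) {
  w <- E(graph)$weight
  !is.null(w) && any(w != 1)
}

# Solve per weakly connected component; anchor each component either at 0
# (ref = NULL, the metaweb case) or at the metaweb level of its minimal node.
set_TL_anchored <- function(graph, ref = NULL, weighted = FALSE) {
  comp <- components(graph, mode = "weak")
  tl <- stats::setNames(numeric(vcount(graph)), V(graph)$name)
  for (ci in seq_len(comp$no)) {
    members <- V(graph)$name[comp$membership == ci]
    sub <- induced_subgraph(graph, members)
    x <- trophic_levels_of(sub, weighted)
    if (!is.null(ref)) {
      cand <- names(x)[x <= min(x) + 1e-10]
      cand <- cand[order(ref[cand], cand)]
      anchor <- cand[1]
      x <- x - x[anchor] + ref[anchor]
    }
    tl[names(x)] <- x
  }
  V(graph)$TL <- unname(tl[V(graph)$name])
  graph
}

#' Export trophic levels as a data frame
#'
#' One row per node per network (`network, node, trophic_level`), suitable
#' for writing with [utils::write.csv()].
#'
#' @param metanet a `metanetwork` after [compute_TL()]
#' @param resolution resolution to export (default finest)
#' @return a `data.frame`
#' @export
trophic_levels_table <- function(metanet, resolution = NULL) {
  nets <- network_names(metanet)
  do.call(rbind, lapply(nets, function(nm) {
    g <- get_network(metanet, nm, resolution)
    if (is.null(V(g)$TL)) stop("trophic levels missing; run compute_TL()")
    data.frame(network = nm, node = V(g)$name, trophic_level = V(g)$TL,
               stringsAsFactors = FALSE)
  }))
}
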