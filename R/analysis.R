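#' Difference network between two local networks
#'
#' The difference network of local webs \eqn{G_1, G_2} is the vertex-induced
#' subgraph of the metaweb by \eqn{V_1 \cup V_2}, annotated per node with
#' the abundance difference \eqn{\Delta p = p_1 - p_2} (0 where absent) and
#' a presence category (`both`, `only-first`, `only-second`), and per edge
#' with the weight difference \eqn{\Delta w} (an edge's weight counts as 0
#' in a network missing either endpoint).
#'
#' @param metanet a `metanetwork`
#' @param name1,name2 local network names
#' @return object of class `diff_network`: list with `graph` (the induced
#'   subgraph), `nodes` (`data.frame(node, delta_ab, category)`), `edges`
#'   (`data.frame(resource, consumer, delta_w)`) and `networks`.
#' @export
diff_networks <- function(metanet, name1, name2) {
  stopifnot(inherits(metanet, "metanetwork"))
  g1 <- get_network(metanet, name1)
  g2 <- get_network(metanet, name2)
  v1 <- V(g1)$name
  v2 <- V(g2)$name
  vd <- V(metanet$metaweb)$name[V(metanet$metaweb)$name %in% union(v1, v2)]
  g <- induced_subgraph(metanet$metaweb, vd)

  p1 <- stats::setNames(V(g1)$ab, v1)
  p2 <- stats::setNames(V(g2)$ab, v2)
  ab1 <- ifelse(vd %in% v1, p1[vd], 0)
  ab2 <- ifelse(vd %in% v2, p2[vd], 0)
  category <- ifelse(vd %in% v1 & vd %in% v2, "both",
                     ifelse(vd %in% v1, "only-first", "only-second"))
  nodes <- data.frame(node = vd, delta_ab = ab1 - ab2,
                      category = category, stringsAsFactors = FALSE)

  el <- as_edgelist(g)
  w <- if ("weight" %in% edge_attr_names(g)) E(g)$weight else
    rep(1, ecount(g))
  in1 <- el[, 1] %in% v1 & el[, 2] %in% v1
  in2 <- el[, 1] %in% v2 & el[, 2] %in% v2
  edges <- data.frame(resource = el[, 1], consumer = el[, 2],
                      delta_w = w * in1 - w * in2,
                      stringsAsFactors = FALSE)

  V(g)$delta_ab <- nodes$delta_ab
  V(g)$category <- nodes$category
  if (ecount(g) > 0) E(g)$delta_w <- edges$delta_w

  structure(list(graph = g, nodes = nodes, edges = edges,
                 networks = c(name1, name2)),
            class = "diff_network")
}

#' @export
print.diff_network <- function(x, ...) {
  cat("difference network ", x$networks[1], " - ", x$networks[2], ": ",
      nrow(x$nodes), " nodes (", sum(x$nodes$category == "both"),
      " shared), ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Structural metrics of every network
#'
#' Mean and max trophic level over present nodes, and the mean directed
#' shortest-path length. Unreachable ordered pairs are excluded from the
#' mean path (the natural convention for local webs, which are often
#' disconnected); a single-node network reports `NA`.
#'
#' @param metanet a `metanetwork` after [compute_TL()]
#' @return `data.frame(network, resolution, mean_TL, max_TL,
#'   mean_shortest_path)`, covering the metaweb and every local network at
#'   the finest and every appended resolution.
#' @export
compute_metrics <- function(metanet) {
  stopifnot(inherits(metanet, "metanetwork"))
  res_list <- c(finest_resolution(metanet), names(metanet$aggregated))
  do.call(rbind, lapply(res_list, function(res) {
    do.call(rbind, lapply(network_names(metanet), function(nm) {
      g <- get_network(metanet, nm, res)
      tl <- V(g)$TL
      if (is.null(tl)) stop("trophic levels missing; run compute_TL()")
      msp <- suppressWarnings(
        mean_distance(g, directed = TRUE, unconnected = TRUE,
                      weights = NA)
      )
      data.frame(network = nm, resolution = res,
                 mean_TL = mean(tl), max_TL = max(tl),
                 mean_shortest_path = if (is.finite(msp)) msp else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }))
}

#' Hill-number node diversity
#'
#' The effective number of nodes of order `q`:
#' \eqn{(\sum_k p_k^q)^{1/(1-q)}} for \eqn{q \neq 1} and
#' \eqn{\exp(-\sum_k p_k \ln p_k)} at \eqn{q = 1}. `q = 0` is richness,
#' `q = 1` exponential Shannon, `q = 2` inverse Simpson. The abundance
#' vector is renormalised internally.
#'
#' @param p non-negative abundance vector with a positive sum
#' @param q viewpoint parameter, `q >= 0`
#' @return the diversity (>= 1 for a non-empty vector)
#' @export
node_diversity <- function(p, q = 1) {
  stopifnot(q >= 0)
  p <- as.numeric(p)
  if (any(!is.finite(p)) || any(p < 0) || sum(p) <= 0) {
    stop("abundances must be non-negative with a positive sum")
  }
  hill(p[p > 0] / sum(p[p > 0]), q)
}

hill <- function(p, q) {
  if (q == 1) exp(-sum(p * log(p))) else sum(p^q)^(1 / (1 - q))
}

#' Hill-number link diversity
#'
#' Diversity of order `q` of the normalised link distribution
#' \eqn{L_{kl} = \pi_{kl} p_k p_l / \sum \pi_{k'l'} p_{k'} p_{l'}} over the
#' edges of the graph. Measures the effective number of trophic links.
#'
#' @param graph an `igraph` graph; edge attribute `weight` is \eqn{\pi} (1
#'   where absent)
#' @param p named node abundances (default the `ab` vertex attribute;
#'   uniform when the graph carries none)
#' @param q viewpoint parameter
#' @return the link diversity
#' @export
link_diversity <- function(graph, p = NULL, q = 1) {
  stopifnot(inherits(graph, "igraph"), q >= 0)
  if (is.null(p)) p <- V(graph)$ab
  if (is.null(p)) p <- rep(1 / vcount(graph), vcount(graph))
  if (is.null(names(p))) names(p) <- V(graph)$name
  el <- as_edgelist(graph)
  if (nrow(el) == 0) stop("graph has no edges")
  w <- if ("weight" %in% edge_attr_names(graph)) E(graph)$weight else
    rep(1, ecount(graph))
  Lkl <- w * p[el[, 1]] * p[el[, 2]]
  if (sum(Lkl) <= 0) stop("no link with positive weight between ",
                          "positive-abundance nodes")
  hill(Lkl[Lkl > 0] / sum(Lkl), q)
}

#' Node and link diversities of every network
#'
#' Applies [node_diversity()] and [link_diversity()] to the metaweb (under
#' uniform abundances) and every local network, at the requested resolution.
#'
#' @param metanet a `metanetwork`
#' @param q viewpoint parameter
#' @param resolution resolution name (default finest; coarser resolutions
#'   require [append_agg_nets()])
#' @return `data.frame(network, resolution, q, node_diversity,
#'   link_diversity)`
#' @export
compute_div <- function(metanet, q = 1, resolution = NULL) {
  stopifnot(inherits(metanet, "metanetwork"))
  res <- if (is.null(resolution)) finest_resolution(metanet) else resolution
  do.call(rbind, lapply(network_names(metanet), function(nm) {
    g <- get_network(metanet, nm, res)
    p <- V(g)$ab
    if (is.null(p)) p <- rep(1 / vcount(g), vcount(g))
    ld <- tryCatch(link_diversity(g, stats::setNames(p, V(g)$name), q),
                   error = function(e) NA_real_)
    data.frame(network = nm, resolution = res, q = q,
               node_diversity = node_diversity(p, q),
               link_diversity = ld, stringsAsFactors = FALSE)
  }))
}

# Pairwise beta-diversity dissimilarity of two distributions (equal network
# weights w = 1/2): D_beta = D_gamma / D_alpha in [1, 2], mapped onto [0, 1]
# by ln(D_beta)/ln 2 at q = 1 and (D_beta^(1-q) - 1)/(2^(1-q) - 1)
# otherwise.
pairwise_dissimilarity <- function(p1, p2, q) {
  p1 <- p1 / sum(p1)
  p2 <- p2 / sum(p2)
  mix <- (p1 + p2) / 2
  mix <- mix[mix > 0]
  if (q == 1) {
    ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
    d_gamma <- exp(-sum(mix * log(mix)))
    d_alpha <- exp((ent(p1) + ent(p2)) / 2)
    log(d_gamma / d_alpha) / log(2)
  } else {
    d_gamma <- sum(mix^q)^(1 / (1 - q))
    d_alpha <- 0.5 * sum(c((p1[p1 > 0] / 2)^q,
                           (p2[p2 > 0] / 2)^q))^(1 / (1 - q))
    d_beta <- d_gamma / d_alpha
    (d_beta^(1 - q) - 1) / (2^(1 - q) - 1)
  }
}

#' Pairwise network dissimilarities
#'
#' Beta-diversity dissimilarity between every pair of local networks, on
#' node abundance distributions and on link distributions, at the requested
#' resolution. With two equally weighted networks the Hill decomposition
#' gives \eqn{D_\beta = D_\gamma / D_\alpha \in [1, 2]}, normalised onto
#' \eqn{[0, 1]} (at `q = 1`, \eqn{\ln D_\beta / \ln 2}; otherwise
#' \eqn{(D_\beta^{1-q} - 1)/(2^{1-q} - 1)}). Identical networks score 0,
#' fully distinct ones 1. The dissimilarity is not guaranteed to satisfy
#' the triangle inequality.
#'
#' @param metanet a `metanetwork` with at least two local networks
#' @param q viewpoint parameter
#' @param resolution resolution name (default finest)
#' @return list with symmetric zero-diagonal matrices `nodes` and `links`
#'   and the scalar `q`.
#' @export
compute_dis <- function(metanet, q = 1, resolution = NULL) {
  stopifnot(inherits(metanet, "metanetwork"))
  nets <- names(metanet$locals)
  if (length(nets) < 2) stop("need at least two local networks")
  res <- if (is.null(resolution)) finest_resolution(metanet) else resolution

  meta <- get_network(metanet, "metaweb", res)
  all_nodes <- V(meta)$name
  el_meta <- as_edgelist(meta)
  edge_ids <- paste(el_meta[, 1], el_meta[, 2], sep = "->")

  node_p <- sapply(nets, function(nm) {
    g <- get_network(metanet, nm, res)
    p <- stats::setNames(V(g)$ab, V(g)$name)
    ifelse(all_nodes %in% names(p), p[all_nodes], 0)
  })
  link_p <- sapply(nets, function(nm) {
    g <- get_network(metanet, nm, res)
    p <- stats::setNames(V(g)$ab, V(g)$name)
    el <- as_edgelist(g)
    w <- if ("weight" %in% edge_attr_names(g)) E(g)$weight else
      rep(1, ecount(g))
    lp <- stats::setNames(w * p[el[, 1]] * p[el[, 2]],
                          paste(el[, 1], el[, 2], sep = "->"))
    ifelse(edge_ids %in% names(lp), lp[edge_ids], 0)
  })

  n <- length(nets)
  dn <- dl <- matrix(0, n, n, dimnames = list(nets, nets))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dn[i, j] <- dn[j, i] <-
        pairwise_dissimilarity(node_p[, i], node_p[, j], q)
      dl[i, j] <- dl[j, i] <- if (sum(link_p[, i]) > 0 &&
                                  sum(link_p[, j]) > 0) {
        pairwise_dissimilarity(link_p[, i], link_p[, j], q)
      } else NA_real_
    }
  }
  list(nodes = dn, links = dl, q = q)
}
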