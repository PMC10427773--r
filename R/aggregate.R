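#' Aggregate a network over a node partition
#'
#' Lumps the nodes of a (meta)web into groups and derives group-level
#' abundances and interaction probabilities. Group abundance is the summed
#' relative abundance of its members, and the group-to-group interaction
#' probability is the abundance-weighted mean of the member-to-member
#' probabilities:
#' \deqn{\tilde p_q = \sum_{k \in C_q} p_k, \qquad
#'   \tilde\pi_{ql} = \frac{\sum_{k \in C_q, k' \in C_l} \pi_{kk'} p_k p_{k'}}
#'   {\sum_{k \in C_q} p_k \; \sum_{k' \in C_l} p_{k'}}.}
#' An aggregated edge \eqn{q \to l} exists iff \eqn{\tilde\pi_{ql} > 0};
#' self-loops (within-group feeding) are kept. Groups whose members all have
#' zero abundance are absent from the result.
#'
#' @param graph an `igraph` directed graph; edge attribute `weight` is the
#'   interaction probability \eqn{\pi} (1 where absent).
#' @param abundances named non-negative vector of node abundances \eqn{p_k};
#'   defaults to the graph's `ab` vertex attribute, or to uniform
#'   \eqn{1/n} when the graph carries no abundances (reported by a message).
#' @param partition named character vector mapping every node name of
#'   `graph` to its group label.
#' @return an `igraph` graph over the groups with vertex attribute `ab`
#'   (\eqn{\tilde p_q}) and edge attribute `weight` (\eqn{\tilde\pi_{ql}}).
#' @examples
#' g <- igraph::graph_from_literal(n1 -+ n3, n2 -+ n3)
#' part <- c(n1 = "A", n2 = "A", n3 = "B")
#' agg <- aggregate_network(g, c(n1 = 0.25, n2 = 0.25, n3 = 0.5), part)
#' igraph::E(agg)$weight  # 1
#' @export
aggregate_network <- function(graph, abundances = NULL, partition) {
  stopifnot(inherits(graph, "igraph"))
  nodes <- V(graph)$name
  if (is.null(abundances)) abundances <- V(graph)$ab
  if (is.null(abundances)) {
    message("no abundances on graph; aggregating with uniform p = 1/n")
    abundances <- stats::setNames(rep(1 / length(nodes), length(nodes)),
                                  nodes)
  }
  if (is.null(names(abundances))) names(abundances) <- nodes
  miss <- setdiff(nodes, names(partition))
  if (length(miss) > 0) {
    stop("partition does not cover node(s): ", paste(miss, collapse = ", "))
  }
  p <- abundances[nodes]
  if (any(!is.finite(p)) || any(p < 0)) stop("abundances must be >= 0")

  grp <- as.character(partition[nodes])
  groups <- unique(grp)
  M <- outer(grp, groups, "==") * 1           # n x Q indicator
  pt <- as.vector(crossprod(M, p))            # group abundances
  names(pt) <- groups

  Pi <- as_adjacency_matrix(graph, attr = edge_weight_attr(graph),
                            sparse = FALSE)
  num <- crossprod(M, (Pi * outer(p, p)) %*% M)
  den <- outer(pt, pt)
  Pit <- matrix(0, length(groups), length(groups),
                dimnames = list(groups, groups))
  ok <- den > 0
  Pit[ok] <- num[ok] / den[ok]

  keep <- pt > 0
  Pit <- Pit[keep, keep, drop = FALSE]
  agg <- graph_from_adjacency_matrix(Pit, mode = "directed",
                                     weighted = TRUE, diag = TRUE)
  V(agg)$ab <- unname(pt[keep])
  if (!is.null(graph$name)) agg$name <- graph$name
  agg
}

# name of the weight attribute to use as pi, or NULL for binary (pi = 1)
edge_weight_attr <- function(graph) {
  if ("weight" %in% edge_attr_names(graph)) "weight" else NULL
}

#' Append aggregated networks at every coarser resolution
#'
#' For each coarser column of the trophic table, computes the aggregated
#' metaweb and every aggregated local network with [aggregate_network()] and
#' stores them in `$aggregated`. The metaweb carries no abundances, so its
#' aggregation uses uniform node weights \eqn{p_k = 1/n}. Repeated calls
#' recompute and overwrite, so the operation is idempotent.
#'
#' @param metanet a `metanetwork` whose trophic table has at least two
#'   resolutions
#' @return the `metanetwork`, with `$aggregated[[resolution]]` holding
#'   `metaweb` and `locals` for every coarser resolution.
#' @export
append_agg_nets <- function(metanet) {
  stopifnot(inherits(metanet, "metanetwork"))
  tt <- metanet$trophic_table
  if (is.null(tt) || ncol(tt) < 2) {
    stop("append_agg_nets() needs a trophic table with at least two ",
         "resolutions")
  }
  for (r in 2:ncol(tt)) {
    res <- colnames(tt)[r]
    part <- stats::setNames(tt[[r]], tt[[1]])
    agg_meta <- suppressMessages(
      aggregate_network(metanet$metaweb, partition = part)
    )
    agg_locals <- lapply(metanet$locals, function(loc) {
      aggregate_network(loc, partition = part)
    })
    metanet$aggregated[[res]] <- list(metaweb = agg_meta,
                                      locals = agg_locals)
  }
  metanet
}

#' Containment tree of a trophic table
#'
#' Builds the forest linking each group to its parent group at the next
#' coarser resolution, validating on the way that the partitions are nested
#' (each group maps to exactly one parent). Vertices are labelled
#' `<resolution>:<group>`; edges point parent to child.
#'
#' @param trophic_table a trophic-table `data.frame` (finest column first)
#' @return an `igraph` forest with vertex attributes `resolution` and
#'   `label`; a single-resolution table yields a forest of isolated leaves.
#' @export
trophic_table_tree <- function(trophic_table) {
  tt <- as.data.frame(trophic_table, stringsAsFactors = FALSE)
  tt[] <- lapply(tt, as.character)
  res_names <- colnames(tt)
  vid <- function(r, g) paste0(res_names[r], ":", g)
  verts <- data.frame(name = character(0), resolution = character(0),
                      label = character(0), stringsAsFactors = FALSE)
  for (r in seq_along(res_names)) {
    gr <- unique(tt[[r]])
    verts <- rbind(verts, data.frame(name = vid(r, gr),
                                     resolution = res_names[r],
                                     label = gr, stringsAsFactors = FALSE))
  }
  edges <- NULL
  if (ncol(tt) >= 2) {
    for (r in seq_len(ncol(tt) - 1)) {
      map <- unique(tt[, c(r, r + 1)])
      dup <- unique(map[[1]][duplicated(map[[1]])])
      if (length(dup) > 0) {
        stop("partitions are not nested: group(s) ",
             paste(dup, collapse = ", "), " at resolution '", res_names[r],
             "' map to several groups at resolution '", res_names[r + 1],
             "'")
      }
      edges <- rbind(edges, data.frame(from = vid(r + 1, map[[2]]),
                                       to = vid(r, map[[1]]),
                                       stringsAsFactors = FALSE))
    }
  }
  if (is.null(edges)) {
    tree <- make_empty_graph(n = 0, directed = TRUE) +
      vertices(verts$name, resolution = verts$resolution,
               label = verts$label)
  } else {
    tree <- graph_from_data_frame(edges, directed = TRUE, vertices = verts)
  }
  tree
}
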