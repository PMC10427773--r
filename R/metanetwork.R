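#' trophicspace: trophic metanetworks, Laplacian trophic levels and
#' diffusion-kernel layouts
#'
#' A metanetwork is a regional metaweb -- the directed, connected network of
#' all potential trophic interactions in a species pool -- together with the
#' local food webs induced by site- or time-specific abundances. The package
#' builds such objects, computes trophic levels from the graph Laplacian,
#' embeds webs in two dimensions with the x-axis pinned to trophic level
#' ("TL-tsne" and "group-TL-tsne" layouts), aggregates networks over nested
#' trophic groupings, and compares local webs through difference networks,
#' structural metrics and Hill-number diversity indices.
#'
#' @keywords internal
#' @aliases trophicspace-package
#' @import igraph
"_PACKAGE"

# Edge orientation convention used throughout: edges point resource ->
# consumer (direction of energy flow), so basal species have in-degree 0 and
# solve to the minimal trophic level.

#' Build a trophic metanetwork
#'
#' Assembles a `metanetwork` object from a metaweb, an optional abundance
#' table and an optional trophic table, and derives the local networks: each
#' abundance row induces the vertex-induced subgraph of the metaweb restricted
#' to the species with strictly positive abundance.
#'
#' The metaweb must be directed, weakly connected, and free of self-loops and
#' duplicate edges; edge weights (interaction probabilities or diet
#' fractions), when present, must be non-negative. Local networks, by
#' contrast, may be disconnected -- a routine consequence of sampling.
#'
#' Abundance rows are rescaled to sum to one on ingestion (the aggregation
#' and diversity machinery work on relative abundances); the raw row totals
#' are kept in `$abundance_totals`. Node-name matching between the metaweb,
#' the abundance columns and the trophic table is exact and case-sensitive.
#'
#' @param metaweb the metaweb, as an `igraph` directed graph, a square
#'   adjacency `matrix` with dimnames, or an edge-list `data.frame` with
#'   columns `resource, consumer[, weight]`.
#' @param abundances optional community matrix (`matrix` or `data.frame`),
#'   rows = local networks (rownames = network names), columns = metaweb node
#'   names, entries = non-negative abundances.
#' @param trophic_table optional `data.frame`; first column the finest node
#'   names (one row per metaweb node), each further column a coarser group
#'   label, ordered fine to coarse. Column names name the resolutions.
#' @return an object of class `metanetwork`: a list with elements `metaweb`
#'   (igraph), `abundances` (row-normalised matrix or NULL),
#'   `abundance_totals`, `trophic_table`, `locals` (named list of igraph),
#'   `aggregated` (filled by [append_agg_nets()]) and `layouts` (filled by
#'   [attach_layout()]).
#' @examples
#' g <- make_pyramid(c(2, 1))
#' P <- matrix(c(0.5, 0.5, 0, 0.2, 0.3, 0.5), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("s1", "s2"), igraph::V(g)$name))
#' mn <- build_metanet(g, P)
#' mn
#' @export
build_metanet <- function(metaweb, abundances = NULL, trophic_table = NULL) {
  g <- as_metaweb_graph(metaweb)
  validate_metaweb(g)

  P <- NULL
  totals <- NULL
  locals <- list()
  if (!is.null(abundances)) {
    P <- as.matrix(abundances)
    if (is.null(colnames(P))) {
      stop("abundance table must have column names (metaweb node names)")
    }
    if (is.null(rownames(P))) {
      rownames(P) <- paste0("net_", seq_len(nrow(P)))
    }
    unknown <- setdiff(colnames(P), V(g)$name)
    if (length(unknown) > 0) {
      stop("abundance table names unknown metaweb node(s): ",
           paste(unknown, collapse = ", "))
    }
    if (any(!is.finite(P)) || any(P < 0)) {
      bad <- rownames(P)[apply(P, 1, function(r) any(!is.finite(r) | r < 0))]
      stop("negative or non-finite abundance in row(s): ",
           paste(bad, collapse = ", "))
    }
    totals <- rowSums(P)
    if (any(totals <= 0)) {
      stop("abundance row(s) with no positive entry: ",
           paste(rownames(P)[totals <= 0], collapse = ", "))
    }
    P <- sweep(P, 1, totals, "/")
    locals <- lapply(rownames(P), function(nm) {
      local_from_row(g, P[nm, ], nm)
    })
    names(locals) <- rownames(P)
  }

  tt <- NULL
  if (!is.null(trophic_table)) {
    tt <- as.data.frame(trophic_table, stringsAsFactors = FALSE)
    tt[] <- lapply(tt, as.character)
    validate_trophic_table(tt, V(g)$name)
  }

  structure(list(
    metaweb = g,
    abundances = P,
    abundance_totals = totals,
    trophic_table = tt,
    locals = locals,
    aggregated = list(),
    layouts = list()
  ), class = "metanetwork")
}

# Coerce the accepted metaweb representations to a directed igraph.
as_metaweb_graph <- function(metaweb) {
  if (inherits(metaweb, "igraph")) {
    g <- metaweb
    if (is.null(V(g)$name)) V(g)$name <- as.character(seq_len(vcount(g)))
  } else if (is.matrix(metaweb)) {
    if (is.null(rownames(metaweb))) {
      rownames(metaweb) <- colnames(metaweb) <-
        paste0("n", seq_len(nrow(metaweb)))
    }
    g <- graph_from_adjacency_matrix(metaweb, mode = "directed",
                                     weighted = TRUE)
  } else if (is.data.frame(metaweb)) {
    g <- graph_from_edge_df(metaweb)
  } else {
    stop("metaweb must be an igraph, an adjacency matrix or an edge-list ",
         "data.frame")
  }
  if (!is_directed(g)) stop("metaweb must be a directed graph")
  g
}

graph_from_edge_df <- function(df, reverse = FALSE) {
  if (ncol(df) < 2) stop("edge list needs at least two columns")
  el <- data.frame(from = as.character(df[[1]]), to = as.character(df[[2]]),
                   weight = if (ncol(df) >= 3) as.numeric(df[[3]]) else 1,
                   stringsAsFactors = FALSE)
  if (reverse) el[c("from", "to")] <- el[c("to", "from")]
  key <- paste(el$from, el$to, sep = "\r")
  if (anyDuplicated(key)) {
    warning("duplicate edges collapsed; weights summed")
    el <- stats::aggregate(weight ~ from + to, el, sum)
  }
  graph_from_data_frame(el, directed = TRUE)
}

validate_metaweb <- function(g) {
  if (vcount(g) == 0) stop("metaweb is empty")
  if (any(which_loop(g))) {
    loops <- unique(tail_of(g, E(g)[which_loop(g)])$name)
    stop("metaweb has self-loop(s) at: ", paste(loops, collapse = ", "))
  }
  if (any(which_multiple(g))) stop("metaweb has duplicate edges")
  w <- E(g)$weight
  if (!is.null(w) && (any(!is.finite(w)) || any(w < 0))) {
    stop("metaweb edge weights must be finite and non-negative")
  }
  comp <- components(g, mode = "weak")
  if (comp$no > 1) {
    members <- split(V(g)$name, comp$membership)
    stop("metaweb must be weakly connected; found ", comp$no,
         " components: ",
         paste(vapply(members, function(m) paste0("{", paste(m, collapse = ","), "}"),
                      character(1)), collapse = " "))
  }
  invisible(g)
}

local_from_row <- function(g, p, nm) {
  present <- names(p)[p > 0]
  sub <- induced_subgraph(g, vids = present)
  V(sub)$ab <- unname(p[V(sub)$name])
  sub$name <- nm
  sub
}

validate_trophic_table <- function(tt, node_names) {
  if (ncol(tt) < 1) stop("trophic table needs at least one column")
  finest <- tt[[1]]
  if (anyDuplicated(finest)) {
    stop("trophic table repeats finest node(s): ",
         paste(unique(finest[duplicated(finest)]), collapse = ", "))
  }
  unknown <- setdiff(finest, node_names)
  if (length(unknown) > 0) {
    stop("trophic table names unknown metaweb node(s): ",
         paste(unknown, collapse = ", "))
  }
  missing <- setdiff(node_names, finest)
  if (length(missing) > 0) {
    stop("trophic table misses metaweb node(s): ",
         paste(missing, collapse = ", "))
  }
  # nestedness across consecutive resolutions
  if (ncol(tt) >= 2) {
    for (r in seq_len(ncol(tt) - 1)) {
      map <- unique(tt[, c(r, r + 1)])
      dup <- map[[1]][duplicated(map[[1]])]
      if (length(dup) > 0) {
        stop("partitions are not nested: group(s) ",
             paste(unique(dup), collapse = ", "), " at resolution '",
             colnames(tt)[r], "' map to several groups at resolution '",
             colnames(tt)[r + 1], "'")
      }
    }
  }
  invisible(tt)
}

#' Resolutions available in a metanetwork
#'
#' @param metanet a `metanetwork`
#' @return character vector of resolution names, finest first; the finest
#'   resolution is the first trophic-table column (or `"species"` when no
#'   trophic table is present).
#' @export
resolutions <- function(metanet) {
  stopifnot(inherits(metanet, "metanetwork"))
  if (is.null(metanet$trophic_table)) "species" else
    colnames(metanet$trophic_table)
}

finest_resolution <- function(metanet) resolutions(metanet)[1]

#' Names of the networks held by a metanetwork
#'
#' @param metanet a `metanetwork`
#' @return character vector: `"metaweb"` followed by the local network names.
#' @export
network_names <- function(metanet) {
  stopifnot(inherits(metanet, "metanetwork"))
  c("metaweb", names(metanet$locals))
}

#' Extract one network from a metanetwork
#'
#' @param metanet a `metanetwork`
#' @param network `"metaweb"` or a local network name
#' @param resolution a resolution name; default the finest
#' @return an `igraph` graph (with `ab` and `TL` vertex attributes when
#'   computed)
#' @export
get_network <- function(metanet, network = "metaweb", resolution = NULL) {
  stopifnot(inherits(metanet, "metanetwork"))
  if (is.null(resolution) || identical(resolution, finest_resolution(metanet))) {
    if (identical(network, "metaweb")) return(metanet$metaweb)
    if (!network %in% names(metanet$locals)) {
      stop("unknown network '", network, "'; available: ",
           paste(network_names(metanet), collapse = ", "))
    }
    return(metanet$locals[[network]])
  }
  if (!resolution %in% names(metanet$aggregated)) {
    stop("resolution '", resolution, "' not appended; run append_agg_nets()")
  }
  agg <- metanet$aggregated[[resolution]]
  if (identical(network, "metaweb")) return(agg$metaweb)
  if (!network %in% names(agg$locals)) {
    stop("unknown network '", network, "' at resolution '", resolution, "'")
  }
  agg$locals[[network]]
}

#' @export
print.metanetwork <- function(x, ...) {
  cat("metanetwork\n")
  cat("  metaweb: ", vcount(x$metaweb), " nodes, ", ecount(x$metaweb),
      " edges\n", sep = "")
  cat("  local networks: ", length(x$locals),
      if (length(x$locals) > 0)
        paste0(" (", paste(names(x$locals), collapse = ", "), ")") else "",
      "\n", sep = "")
  if (!is.null(x$trophic_table)) {
    cat("  resolutions: ", paste(resolutions(x), collapse = " > "), "\n",
        sep = "")
  }
  if (length(x$aggregated) > 0) {
    cat("  aggregated at: ", paste(names(x$aggregated), collapse = ", "),
        "\n", sep = "")
  }
  if (length(x$layouts) > 0) {
    cat("  layouts attached: ", length(x$layouts), "\n", sep = "")
  }
  invisible(x)
}
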