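#' Read a metaweb from an edge list or GraphML file
#'
#' Edge-list CSVs are comma-separated UTF-8 with a mandatory header
#' `resource,consumer[,weight]`. GraphML files must describe a directed
#' graph; a `weight` edge attribute is honoured when present. Files encoded
#' predator-to-prey can be ingested with `orientation = "consumer-resource"`,
#' which reverses every edge so that the in-memory graph always points
#' resource to consumer. Duplicate edge rows are collapsed by summing their
#' weights, with a warning.
#'
#' @param path file path
#' @param format `"csv"` (default, or guessed from the extension) or
#'   `"graphml"`
#' @param orientation `"resource-consumer"` (default) or
#'   `"consumer-resource"`
#' @return a directed `igraph` metaweb (not yet validated for connectivity;
#'   [build_metanet()] does that)
#' @export
read_metaweb <- function(path,
                         format = c("csv", "graphml"),
                         orientation = c("resource-consumer",
                                         "consumer-resource")) {
  if (missing(format) && grepl("\\.graphml$", path, ignore.case = TRUE)) {
    format <- "graphml"
  }
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  reverse <- orientation == "consumer-resource"
  if (format == "graphml") {
    g <- read_graph(path, format = "graphml")
    if (!is_directed(g)) stop("GraphML metaweb must be directed")
    if (reverse) g <- reverse_edges(g)
    return(g)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  need <- c("resource", "consumer")
  if (!all(need %in% colnames(df))) {
    stop("edge-list CSV must have header columns 'resource,consumer",
         "[,weight]'; got: ", paste(colnames(df), collapse = ", "))
  }
  bad <- which(is.na(df$resource) | is.na(df$consumer) |
                 df$resource == "" | df$consumer == "")
  if (length(bad) > 0) {
    stop("malformed edge row(s) at line(s) ",
         paste(bad + 1, collapse = ", "), " of ", path)
  }
  cols <- c("resource", "consumer",
            if ("weight" %in% colnames(df)) "weight")
  graph_from_edge_df(df[cols], reverse = reverse)
}

#' Write a metaweb as an edge-list CSV
#'
#' Columns `resource,consumer,weight` (weight 1 when the graph is
#' unweighted); round-trips losslessly through [read_metaweb()].
#'
#' @param graph a directed `igraph`
#' @param path output file path
#' @export
write_metaweb <- function(graph, path) {
  el <- as_edgelist(graph)
  w <- if ("weight" %in% edge_attr_names(graph)) E(graph)$weight else
    rep(1, ecount(graph))
  utils::write.csv(data.frame(resource = el[, 1], consumer = el[, 2],
                              weight = w),
                   path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an abundance table
#'
#' CSV with first column `network` (local network names) and one further
#' column per metaweb node.
#'
#' @param path file path
#' @return numeric matrix, rownames = network names
#' @export
read_abundances <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        fileEncoding = "UTF-8")
  if (colnames(df)[1] != "network") {
    stop("abundance CSV must have 'network' as its first column")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- as.character(df[[1]])
  m
}

#' Write an abundance table
#' @param abundances matrix, rows = networks, columns = node names
#' @param path output file path
#' @export
write_abundances <- function(abundances, path) {
  df <- data.frame(network = rownames(abundances), abundances,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a trophic table
#'
#' CSV whose first column holds the finest node names and each further
#' column one coarser resolution, ordered fine to coarse; the header row
#' names the resolutions.
#'
#' @param path file path
#' @return `data.frame` of characters
#' @export
read_trophic_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character", fileEncoding = "UTF-8")
  if (ncol(df) < 1) stop("trophic table CSV is empty")
  df
}

#' Write a trophic table
#' @param trophic_table a trophic-table `data.frame`
#' @param path output file path
#' @export
write_trophic_table <- function(trophic_table, path) {
  utils::write.csv(trophic_table, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a Moran beta-selection profile
#'
#' Columns `beta,moran_index`.
#'
#' @param profile a `moran_profile` from [select_beta()]
#' @param path output file path
#' @export
write_moran_profile <- function(profile, path) {
  stopifnot(inherits(profile, "moran_profile"))
  utils::write.csv(profile$profile, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
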