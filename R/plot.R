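#' Static plot of a network with an attached layout
#'
#' Scatter of the nodes at their stored layout coordinates (x = trophic
#' level, y = embedded coordinate), node size proportional to abundance,
#' node colour by trophic-table group, edge width proportional to
#' interaction weight. Purely a view: never alters stored data.
#'
#' @param metanet a `metanetwork` with the requested layout attached
#' @param network `"metaweb"` or a local network name
#' @param resolution resolution of the layout key (default finest); for a
#'   group-TL-tsne layout pass `"group-TL-tsne@<resolution>"`
#' @param beta beta of the layout key
#' @param colour_by trophic-table column used for node colour (default the
#'   first coarser resolution, if any)
#' @param flip_coords swap the x and y axes (useful to put trophic level on
#'   the vertical axis for large webs)
#' @param legend show legends
#' @param file optional output path (`.png`, `.svg`, `.pdf`); written with
#'   [ggplot2::ggsave()]
#' @param width,height device size in inches when writing to file
#' @return the `ggplot` object, invisibly when written to file
#' @export
plot_metanet <- function(metanet, network = "metaweb", resolution = NULL,
                         beta, colour_by = NULL, flip_coords = FALSE,
                         legend = TRUE, file = NULL, width = 7,
                         height = 5) {
  lay <- get_layout(metanet, network, resolution, beta)
  nodes <- lay$coords
  is_group_key <- !is.null(resolution) &&
    grepl("^group-TL-tsne@", resolution)
  g <- if (is_group_key) get_network(metanet, network, NULL) else
    get_network(metanet, network, resolution)

  ab <- V(g)$ab
  nodes$ab <- if (is.null(ab)) 1 else ab[match(nodes$node, V(g)$name)]
  tt <- metanet$trophic_table
  if (is.null(colour_by) && !is.null(tt) && ncol(tt) >= 2) {
    colour_by <- colnames(tt)[2]
  }
  nodes$group <- if (!is.null(colour_by) && !is.null(tt) &&
                       colour_by %in% colnames(tt)) {
    tt[[colour_by]][match(nodes$node, tt[[1]])]
  } else "all"

  el <- as_edgelist(g)
  edges <- data.frame(
    x = nodes$x[match(el[, 1], nodes$node)],
    y = nodes$y[match(el[, 1], nodes$node)],
    xend = nodes$x[match(el[, 2], nodes$node)],
    yend = nodes$y[match(el[, 2], nodes$node)],
    w = if ("weight" %in% edge_attr_names(g)) E(g)$weight else
      rep(1, ecount(g))
  )
  if (flip_coords) {
    nodes[c("x", "y")] <- nodes[c("y", "x")]
    edges[c("x", "y", "xend", "yend")] <- edges[c("y", "x", "yend", "xend")]
  }

  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = x, y = y, xend = xend, yend = yend,
                   linewidth = w),
      colour = "grey60", alpha = 0.6, show.legend = FALSE) +
    ggplot2::scale_linewidth(range = c(0.2, 1.2)) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = x, y = y, size = ab, colour = group)) +
    ggplot2::scale_size(range = c(2, 8)) +
    ggplot2::labs(
      x = if (flip_coords) "embedded coordinate" else "trophic level",
      y = if (flip_coords) "trophic level" else "embedded coordinate",
      title = paste0(network, " (beta = ", beta, ")")) +
    ggplot2::theme_minimal()
  if (!legend) p <- p + ggplot2::theme(legend.position = "none")
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = width, height = height)
    return(invisible(p))
  }
  p
}

# fixed, documented colour code for difference plots
diff_palette <- c("both" = "grey30",
                  "only-first" = "#1b9e77",
                  "only-second" = "#d95f02")

#' Static plot of a difference network
#'
#' Nodes at supplied coordinates, shaped/coloured by presence category
#' (`both` grey, `only-first` green, `only-second` orange) and sized by
#' |abundance difference|; edges coloured by the sign of the weight
#' difference (blue negative, red positive, grey zero). The legend lists
#' exactly the categories present.
#'
#' @param diff a `diff_network` from [diff_networks()]
#' @param coords `data.frame(node, x, y)` giving node positions, e.g. the
#'   `$coords` of a metaweb layout; defaults to x = trophic level of the
#'   diff graph (requires [compute_TL()] upstream) and y = 0
#' @param file optional output path, as in [plot_metanet()]
#' @param width,height device size in inches
#' @return the `ggplot` object
#' @export
plot_diff <- function(diff, coords = NULL, file = NULL, width = 7,
                      height = 5) {
  stopifnot(inherits(diff, "diff_network"))
  g <- diff$graph
  nodes <- diff$nodes
  if (is.null(coords)) {
    tl <- V(g)$TL
    if (is.null(tl)) stop("no coords supplied and no trophic levels on ",
                          "the difference graph")
    coords <- data.frame(node = V(g)$name, x = tl, y = 0)
  }
  nodes$x <- coords$x[match(nodes$node, coords$node)]
  nodes$y <- coords$y[match(nodes$node, coords$node)]
  if (any(is.na(nodes$x))) {
    stop("coords missing for node(s): ",
         paste(nodes$node[is.na(nodes$x)], collapse = ", "))
  }
  edges <- diff$edges
  edges$x <- nodes$x[match(edges$resource, nodes$node)]
  edges$y <- nodes$y[match(edges$resource, nodes$node)]
  edges$xend <- nodes$x[match(edges$consumer, nodes$node)]
  edges$yend <- nodes$y[match(edges$consumer, nodes$node)]
  edges$sign <- ifelse(edges$delta_w > 0, "gain",
                       ifelse(edges$delta_w < 0, "loss", "unchanged"))

  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = x, y = y, xend = xend, yend = yend,
                   colour = sign),
      alpha = 0.6) +
    ggplot2::scale_colour_manual(
      values = c(gain = "#d73027", loss = "#4575b4",
                 unchanged = "grey70"),
      name = "edge weight") +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = x, y = y, fill = category,
                   size = abs(delta_ab)),
      shape = 21) +
    ggplot2::scale_fill_manual(values = diff_palette,
                               name = "presence") +
    ggplot2::scale_size(range = c(2, 8), name = "|delta abundance|") +
    ggplot2::labs(x = "trophic level", y = "embedded coordinate",
                  title = paste("difference:", diff$networks[1], "-",
                                diff$networks[2])) +
    ggplot2::theme_minimal()
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = width, height = height)
    return(invisible(p))
  }
  p
}
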