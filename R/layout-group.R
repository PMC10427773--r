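#' Configuration of the group-TL-tsne layout
#'
#' @param beta diffusion parameter of the aggregated-network TL-tsne stage
#' @param group_diameter target diameter of each group's node cloud, in
#'   layout coordinate units; a scalar (recycled) or a named vector per
#'   group
#' @param fr_iter iterations of the within-group force-directed placement
#' @param seed RNG seed for both stages
#' @param strict_x re-pin each node's x-coordinate to its own trophic level
#'   after centring (by default the group centre carries the aggregated
#'   trophic level and members spread around it)
#' @param tsne list of extra arguments passed on to [layout_config()] for
#'   the aggregated stage
#' @return object of class `group_layout_config`
#' @export
group_layout_config <- function(beta, group_diameter = 1, fr_iter = 500,
                                seed = 1, strict_x = FALSE, tsne = list()) {
  stopifnot(beta > 0, all(group_diameter > 0), fr_iter >= 1)
  structure(list(beta = beta, group_diameter = group_diameter,
                 fr_iter = fr_iter, seed = as.integer(seed),
                 strict_x = isTRUE(strict_x), tsne = tsne),
            class = "group_layout_config")
}

#' Group-TL-tsne layout for large webs
#'
#' Two-stage layout for networks too large for a direct embedding: (1) a
#' TL-tsne layout of the *aggregated* network at the requested resolution --
#' the expensive stage therefore runs on the Q group nodes only; (2) inside
#' each group, a seeded Fruchterman-Reingold placement of the group's
#' vertex-induced subgraph, centred so the group's node centroid coincides
#' with the group's aggregated coordinate and rescaled so no node lies
#' farther than `group_diameter / 2` from it. Singleton groups sit exactly
#' at their group's coordinate.
#'
#' @param metanet a `metanetwork` with aggregated networks appended and
#'   trophic levels computed at both resolutions
#' @param network `"metaweb"` or a local network name
#' @param resolution the aggregation resolution driving the layout
#' @param config a [group_layout_config()]
#' @return a `tl_layout` over the finest-resolution nodes, with extra
#'   fields `resolution` (the aggregation level used), `tsne_n` (number of
#'   nodes the t-SNE stage embedded) and `group_coords`.
#' @export
group_tl_tsne <- function(metanet, network = "metaweb", resolution,
                          config) {
  stopifnot(inherits(metanet, "metanetwork"),
            inherits(config, "group_layout_config"))
  if (!resolution %in% names(metanet$aggregated)) {
    stop("resolution '", resolution,
         "' not appended; run append_agg_nets() first")
  }
  agg_g <- get_network(metanet, network, resolution)
  fine_g <- get_network(metanet, network, NULL)
  if (is.null(V(agg_g)$TL) || is.null(V(fine_g)$TL)) {
    stop("trophic levels missing; run compute_TL() after append_agg_nets()")
  }

  tsne_args <- c(list(beta = config$beta, seed = config$seed), config$tsne)
  agg_lay <- embed_components(agg_g, do.call(layout_config, tsne_args))
  centers <- agg_lay$coords

  tt <- metanet$trophic_table
  part <- stats::setNames(tt[[resolution]], tt[[1]])
  diam <- config$group_diameter
  if (is.null(names(diam))) {
    diam <- stats::setNames(rep_len(diam, nrow(centers)), centers$node)
  }

  coords <- data.frame(node = V(fine_g)$name, x = NA_real_, y = NA_real_,
                       stringsAsFactors = FALSE)
  for (gi in seq_len(nrow(centers))) {
    grp <- centers$node[gi]
    members <- coords$node[part[coords$node] == grp]
    idx <- match(members, coords$node)
    if (length(members) == 1) {
      coords$x[idx] <- centers$x[gi]
      coords$y[idx] <- centers$y[gi]
      next
    }
    sub <- induced_subgraph(fine_g, members)
    xy <- withr::with_seed(config$seed,
                           layout_with_fr(sub, niter = config$fr_iter,
                                          dim = 2))
    xy <- sweep(xy, 2, colMeans(xy))  # centre on the group coordinate
    maxd <- max(sqrt(rowSums(xy^2)))
    half <- diam[grp] / 2
    if (is.na(half)) half <- 0.5
    if (maxd > 0) xy <- xy * (half / maxd)
    coords$x[idx] <- centers$x[gi] + xy[match(members, V(sub)$name), 1]
    coords$y[idx] <- centers$y[gi] + xy[match(members, V(sub)$name), 2]
  }
  if (config$strict_x) coords$x <- V(fine_g)$TL

  structure(list(
    coords = coords,
    beta = config$beta,
    kl_initial = agg_lay$kl_initial,
    kl_final = agg_lay$kl_final,
    iterations = agg_lay$iterations,
    seed = config$seed,
    resolution = resolution,
    tsne_n = vcount(agg_g),
    group_coords = centers
  ), class = "tl_layout")
}
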