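#' Pyramid food web
#'
#' An idealised, strongly hierarchical trophic network: trophic layers of
#' the given sizes, every node of layer t feeding on (receiving an edge
#' from) every node of layer t - 1. The basal layer has in-degree 0 and the
#' resulting web is always weakly connected. Useful as a reference fixture:
#' its Laplacian trophic levels equal the layer indices.
#'
#' @param layer_sizes integer vector (>= 2 layers), basal layer first, e.g.
#'   `c(4, 3, 2, 1)`
#' @return a directed `igraph` metaweb; nodes are named
#'   `l<layer>_<index>`.
#' @export
make_pyramid <- function(layer_sizes) {
  layer_sizes <- as.integer(layer_sizes)
  stopifnot(length(layer_sizes) >= 2, all(layer_sizes >= 1))
  layers <- lapply(seq_along(layer_sizes), function(t) {
    paste0("l", t, "_", seq_len(layer_sizes[t]))
  })
  el <- do.call(rbind, lapply(seq_len(length(layers) - 1), function(t) {
    expand.grid(from = layers[[t]], to = layers[[t + 1]],
                stringsAsFactors = FALSE)
  }))
  g <- graph_from_data_frame(el, directed = TRUE,
                             vertices = unlist(layers))
  V(g)$layer <- rep(seq_along(layer_sizes), layer_sizes)
  g
}

#' Two-branch (two-channel) food web
#'
#' One basal node feeding two disjoint chains of equal length that rejoin
#' at a single top consumer -- the minimal web with two parallel energetic
#' channels. By symmetry the two branches carry identical trophic levels,
#' and the branch-swapping automorphism permutes the diffusion kernel; the
#' within- versus between-branch kernel contrast grows with the diffusion
#' parameter, which makes this the fixture of choice for channel-separation
#' checks.
#'
#' @param chain_length number of nodes in each branch (>= 1)
#' @return a directed `igraph` with `1 + 2 * chain_length + 1` nodes; branch
#'   membership is in the `branch` vertex attribute (`"A"`, `"B"`, or
#'   `"shared"`).
#' @export
make_two_branch <- function(chain_length) {
  chain_length <- as.integer(chain_length)
  stopifnot(chain_length >= 1)
  a <- paste0("A", seq_len(chain_length))
  b <- paste0("B", seq_len(chain_length))
  chain_el <- function(nodes) {
    if (length(nodes) < 2) NULL else cbind(nodes[-length(nodes)], nodes[-1])
  }
  el <- rbind(cbind("basal", a[1]), chain_el(a), cbind(a[chain_length], "top"),
              cbind("basal", b[1]), chain_el(b), cbind(b[chain_length], "top"))
  g <- graph_from_data_frame(as.data.frame(el, stringsAsFactors = FALSE),
                             directed = TRUE,
                             vertices = c("basal", a, b, "top"))
  V(g)$branch <- c("shared", rep("A", chain_length),
                   rep("B", chain_length), "shared")
  g
}

#' Random metanetwork generator
#'
#' Draws a random metaweb and community matrix for testing and simulation.
#' The metaweb is a random DAG: nodes in a random order, each forward pair
#' linked independently with probability `connectance`, rejection-resampled
#' until weakly connected. Abundance rows are Dirichlet(1) draws with a
#' random subset of nodes masked to zero (at least `min_present` kept).
#' Optionally a nested random trophic table is attached (groups drawn at
#' `n_groups` resolution, then coarsened 3-to-1 per extra level).
#'
#' @param n_nodes metaweb size
#' @param connectance probability of each forward edge
#' @param n_communities number of local networks (abundance rows)
#' @param seed RNG seed; fixed seed gives byte-identical output
#' @param prop_present expected proportion of nodes present in each local
#'   community
#' @param min_present minimum nodes present per community
#' @param n_groups number of groups of the first coarser resolution, or
#'   `NULL` for no trophic table
#' @param n_resolutions number of coarser resolutions (nested)
#' @param max_tries resampling attempts for weak connectivity
#' @return a `metanetwork`
#' @export
make_random_metanetwork <- function(n_nodes = 50, connectance = 0.1,
                                    n_communities = 3, seed = 1,
                                    prop_present = 0.7, min_present = 2,
                                    n_groups = NULL, n_resolutions = 1,
                                    max_tries = 100) {
  stopifnot(n_nodes >= 2, connectance > 0, connectance <= 1,
            n_communities >= 1)
  withr::with_seed(as.integer(seed), {
    nodes <- sprintf("sp%02d", seq_len(n_nodes))
    g <- NULL
    for (try in seq_len(max_tries)) {
      ord <- sample(nodes)
      el <- NULL
      idx <- which(upper.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)
      keep <- stats::runif(nrow(idx)) < connectance
      if (any(keep)) {
        el <- cbind(ord[idx[keep, 1]], ord[idx[keep, 2]])
      }
      if (is.null(el) || nrow(el) == 0) next
      cand <- graph_from_data_frame(
        as.data.frame(el, stringsAsFactors = FALSE),
        directed = TRUE, vertices = nodes)
      if (is_connected(cand, mode = "weak")) { g <- cand; break }
    }
    if (is.null(g)) {
      stop("could not draw a weakly connected metaweb in ", max_tries,
           " tries; raise connectance")
    }
    P <- t(vapply(seq_len(n_communities), function(i) {
      repeat {
        present <- stats::runif(n_nodes) < prop_present
        if (sum(present) >= max(min_present, 1)) break
      }
      p <- stats::rgamma(n_nodes, shape = 1) * present
      p / sum(p)
    }, numeric(n_nodes)))
    dimnames(P) <- list(sprintf("com%02d", seq_len(n_communities)), nodes)

    tt <- NULL
    if (!is.null(n_groups)) {
      stopifnot(n_groups >= 1, n_resolutions >= 1)
      tt <- data.frame(species = nodes, stringsAsFactors = FALSE)
      labels <- sprintf("g1_%02d",
                        sample(seq_len(n_groups), n_nodes, replace = TRUE))
      tt$group_1 <- labels
      if (n_resolutions >= 2) {
        for (r in 2:n_resolutions) {
          prev <- unique(tt[[r]])
          coarse <- stats::setNames(
            sprintf("g%d_%02d", r,
                    ceiling(seq_along(prev) / 3)[sample(length(prev))]),
            prev)
          tt[[paste0("group_", r)]] <- unname(coarse[tt[[r]]])
        }
      }
    }
    build_metanet(g, P, tt)
  })
}
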