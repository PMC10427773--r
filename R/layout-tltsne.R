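#' Diffusion graph kernel
#'
#' \eqn{K = \exp(-\beta L)}, the matrix exponential of the symmetrised-graph
#' Laplacian, computed through the eigendecomposition
#' \eqn{L = U \Lambda U^T}, so \eqn{K = U e^{-\beta\Lambda} U^T}. Entries
#' measure node-pair similarity under a diffusion (heat-flow) process --
#' ecologically, the spread of organic matter along the web's paths. Because
#' \eqn{L} has zero row sums, every row of \eqn{K} sums to 1; as
#' \eqn{\beta \to 0}, \eqn{K \to I}, and as \eqn{\beta \to \infty} all
#' entries of a connected graph approach \eqn{1/n}. Larger \eqn{\beta}
#' raises the similarity of nodes that share paths (an energetic channel)
#' and lowers it across channels.
#'
#' @param graph an `igraph` graph
#' @param beta diffusion parameter, \eqn{\beta > 0} (0 is allowed and gives
#'   the identity)
#' @param weighted use edge-weighted Laplacian (default binary, consistent
#'   with [compute_TL()])
#' @return a symmetric matrix with attribute `beta`
#' @export
diffusion_kernel <- function(graph, beta, weighted = FALSE) {
  stopifnot(is.numeric(beta), length(beta) == 1, beta >= 0)
  L <- laplacian_sym(graph, weighted)
  eig <- eigen(L, symmetric = TRUE)
  K <- eig$vectors %*% (exp(-beta * eig$values) * t(eig$vectors))
  if (any(!is.finite(K))) {
    stop("diffusion kernel overflowed; try a smaller beta")
  }
  K <- (K + t(K)) / 2
  dimnames(K) <- dimnames(L)
  attr(K, "beta") <- beta
  K
}

#' Joint affinities from a diffusion kernel
#'
#' Turns the kernel into the high-dimensional joint similarity matrix of the
#' embedding: off-diagonal entries of \eqn{K}, clipped at 0 and normalised to
#' sum to 1 over all ordered pairs, with a zero diagonal. The kernel itself
#' replaces the usual perplexity-calibrated Gaussian affinities -- it is
#' already symmetric and row-stochastic.
#'
#' @param K a kernel matrix from [diffusion_kernel()]
#' @return symmetric non-negative matrix `P` with zero diagonal summing to 1
#' @export
kernel_to_affinities <- function(K) {
  n <- nrow(K)
  if (is.null(n) || n < 2) stop("need at least 2 nodes to embed")
  P <- unclass(K)
  attr(P, "beta") <- NULL
  diag(P) <- 0
  P[P < 0] <- 0
  s <- sum(P)
  if (s < 1e-10) {
    stop("degenerate affinities: kernel is (numerically) the identity; ",
         "increase beta")
  }
  P / s
}

#' Configuration of the TL-tsne embedding
#'
#' Bundles the diffusion parameter and the gradient-descent hyperparameters.
#' Defaults are the standard t-SNE settings: 1000 iterations, momentum 0.5
#' switching to 0.8 at iteration 250, early exaggeration x4 for the first
#' 100 iterations, y initialised from N(0, 1e-4^2). The learning rate
#' defaults to the size-adaptive `max(2, n / exaggeration)`: food webs are
#' orders of magnitude smaller than the datasets the classic fixed rate of
#' 200 was tuned for, and with the x-axis pinned a large fixed step makes
#' the free coordinate overshoot irrecoverably (Student-t attraction decays
#' with distance). The seed is part of the configuration so layouts are
#' reproducible.
#'
#' @param beta diffusion parameter (> 0)
#' @param max_iter maximum gradient iterations
#' @param learning_rate gradient step size; `NULL` (default) resolves to
#'   `max(2, n / exaggeration)` at embedding time
#' @param momentum length-2 numeric: momentum before and after
#'   `momentum_switch`
#' @param momentum_switch iteration at which momentum switches
#' @param exaggeration early-exaggeration factor on the affinities
#' @param exaggeration_iter number of early-exaggeration iterations
#' @param init_scale sd of the normal initialisation of y
#' @param seed RNG seed (mandatory for reproducibility; defaults to 1)
#' @param tol optional early stopping: when positive, the run stops once the
#'   |change in KL divergence| per iteration falls below `tol`. Checked only
#'   after the momentum switch, because the descent crosses long flat
#'   saddles (the symmetric y = 0 start is a critical point) where the KL is
#'   stationary to machine precision long before the layout has formed. The
#'   default 0 runs all `max_iter` iterations, which at food-web sizes is
#'   cheap and never stops on a saddle.
#' @return an object of class `layout_config`
#' @export
layout_config <- function(beta, max_iter = 1000, learning_rate = NULL,
                          momentum = c(0.5, 0.8), momentum_switch = 250,
                          exaggeration = 4, exaggeration_iter = 100,
                          init_scale = 1e-4, seed = 1, tol = 0) {
  stopifnot(beta > 0, max_iter >= 1,
            is.null(learning_rate) || learning_rate > 0,
            length(momentum) == 2, all(momentum > 0), momentum_switch >= 1,
            exaggeration >= 1, exaggeration_iter >= 0, init_scale > 0,
            is.numeric(seed), tol >= 0)
  structure(list(beta = beta, max_iter = max_iter,
                 learning_rate = learning_rate, momentum = momentum,
                 momentum_switch = momentum_switch,
                 exaggeration = exaggeration,
                 exaggeration_iter = exaggeration_iter,
                 init_scale = init_scale, seed = as.integer(seed),
                 tol = tol),
            class = "layout_config")
}

#' TL-tsne: trophic-level-constrained diffusion-kernel embedding
#'
#' Embeds a connected web in two dimensions. The x-coordinate of every node
#' is pinned to its trophic level throughout; only the y-coordinate is free.
#' High-dimensional similarities come from the diffusion kernel
#' ([kernel_to_affinities()]); low-dimensional similarities are the standard
#' Student-t kernel \eqn{q_{ij} \propto (1 + \|y_i - y_j\|^2)^{-1}} on the
#' (x, y) positions. Gradient descent with momentum minimises the
#' Kullback-Leibler divergence KL(P || Q), moving y only.
#'
#' Because affinities factor over connected components, disconnected graphs
#' must be embedded one component at a time (as [attach_layout()] does).
#'
#' @param graph a weakly connected `igraph` graph with >= 2 nodes
#' @param trophic_levels named vector of trophic levels for the nodes of
#'   `graph` (defaults to the `TL` vertex attribute)
#' @param config a [layout_config()]
#' @param weighted passed to [diffusion_kernel()]
#' @return an object of class `tl_layout`: list with `coords`
#'   (`data.frame(node, x, y)`), `beta`, `kl_initial`, `kl_final`,
#'   `iterations`, `seed`.
#' @export
tl_tsne <- function(graph, trophic_levels = NULL, config, weighted = FALSE) {
  stopifnot(inherits(config, "layout_config"))
  n <- vcount(graph)
  if (n < 2) stop("need at least 2 nodes to embed")
  if (is.null(trophic_levels)) trophic_levels <- V(graph)$TL
  if (is.null(trophic_levels)) {
    stop("no trophic levels supplied; run compute_TL() first")
  }
  if (!is.null(names(trophic_levels))) {
    trophic_levels <- trophic_levels[V(graph)$name]
  }
  stopifnot(length(trophic_levels) == n, all(is.finite(trophic_levels)))

  P <- kernel_to_affinities(diffusion_kernel(graph, config$beta, weighted))
  x <- as.numeric(trophic_levels)
  lr <- if (is.null(config$learning_rate)) {
    max(2, n / config$exaggeration)
  } else config$learning_rate
  y <- withr::with_seed(config$seed, stats::rnorm(n, 0, config$init_scale))

  kl_div <- function(y) {
    Q <- student_q(x, y)
    pos <- P > 0
    sum(P[pos] * log(P[pos] / Q[pos]))
  }
  kl_initial <- kl_div(y)

  if (n == 2) {
    # pairwise normalisation forces P = Q = {1/2, 1/2}: the KL is
    # identically 0 and its gradient vanishes, so the seeded (centred)
    # initialisation is already the layout
    return(structure(list(
      coords = data.frame(node = V(graph)$name, x = x, y = y - mean(y),
                          stringsAsFactors = FALSE),
      beta = config$beta, kl_initial = kl_initial, kl_final = kl_initial,
      iterations = 0L, seed = config$seed), class = "tl_layout"))
  }

  inc <- numeric(n)
  kl_prev <- kl_initial
  iters <- 0
  for (i in seq_len(config$max_iter)) {
    iters <- i
    exag <- i <= config$exaggeration_iter
    Pe <- if (exag) P * config$exaggeration else P
    D2 <- sq_dist(x, y)
    W <- 1 / (1 + D2)
    diag(W) <- 0
    Q <- W / sum(W)
    M <- (Pe - Q) * W
    grad_y <- 4 * (rowSums(M) * y - as.vector(M %*% y))
    mom <- if (i < config$momentum_switch) config$momentum[1] else
      config$momentum[2]
    inc <- mom * inc - lr * grad_y
    y <- y + inc
    y <- y - mean(y)
    if (config$tol > 0 && !exag && i > config$momentum_switch) {
      kl_cur <- kl_div(y)
      if (abs(kl_prev - kl_cur) < config$tol) {
        kl_prev <- kl_cur
        break
      }
      kl_prev <- kl_cur
    }
  }
  kl_final <- kl_div(y)

  structure(list(
    coords = data.frame(node = V(graph)$name, x = x, y = y,
                        stringsAsFactors = FALSE),
    beta = config$beta,
    kl_initial = kl_initial,
    kl_final = kl_final,
    iterations = iters,
    seed = config$seed
  ), class = "tl_layout")
}

sq_dist <- function(x, y) {
  outer(x, x, "-")^2 + outer(y, y, "-")^2
}

student_q <- function(x, y) {
  W <- 1 / (1 + sq_dist(x, y))
  diag(W) <- 0
  W / sum(W)
}

#' @export
print.tl_layout <- function(x, ...) {
  cat("TL-tsne layout: ", nrow(x$coords), " nodes, beta = ", x$beta,
      ", KL ", format(x$kl_initial, digits = 4), " -> ",
      format(x$kl_final, digits = 4), " in ", x$iterations,
      " iterations\n", sep = "")
  invisible(x)
}

#' Extended Moran index of a layout
#'
#' Spatial autocorrelation of the embedded y-coordinate over the symmetrised
#' adjacency \eqn{w = A + A^T}:
#' \deqn{I = \frac{n}{\sum_{ij} w_{ij}}
#'   \frac{\sum_{ij} w_{ij} (y_i - \bar y)(y_j - \bar y)}
#'        {\sum_i (y_i - \bar y)^2}.}
#' Only y enters: x is pinned to the trophic levels, so its autocorrelation
#' carries no information about the embedding. High values mean adjacent
#' nodes sit at similar heights -- the quality score used to select
#' \eqn{\beta}.
#'
#' @param layout a `tl_layout`, or directly a numeric vector of y-coordinates
#'   in vertex order
#' @param graph the embedded graph
#' @return the index (a real number)
#' @export
extended_moran <- function(layout, graph) {
  y <- if (inherits(layout, "tl_layout")) layout$coords$y else
    as.numeric(layout)
  n <- vcount(graph)
  stopifnot(length(y) == n)
  yc <- y - mean(y)
  if (sum(yc^2) == 0) stop("constant layout: zero variance in y")
  A <- adjacency_of(graph)
  W <- A + t(A)
  (n / sum(W)) * sum(W * outer(yc, yc)) / sum(yc^2)
}

#' Select the diffusion parameter by the extended Moran index
#'
#' Runs [tl_tsne()] for every \eqn{\beta} of the grid under the same seed,
#' scores each layout with [extended_moran()], and returns the full profile
#' together with the argmax \eqn{\beta} (ties resolved towards the smallest
#' \eqn{\beta}). A failed embedding is recorded as `NA` in the profile
#' rather than aborting the scan. The profile is a guide: exploring several
#' \eqn{\beta} values by eye is encouraged, since channel separation
#' develops gradually with \eqn{\beta}.
#'
#' @inheritParams tl_tsne
#' @param beta_grid strictly positive numeric vector of candidate
#'   \eqn{\beta} values
#' @param config a [layout_config()]; its `beta` is overridden by the grid
#' @return object of class `moran_profile`: list with `profile`
#'   (`data.frame(beta, moran_index)`) and `selected_beta`.
#' @export
select_beta <- function(graph, trophic_levels = NULL, beta_grid, config,
                        weighted = FALSE) {
  stopifnot(length(beta_grid) >= 1, all(beta_grid > 0))
  beta_grid <- sort(unique(as.numeric(beta_grid)))
  moran <- vapply(beta_grid, function(b) {
    cfg <- config
    cfg$beta <- b
    tryCatch(
      extended_moran(tl_tsne(graph, trophic_levels, cfg, weighted), graph),
      error = function(e) NA_real_
    )
  }, numeric(1))
  profile <- data.frame(beta = beta_grid, moran_index = moran)
  sel <- if (all(is.na(moran))) NA_real_ else
    beta_grid[which.max(moran)]  # first max = smallest beta on ties
  structure(list(profile = profile, selected_beta = sel),
            class = "moran_profile")
}

#' @export
print.moran_profile <- function(x, ...) {
  cat("extended-Moran beta profile (selected beta = ", x$selected_beta,
      ")\n", sep = "")
  print(x$profile, row.names = FALSE)
  invisible(x)
}

layout_key <- function(network, resolution, beta) {
  paste(network, resolution, format(beta, digits = 15), sep = "|")
}

#' Attach a layout to a metanetwork
#'
#' Computes and stores a layout for one network at one resolution. With a
#' [layout_config()] this is the TL-tsne layout; each weakly connected
#' component of the network is embedded separately (the kernel of a
#' disconnected graph is block-diagonal, so cross-component affinities are
#' zero and relative placement would be arbitrary), the components sharing
#' the x-axis through their metaweb-anchored trophic levels. Single-node
#' components get y = 0. With a [group_layout_config()] the group-TL-tsne
#' layout of [group_tl_tsne()] is computed and stored under the resolution
#' key `"group-TL-tsne@<resolution>"`.
#'
#' Layouts are stored under the key (network, resolution, beta); several
#' beta values coexist, and re-attaching an existing key overwrites it with
#' a message.
#'
#' @param metanet a `metanetwork` after [compute_TL()]
#' @param network `"metaweb"` or a local network name
#' @param resolution resolution name (default finest)
#' @param config a [layout_config()] or [group_layout_config()]
#' @param weighted passed to the kernel
#' @return the `metanetwork` with the layout stored in `$layouts`.
#' @seealso [get_layout()]
#' @export
attach_layout <- function(metanet, network = "metaweb", resolution = NULL,
                          config, weighted = FALSE) {
  stopifnot(inherits(metanet, "metanetwork"))
  if (inherits(config, "group_layout_config")) {
    if (is.null(resolution)) {
      stop("group-TL-tsne needs an aggregation resolution")
    }
    lay <- group_tl_tsne(metanet, network, resolution, config)
    res_key <- paste0("group-TL-tsne@", resolution)
    return(store_layout(metanet, network, res_key, config$beta, lay))
  }
  stopifnot(inherits(config, "layout_config"))
  g <- get_network(metanet, network, resolution)
  if (is.null(V(g)$TL)) {
    stop("trophic levels missing on '", network, "'; run compute_TL() first")
  }
  lay <- embed_components(g, config, weighted)
  res_key <- if (is.null(resolution)) finest_resolution(metanet) else
    resolution
  store_layout(metanet, network, res_key, config$beta, lay)
}

embed_components <- function(g, config, weighted = FALSE) {
  comp <- components(g, mode = "weak")
  coords <- data.frame(node = V(g)$name, x = V(g)$TL, y = 0,
                       stringsAsFactors = FALSE)
  parts <- list()
  for (ci in seq_len(comp$no)) {
    members <- V(g)$name[comp$membership == ci]
    if (length(members) < 2) next
    sub <- induced_subgraph(g, members)
    sl <- tl_tsne(sub, config = config, weighted = weighted)
    coords$y[match(sl$coords$node, coords$node)] <- sl$coords$y
    parts[[length(parts) + 1]] <- sl
  }
  structure(list(
    coords = coords,
    beta = config$beta,
    kl_initial = sum(vapply(parts, `[[`, numeric(1), "kl_initial")),
    kl_final = sum(vapply(parts, `[[`, numeric(1), "kl_final")),
    iterations = sum(vapply(parts, `[[`, numeric(1), "iterations")),
    seed = config$seed,
    components = parts
  ), class = "tl_layout")
}

store_layout <- function(metanet, network, res_key, beta, lay) {
  key <- layout_key(network, res_key, beta)
  if (key %in% names(metanet$layouts)) {
    message("overwriting existing layout ", key)
  }
  metanet$layouts[[key]] <- lay
  metanet
}

#' Retrieve a stored layout
#'
#' @inheritParams attach_layout
#' @param beta the beta value it was attached with
#' @return the stored `tl_layout`
#' @export
get_layout <- function(metanet, network = "metaweb", resolution = NULL,
                       beta) {
  res_key <- if (is.null(resolution)) finest_resolution(metanet) else
    resolution
  key <- layout_key(network, res_key, beta)
  if (!key %in% names(metanet$layouts)) {
    stop("no layout stored under (", network, ", ", res_key, ", beta = ",
         beta, "); run attach_layout()")
  }
  metanet$layouts[[key]]
}

#' All stored layouts as one data frame
#'
#' Long format `network, resolution, beta, node, x, y`, ready for
#' [utils::write.csv()].
#'
#' @param metanet a `metanetwork`
#' @return a `data.frame` (zero rows when no layout is attached)
#' @export
layouts_table <- function(metanet) {
  if (length(metanet$layouts) == 0) {
    return(data.frame(network = character(0), resolution = character(0),
                      beta = numeric(0), node = character(0),
                      x = numeric(0), y = numeric(0)))
  }
  do.call(rbind, lapply(names(metanet$layouts), function(key) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    lay <- metanet$layouts[[key]]
    data.frame(network = parts[1], resolution = parts[2],
               beta = lay$beta, node = lay$coords$node,
               x = lay$coords$x, y = lay$coords$y,
               stringsAsFactors = FALSE)
  }))
}
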