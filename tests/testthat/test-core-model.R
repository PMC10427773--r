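test_that("local networks are vertex-induced subgraphs of the metaweb", {
  g <- chain_graph()
  P <- chain_abundances(list(full = c(1, 1, 1) / 3, ab = c(0.5, 0.5, 0)))
  mn <- build_metanet(g, P)

  full <- get_network(mn, "full")
  expect_setequal(V(full)$name, c("a", "b", "c"))
  expect_equal(ecount(full), 2)

  ab <- get_network(mn, "ab")
  expect_setequal(V(ab)$name, c("a", "b"))
  el <- as_edgelist(ab)
  expect_equal(unname(el), matrix(c("a", "b"), 1))
  expect_equal(sum(V(ab)$ab), 1)  # rows normalised on ingestion

  # induced-subgraph property on a random metanetwork: every metaweb edge
  # between present nodes appears, and no other edge does
  mn2 <- make_random_metanetwork(n_nodes = 30, connectance = 0.12,
                                 n_communities = 4, seed = 42)
  meta_el <- apply(as_edgelist(mn2$metaweb), 1, paste, collapse = "->")
  for (loc in mn2$locals) {
    present <- V(loc)$name
    expected <- meta_el[
      vapply(strsplit(meta_el, "->", fixed = TRUE),
             function(e) all(e %in% present), logical(1))]
    got <- apply(as_edgelist(loc), 1, paste, collapse = "->")
    expect_setequal(got, expected)
  }
})

test_that("build_metanet rejects bad inputs with informative errors", {
  two_comp <- graph_from_data_frame(
    data.frame(from = c("a", "c"), to = c("b", "d")), directed = TRUE)
  expect_error(build_metanet(two_comp), "weakly connected")
  expect_error(build_metanet(two_comp), "\\{a,b\\}")

  g <- chain_graph()
  P_unknown <- chain_abundances(list(s = c(1, 1, 1)), c("a", "b", "zz"))
  expect_error(build_metanet(g, P_unknown), "zz")
  P_neg <- chain_abundances(list(s = c(1, -1, 1)))
  expect_error(build_metanet(g, P_neg), "negative")
  P_zero <- chain_abundances(list(s = c(0, 0, 0)))
  expect_error(build_metanet(g, P_zero), "no positive")

  loopy <- graph_from_data_frame(
    data.frame(from = c("a", "b"), to = c("b", "b")), directed = TRUE)
  expect_error(build_metanet(loopy), "self-loop")

  tt_bad <- data.frame(species = c("a", "b", "x"), g = c("g1", "g1", "g2"))
  expect_error(build_metanet(g, trophic_table = tt_bad), "x")
})

test_that("abundance-free metanetworks hold the metaweb alone", {
  mn <- build_metanet(chain_graph())
  expect_length(mn$locals, 0)
  expect_equal(network_names(mn), "metaweb")
})

test_that("aggregation reproduces the worked two-group examples exactly", {
  g <- graph_from_data_frame(
    data.frame(from = c("n1", "n2"), to = c("n3", "n3")), directed = TRUE)
  part <- c(n1 = "A", n2 = "A", n3 = "B")
  p <- c(n1 = 0.25, n2 = 0.25, n3 = 0.5)

  agg <- aggregate_network(g, p, part)
  expect_equal(sort(V(agg)$name), c("A", "B"))
  expect_equal(stats::setNames(V(agg)$ab, V(agg)$name)[c("A", "B")],
               c(A = 0.5, B = 0.5), tolerance = 1e-12)
  expect_equal(E(agg)$weight, 1, tolerance = 1e-12)

  # same but pi_13 = 1, pi_23 = 0 -> pi_AB = 0.125 / 0.25 = 0.5
  g2 <- graph_from_data_frame(
    data.frame(from = "n1", to = "n3", weight = 1), directed = TRUE)
  g2 <- add_vertices(g2, 1, name = "n2")
  agg2 <- aggregate_network(g2, p, part)
  expect_equal(E(agg2)$weight, 0.5, tolerance = 1e-12)
})

test_that("aggregation under the identity partition is the identity", {
  mn <- make_random_metanetwork(n_nodes = 15, connectance = 0.2,
                                n_communities = 1, seed = 3)
  g <- mn$locals[[1]]
  part <- stats::setNames(V(g)$name, V(g)$name)
  agg <- aggregate_network(g, partition = part)
  expect_equal(canonical_graph(agg)$edges, canonical_graph(g)$edges,
               tolerance = 1e-12)
  expect_equal(canonical_graph(agg)$ab, canonical_graph(g)$ab,
               tolerance = 1e-12)
})

test_that("aggregation conserves total abundance on random partitions", {
  withr::with_seed(11, {
    for (rep in 1:20) {
      n <- sample(5:25, 1)
      g <- random_connected_digraph(n)
      p <- stats::setNames(stats::rgamma(n, 1), V(g)$name)
      p <- p / sum(p)
      for (Q in unique(c(1, sample(1:n, 4, replace = TRUE)))) {
        part <- stats::setNames(
          paste0("grp", sample(seq_len(Q), n, replace = TRUE)), V(g)$name)
        agg <- aggregate_network(g, p, part)
        expect_equal(sum(V(agg)$ab), sum(p), tolerance = 1e-12)
        # bounded interaction probabilities for binary pi
        if (ecount(agg) > 0) {
          expect_true(all(E(agg)$weight >= 0))
          expect_true(all(E(agg)$weight <= 1 + 1e-12))
        }
      }
    }
  })
})

test_that("append_agg_nets is idempotent and handles trivial coarsening", {
  g <- chain_graph()
  P <- chain_abundances(list(s1 = c(0.5, 0.5, 0), s2 = c(0.2, 0.3, 0.5)))
  tt <- data.frame(species = c("a", "b", "c"),
                   group = c("low", "low", "high"),
                   whole = c("all", "all", "all"))
  mn <- append_agg_nets(build_metanet(g, P, tt))

  # trivial coarse partition: one node, self-loop iff any edge existed
  whole <- get_network(mn, "metaweb", "whole")
  expect_equal(vcount(whole), 1)
  expect_equal(ecount(whole), 1)
  expect_true(which_loop(whole))

  mn2 <- append_agg_nets(mn)
  for (res in names(mn$aggregated)) {
    expect_equal(canonical_graph(get_network(mn2, "metaweb", res)),
                 canonical_graph(get_network(mn, "metaweb", res)))
    for (nm in names(mn$locals)) {
      expect_equal(canonical_graph(get_network(mn2, nm, res)),
                   canonical_graph(get_network(mn, nm, res)))
    }
  }

  expect_error(append_agg_nets(build_metanet(g, P)), "trophic table")
})

test_that("nested aggregation of abundances is associative", {
  mn <- make_random_metanetwork(n_nodes = 24, connectance = 0.15,
                                n_communities = 2, seed = 9, n_groups = 6,
                                n_resolutions = 2)
  mn <- append_agg_nets(mn)
  tt <- mn$trophic_table
  coarse <- colnames(tt)[3]
  for (nm in names(mn$locals)) {
    # finest -> coarsest directly
    g <- get_network(mn, nm)
    part <- stats::setNames(tt[[coarse]], tt[[1]])
    direct <- aggregate_network(g, partition = part)
    # via the appended middle resolution
    via <- get_network(mn, nm, coarse)
    d <- canonical_graph(direct)
    v <- canonical_graph(via)
    expect_equal(d$nodes, v$nodes)
    expect_equal(d$ab, v$ab, tolerance = 1e-12)
  }
})

test_that("zero-abundance groups are absent from aggregated local nets", {
  g <- chain_graph()
  P <- chain_abundances(list(s1 = c(0.5, 0.5, 0)))
  tt <- data.frame(species = c("a", "b", "c"),
                   group = c("lo", "lo", "hi"))
  mn <- append_agg_nets(build_metanet(g, P, tt))
  agg <- get_network(mn, "s1", "group")
  expect_equal(V(agg)$name, "lo")  # "hi" has zero abundance in s1
})

test_that("trophic_table_tree builds the containment forest, rejects non-nested tables", {
  tt <- data.frame(species = c("a", "b", "c"),
                   group = c("g1", "g1", "g2"),
                   kingdom = c("k", "k", "k"))
  tr <- trophic_table_tree(tt)
  expect_equal(vcount(tr), 3 + 2 + 1)
  expect_equal(ecount(tr), 3 + 2)
  expect_true(is_forest(tr, mode = "out"))

  single <- trophic_table_tree(tt["species"])
  expect_equal(vcount(single), 3)
  expect_equal(ecount(single), 0)

  bad <- data.frame(species = c("a", "b", "c"),
                    group = c("g1", "g1", "g2"),
                    kingdom = c("k1", "k2", "k1"))
  expect_error(trophic_table_tree(bad), "g1")
})
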