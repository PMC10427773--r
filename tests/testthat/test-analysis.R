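chain_metanet <- function() {
  g <- chain_graph()
  P <- chain_abundances(list(t1 = c(0.5, 0.5, 0), t2 = c(0, 0.5, 0.5),
                             all = c(1, 1, 1) / 3))
  compute_TL(build_metanet(g, P))
}

test_that("difference networks carry signed abundance and weight differences", {
  mn <- chain_metanet()
  d <- diff_networks(mn, "t1", "t2")
  expect_setequal(d$nodes$node, c("a", "b", "c"))
  got <- stats::setNames(d$nodes$delta_ab, d$nodes$node)
  expect_equal(got[c("a", "b", "c")], c(a = 0.5, b = 0, c = -0.5))
  cat_got <- stats::setNames(d$nodes$category, d$nodes$node)
  expect_equal(cat_got[c("a", "b", "c")],
               c(a = "only-first", b = "both", c = "only-second"))
  # edge a->b is in t1 only, b->c in t2 only
  ew <- stats::setNames(d$edges$delta_w,
                        paste(d$edges$resource, d$edges$consumer))
  expect_equal(ew[c("a b", "b c")], c("a b" = 1, "b c" = -1))

  self <- diff_networks(mn, "t1", "t1")
  expect_true(all(self$nodes$delta_ab == 0))
  expect_true(all(self$nodes$category == "both"))
  expect_true(all(self$edges$delta_w == 0))

  rev <- diff_networks(mn, "t2", "t1")
  expect_setequal(rev$nodes$node, d$nodes$node)
  expect_equal(rev$nodes$delta_ab[match(d$nodes$node, rev$nodes$node)],
               -d$nodes$delta_ab)

  expect_error(diff_networks(mn, "t1", "nope"), "unknown network")
})

test_that("compute_metrics reports TL summaries and mean shortest paths", {
  mn <- chain_metanet()
  m <- compute_metrics(mn)
  meta <- m[m$network == "metaweb", ]
  expect_equal(meta$mean_TL, 1)
  expect_equal(meta$max_TL, 2)
  expect_equal(meta$mean_shortest_path, 4 / 3)  # pairs (1 + 2 + 1) / 3
  expect_true("metaweb" %in% m$network)

  # single-node network: path length undefined, reported as NA
  g <- chain_graph()
  P1 <- chain_abundances(list(lone = c(1, 0, 0)))
  m1 <- compute_metrics(compute_TL(build_metanet(g, P1)))
  lone <- m1[m1$network == "lone", ]
  expect_true(is.na(lone$mean_shortest_path))
  expect_equal(lone$mean_TL, 0)
})

test_that("node diversity follows the Hill-number identities", {
  for (q in c(0, 0.5, 1, 2)) {
    expect_equal(node_diversity(rep(0.2, 5), q), 5, tolerance = 1e-12)
    expect_equal(node_diversity(rep(7, 5), q), 5, tolerance = 1e-12)
    expect_equal(node_diversity(1, q), 1)
  }
  expect_equal(node_diversity(c(0.5, 0.3, 0.2, 0), 0), 3)
  expect_equal(node_diversity(c(0.5, 0.5), 1), 2, tolerance = 1e-12)
  expect_error(node_diversity(c(0, 0), 1), "positive")

  # non-increasing in q on random abundance vectors
  withr::with_seed(53, {
    for (rep in 1:20) {
      p <- stats::rgamma(sample(3:30, 1), 0.7)
      d <- vapply(c(0, 1, 2), function(q) node_diversity(p, q), numeric(1))
      expect_true(all(diff(d) <= 1e-10))
    }
  })
})

test_that("link diversity counts effective trophic links", {
  py <- make_pyramid(c(2, 1))
  # two edges with equal weight and uniform abundances: L uniform over 2
  for (q in c(0, 1, 2)) {
    expect_equal(link_diversity(py, rep(1 / 3, 3), q), 2,
                 tolerance = 1e-12)
  }
  g1 <- graph_from_data_frame(data.frame(from = "a", to = "b"))
  expect_equal(link_diversity(g1, c(0.5, 0.5), 1), 1)
  lone <- make_empty_graph(directed = TRUE) + vertices("x")
  expect_error(link_diversity(lone, 1, 1), "no edges")
})

test_that("compute_div covers all networks and collapses at one group", {
  mn <- chain_metanet()
  div <- compute_div(mn, q = 1)
  expect_equal(nrow(div), 4)  # metaweb + 3 locals
  all_row <- div[div$network == "all", ]
  expect_equal(all_row$node_diversity, 3, tolerance = 1e-12)

  tt <- data.frame(species = c("a", "b", "c"), whole = "all")
  g <- chain_graph()
  P <- chain_abundances(list(s1 = c(0.5, 0.5, 0), s2 = c(0.2, 0.3, 0.5)))
  mn2 <- compute_TL(append_agg_nets(build_metanet(g, P, tt)))
  div2 <- compute_div(mn2, q = 1, resolution = "whole")
  expect_true(all(div2$node_diversity == 1))
})

test_that("aggregation can only lower node diversity (lumping property)", {
  withr::with_seed(59, {
    for (rep in 1:10) {
      n <- sample(6:25, 1)
      p <- stats::rgamma(n, 1)
      part <- sample(letters[1:sample(2:5, 1)], n, replace = TRUE)
      fine <- node_diversity(p, 1)
      coarse <- node_diversity(tapply(p, part, sum), 1)
      expect_lte(coarse, fine + 1e-10)
    }
  })
})

test_that("pairwise dissimilarities behave as beta diversities", {
  mn <- chain_metanet()
  dis <- compute_dis(mn, q = 1)
  expect_equal(dis$nodes, t(dis$nodes))
  expect_true(all(diag(dis$nodes) == 0))
  expect_true(all(dis$nodes >= -1e-12 & dis$nodes <= 1 + 1e-12))

  # disjoint, equally weighted node sets at q = 1 -> dissimilarity 1
  g <- chain_graph(c("a", "b", "c", "d"))
  P <- chain_abundances(list(left = c(0.5, 0.5, 0, 0),
                             right = c(0, 0, 0.5, 0.5)),
                        c("a", "b", "c", "d"))
  mn2 <- compute_TL(build_metanet(g, P))
  dis2 <- compute_dis(mn2, q = 1)
  expect_equal(dis2$nodes["left", "right"], 1, tolerance = 1e-12)
  expect_equal(dis2$links["left", "right"], 1, tolerance = 1e-12)

  # identical networks -> 0 (nodes and links)
  P3 <- chain_abundances(list(x = c(0.2, 0.3, 0.5), y = c(0.2, 0.3, 0.5)))
  dis3 <- compute_dis(compute_TL(build_metanet(chain_graph(), P3)), q = 1)
  expect_equal(dis3$nodes["x", "y"], 0, tolerance = 1e-12)
  expect_equal(dis3$links["x", "y"], 0, tolerance = 1e-12)

  # q != 1 normalisation stays in [0, 1] with the same endpoints
  for (q in c(0, 0.5, 2)) {
    dq <- compute_dis(mn2, q = q)
    expect_equal(dq$nodes["left", "right"], 1, tolerance = 1e-10)
    dq3 <- compute_dis(compute_TL(build_metanet(chain_graph(), P3)), q = q)
    expect_equal(dq3$nodes["x", "y"], 0, tolerance = 1e-10)
  }

  expect_error(compute_dis(compute_TL(build_metanet(
    chain_graph(), chain_abundances(list(only = c(1, 1, 1))))), q = 1),
    "two local networks")
})
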