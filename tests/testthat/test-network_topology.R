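test_that("network induction drops non-seeds and isolated seeds", {
  edges <- data.frame(node_a = c("A", "B"), node_b = c("B", "D"))
  net <- build_network(edges, c("A", "B", "C"))
  expect_setequal(igraph::V(net)$name, c("A", "B"))
  expect_equal(igraph::ecount(net), 1L)
  expect_error(build_network(edges, c("X", "Y")), "empty")
})

test_that("with no between-module edges the components are the planted modules", {
  truth <- make_truth(rep(c("G2", "G6"), each = 6))
  net <- sbm_net(truth, p_in = 1, p_out = 0, seed = 3)
  comp <- igraph::components(net)
  expect_equal(comp$no, 2L)
  grp <- igraph::V(net)$group
  expect_true(all(tapply(grp, comp$membership, function(g) length(unique(g))) == 1))
})

test_that("betweenness matches hand values on canonical graphs", {
  bc_star <- betweenness_centrality(star_graph(5))
  expect_equal(bc_star$bc[bc_star$node == "A"], 1.0)
  expect_true(all(bc_star$bc[bc_star$node != "A"] == 0))

  path <- graph_from_pairs(c("A", "B"), c("B", "C"))
  bc_path <- betweenness_centrality(path)
  expect_equal(bc_path$bc[bc_path$node == "B"], 1.0)

  # 4-cycle: opposite pairs split 0.5/0.5 over the two intermediates
  expect_equal(betweenness_centrality(ring_graph(4))$bc, rep(1 / 6, 4))

  # two disconnected 3-paths: middles carry one pair each, global normalization
  g2 <- graph_from_pairs(c("A", "B", "D", "E"), c("B", "C", "E", "F"))
  bc2 <- betweenness_centrality(g2)
  expect_equal(sort(bc2$bc, decreasing = TRUE), c(0.1, 0.1, 0, 0, 0, 0))

  # n < 3: normalized BC defined as zero
  tiny <- graph_from_pairs("A", "B")
  expect_equal(betweenness_centrality(tiny)$bc, c(0, 0))
})

test_that("Brandes accumulation equals the exhaustive-path oracle and igraph", {
  for (s in 1:12) {
    g <- er_graph(8, 0.4, seed = 100 + s)
    a <- betweenness_centrality(g)
    b <- brute_force_betweenness(g)
    expect_equal(a$bc[order(a$node)], b$bc[order(b$node)], tolerance = 1e-12)
    ig <- igraph::betweenness(g, directed = FALSE)
    expect_equal(a$bc_raw[order(a$node)], unname(ig[sort(names(ig))]),
                 tolerance = 1e-10)
  }
  expect_error(brute_force_betweenness(er_graph(15, 0.3, 1)), "limited to")
})

test_that("betweenness is invariant under node relabeling", {
  g <- er_graph(10, 0.35, seed = 77)
  bc1 <- betweenness_centrality(g)
  perm <- sample(igraph::vcount(g))
  g2 <- igraph::permute(g, perm)
  bc2 <- betweenness_centrality(g2)
  m <- match(bc1$node, bc2$node)
  expect_equal(bc1$bc, bc2$bc[m], tolerance = 1e-12)
})

test_that("link partition counts are exact and additive", {
  groups <- c(a = "G1", b = "G1", c = "G2", d = "G2")
  net <- graph_from_pairs(c("a", "c", "b"), c("b", "d", "c"), groups = groups)
  lp <- count_links_by_group(net)
  expect_equal(lp$within_total, 2L)
  expect_equal(lp$between_total, 1L)
  expect_equal(lp$counts["G1", "G2"], 1L)

  one <- graph_from_pairs(c("a", "b"), c("b", "c"),
                          groups = c(a = "G3", b = "G3", c = "G3"))
  expect_equal(count_links_by_group(one)$between_total, 0L)

  # random labeled graph: totals equal an independent edge scan
  truth <- make_truth(sample(paste0("G", 1:4), 30, replace = TRUE))
  net2 <- sbm_net(truth, 0.4, 0.4, seed = 9)
  lp2 <- count_links_by_group(net2)
  el <- igraph::as_edgelist(net2)
  grp <- stats::setNames(igraph::V(net2)$group, igraph::V(net2)$name)
  expect_equal(lp2$within_total, sum(grp[el[, 1]] == grp[el[, 2]]))
  expect_equal(lp2$within_total + lp2$between_total, igraph::ecount(net2))
})

test_that("within-fractions and their random-neighbor expectation are correct", {
  groups <- c(a = "G1", b = "G1", c = "G2", d = "G2")
  net <- graph_from_pairs(c("a", "c", "b"), c("b", "d", "c"), groups = groups)
  obs <- within_fraction_per_gene(net)
  expect_equal(unname(obs[c("A", "B", "C", "D")]), c(1, 0.5, 0.5, 1))
  expect_equal(unname(expected_within_fraction(net)), rep(1 / 3, 4))

  # shuffling labels leaves the mean expectation consistent with the mean
  # observation on average
  truth <- make_truth(rep(paste0("G", 1:3), each = 8))
  net2 <- sbm_net(truth, 0.3, 0.3, seed = 15)
  set.seed(15)
  diffs <- replicate(200, {
    labs <- sample(igraph::V(net2)$group)
    igraph::V(net2)$group <- labs
    mean(within_fraction_per_gene(net2)) - mean(expected_within_fraction(net2))
  })
  expect_lt(abs(mean(diffs)), 0.02)
})

test_that("likelihood score is 1 at its null and increases under rewiring", {
  # observed == expected exactly: single group, so both vectors are all 1
  one <- graph_from_pairs(c("a", "b", "c"), c("b", "c", "a"),
                          groups = c(a = "G1", b = "G1", c = "G1"))
  ls <- likelihood_score(one)
  expect_equal(ls$score, 1.0)

  # degree-preserving swaps converting between- to within-links raise the score
  groups <- stats::setNames(rep(c("G1", "G2"), each = 4),
                            c("a1", "a2", "a3", "a4", "b1", "b2", "b3", "b4"))
  seq_a <- list(   # perfect matchings: every node keeps degree 1
    list(a = c("a1", "a2", "a3", "a4"), b = c("b1", "b2", "b3", "b4")),
    list(a = c("a1", "b1", "a3", "a4"), b = c("a2", "b2", "b3", "b4")),
    list(a = c("a1", "b1", "a3", "b3"), b = c("a2", "b2", "a4", "b4")))
  scores <- vapply(seq_a, function(e) {
    likelihood_score(graph_from_pairs(e$a, e$b, groups = groups))$score
  }, 0)
  expect_true(all(diff(scores) > 0))
})

test_that("permutation null is deterministic and extreme for modular graphs", {
  truth <- make_truth(rep(paste0("G", 1:2), each = 8))
  net <- sbm_net(truth, 0.9, 0.05, seed = 30)
  pn1 <- permutation_null(net, n_perm = 100, seed = 5)
  pn2 <- permutation_null(net, n_perm = 100, seed = 5)
  expect_identical(pn1$null, pn2$null)
  expect_equal(pn1$p_empirical, 1 / 101)
  expect_error(permutation_null(net, n_perm = 50), "n_perm")
})
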