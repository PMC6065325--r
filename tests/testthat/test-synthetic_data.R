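test_that("noiseless planted effects reproduce exact per-rat ratios", {
  pr <- synth_params(n_genes = 50, sigma = 0,
                     group_props = c(G2 = 0.2, G6 = 0.2))
  ex <- generate_expression(pr, seed = 5)
  prof <- ratio_profiles(ex$em)
  tr <- ex$truth
  g2 <- tr$gene[tr$group == "G2"][1]
  i <- match(g2, prof$gene)
  expect_equal(unname(prof$r1[i, ]), rep(tr$e1[tr$gene == g2], 3))
  expect_equal(unname(prof$r2[i, ]), rep(tr$e2[tr$gene == g2], 3))

  # a worked-example-style G2 gene: e1 = 1.58, WD mean = 0.80 x CON
  tr2 <- make_truth("G2", genes = "AKT1")
  tr2$e1 <- 1.58; tr2$e2 <- 0.80 / 1.58
  # plant manually through the mean model: CON=10
  con <- 10; masa <- con * tr2$e1; wd <- masa * tr2$e2
  expect_equal(masa / con, 1.58)
  expect_equal(wd / con, 0.80)

  # NONE gene: all nine values equal the baseline
  none <- tr$gene[tr$group == "NONE"][1]
  v <- ex$em$values[none, ]
  expect_true(all(v == v[1]))
})

test_that("the generator is deterministic and validates proportions", {
  pr <- synth_params(n_genes = 40)
  a <- generate_expression(pr, seed = 9)
  b <- generate_expression(pr, seed = 9)
  expect_identical(a$em$values, b$em$values)
  expect_identical(a$truth$group, b$truth$group)
  expect_error(synth_params(group_props = c(G1 = 0.7, G2 = 0.7)), "more than 1")
})

test_that("degenerate block models give exactly the planted cliques", {
  truth <- make_truth(rep(c("G1", "G2"), each = 3))
  edges <- generate_network(truth, p_in = 1, p_out = 0, p_decoy = 0, seed = 2)
  expect_equal(nrow(edges), 6L)              # two 3-cliques
  expect_true(all(edges$combined_score >= 400))
  net <- build_network(edges, truth$gene,
                       groups = stats::setNames(truth$group, truth$gene))
  comp <- igraph::components(net)
  expect_equal(comp$no, 2L)
  expect_true(all(igraph::degree(net) == 2))
  expect_error(generate_network(truth, p_in = 0.2, p_out = 0.5), "p_out <= p_in")
})

test_that("decoy edges stay below the score threshold", {
  truth <- make_truth(rep("G2", 20))
  edges <- generate_network(truth, p_in = 0, p_out = 0, p_decoy = 0.5, seed = 6)
  expect_gt(nrow(edges), 0)
  expect_true(all(edges$combined_score < 400))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_string_links(edges, p)
  expect_equal(nrow(read_string_links(p, score_min = 400)), 0L)
})

test_that("module relabeling permutes but preserves the link-count multiset", {
  truth <- make_truth(rep(paste0("G", 1:3), each = 8))
  net1 <- sbm_net(truth, 0.5, 0.1, seed = 44)
  lp1 <- count_links_by_group(net1)
  # relabel modules by a permutation of the group names
  perm <- c(G1 = "G3", G2 = "G1", G3 = "G2")
  truth2 <- truth; truth2$group <- unname(perm[truth$group])
  net2 <- sbm_net(truth2, 0.5, 0.1, seed = 44)
  lp2 <- count_links_by_group(net2)
  expect_equal(lp2$within_total, lp1$within_total)
  expect_equal(sort(lp2$counts[upper.tri(lp2$counts, diag = TRUE)]),
               sort(lp1$counts[upper.tri(lp1$counts, diag = TRUE)]))
})

test_that("curated planting follows its sampling rule", {
  # all nodes curated: fold enrichment is exactly 1
  truth <- make_truth(rep(c("G1", "G2"), each = 6))
  net <- sbm_net(truth, 0.8, 0.2, seed = 21)
  cur <- plant_curated_set(net, rule = "uniform",
                           size = igraph::vcount(net), seed = 1)
  res <- enrichment_result(net, betweenness_centrality(net), cur)
  expect_equal(res$fold_enrichment, 1.0)

  # degree-biased on a star: center drawn with weight (n-1)^2 vs (n-1) leaves
  st <- star_graph(5)
  hits <- vapply(1:10000, function(s) {
    plant_curated_set(st, rule = "degree", size = 1, beta = 2, seed = s)$symbols == "A"
  }, TRUE)
  expect_equal(mean(hits), 16 / 20, tolerance = 0.03)
  expect_error(plant_curated_set(st, rule = "degree", size = 1, beta = -1),
               "beta")

  # off-network extras dilute the mapping rate as designed
  cur2 <- plant_curated_set(net, rule = "uniform", size = 5,
                            n_extras = 15, seed = 2)
  expect_equal(map_gene_set(net, cur2)$mapping_rate, 5 / 20)
})

test_that("study bundles are byte-identical under a fixed seed and re-read exactly", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  pr <- synth_params(n_genes = 60, group_props = c(G2 = 0.3, G6 = 0.2))
  b1 <- generate_study(d1, params = pr, seed = 33)
  b2 <- generate_study(d2, params = pr, seed = 33)
  for (f in names(b1$paths)) {
    expect_identical(readLines(b1$paths[[f]]), readLines(b2$paths[[f]]),
                     label = f)
  }
  em <- read_expression_table(b1$paths$expression)
  expect_identical(em$values, b1$em$values)
})

test_that("a null block model gives likelihood scores centered on one", {
  truth <- make_truth(rep(paste0("G", 1:4), each = 8))
  scores <- vapply(1:200, function(s) {
    likelihood_score(sbm_net(truth, 0.2, 0.2, seed = s))$score
  }, 0)
  expect_lt(abs(mean(scores) - 1), 0.05)
})
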