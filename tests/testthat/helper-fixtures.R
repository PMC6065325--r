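# Shared builders for small graphs, synthetic truths and file fixtures.

graph_from_pairs <- function(a, b, groups = NULL, curated = NULL) {
  edges <- data.frame(node_a = a, node_b = b, stringsAsFactors = FALSE)
  build_network(edges, unique(c(a, b)), groups = groups, curated = curated)
}

star_graph <- function(n = 5) {
  g <- igraph::make_star(n, mode = "undirected")
  igraph::V(g)$name <- LETTERS[seq_len(n)]
  g
}

ring_graph <- function(n = 4) {
  g <- igraph::make_ring(n)
  igraph::V(g)$name <- LETTERS[seq_len(n)]
  g
}

er_graph <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("V%02d", seq_len(n))
  g
}

# minimal ground-truth table for generate_network / plant_curated_set
make_truth <- function(groups, genes = sprintf("N%04d", seq_along(groups))) {
  data.frame(gene = genes, group = groups, e1 = 1, e2 = 1,
             stringsAsFactors = FALSE)
}

sbm_net <- function(truth, p_in, p_out, seed, p_decoy = 0) {
  edges <- generate_network(truth, p_in = p_in, p_out = p_out,
                            p_decoy = p_decoy, seed = seed)
  build_network(edges, truth$gene,
                groups = stats::setNames(truth$group, truth$gene))
}

# the published 43-gene worked-example candidate table shipped with the
# package (rank, normalized BC, curated flag, trajectory group, normalized
# MASA/WD ratios)
load_top43 <- function() {
  read_candidate_table(system.file("extdata", "candidates_top43.tsv",
                                   package = "patternet"))
}

# tiny balanced 3-gene x 3-rat expression fixture with known trajectories
tiny_expression <- function() {
  vals <- rbind(
    UPDOWN = c(10, 10, 10, 20, 20, 20, 10, 10, 10),
    FLAT   = c(5, 5, 5, 5, 5, 5, 5, 5, 5),
    DOWNDN = c(8, 8, 8, 4, 4, 4, 2, 2, 2))
  colnames(vals) <- c("CON_1", "CON_2", "CON_3", "MASA_1", "MASA_2",
                      "MASA_3", "WD_1", "WD_2", "WD_3")
  expr_matrix(vals)
}
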