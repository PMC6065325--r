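#' Default synthetic-study parameters
#'
#' The defaults emulate the study conditions the pipeline was designed
#' for: 2,000 genes of which 666 carry a planted trajectory group in the
#' observed proportions 3:422:2:51:25:163 (G1..G6), three paired rats,
#' log-normal FPKM-scale baselines, multiplicative per-sample log-normal
#' noise with sd 0.1, up effects drawn from [1.2, 4.0] and down effects
#' from [0.25, 0.83] so planted ratios straddle the 1.1/0.9 thresholds
#' with margin.
#'
#' @param n_genes total genes (>= 10).
#' @param group_props named proportions for G1..G6 (sum <= 1; remainder
#'   are unpatterned NONE genes).
#' @param n_rats paired animals (>= 2).
#' @param sigma per-sample log-normal noise sd (>= 0).
#' @param up_range,down_range effect ranges for up / down steps.
#' @param baseline_meanlog,baseline_sdlog log-normal baseline parameters.
#' @return list of parameters for [generate_expression()].
#' @export
synth_params <- function(n_genes = 2000,
                         group_props = c(G1 = 3, G2 = 422, G3 = 2,
                                         G4 = 51, G5 = 25, G6 = 163) / 2000,
                         n_rats = 3,
                         sigma = 0.1,
                         up_range = c(1.2, 4.0),
                         down_range = c(0.25, 0.83),
                         baseline_meanlog = 3,
                         baseline_sdlog = 1.5) {
  if (n_genes < 10) stopf("n_genes must be >= 10")
  if (n_rats < 2) stopf("n_rats must be >= 2")
  if (sigma < 0) stopf("sigma must be >= 0")
  if (is.null(names(group_props)) || !all(names(group_props) %in% PATTERN_GROUPS))
    stopf("group_props must be named with G1..G6")
  if (sum(group_props) > 1 + 1e-12)
    stopf("group proportions sum to more than 1")
  list(n_genes = n_genes, group_props = group_props, n_rats = n_rats,
       sigma = sigma, up_range = up_range, down_range = down_range,
       baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog)
}

GROUP_DIRECTIONS <- list(G1 = c("up", "up"), G2 = c("up", "down"),
                         G3 = c("constant", "up"), G4 = c("constant", "down"),
                         G5 = c("down", "up"), G6 = c("down", "down"))

#' Generate a synthetic paired three-timepoint expression matrix
#'
#' Baseline CON means are log-normal per gene. For each planted gene the
#' MASA mean is baseline x e1 and the WD mean is MASA mean x e2, where e1
#' and e2 are drawn from the group's direction ranges (up from `up_range`,
#' down from `down_range`, constant exactly 1). Every rat-sample value is
#' its mean times exp(N(0, sigma^2)). Unpatterned (NONE) genes keep the
#' baseline mean at all timepoints. Deterministic given the seed.
#'
#' @param params from [synth_params()].
#' @param seed RNG seed.
#' @return list with `em` (an [expr_matrix()]) and `truth` (class
#'   `synthetic_truth`: data.frame gene/group/e1/e2 plus the parameters and
#'   seed as attributes).
#' @export
generate_expression <- function(params = synth_params(), seed = 1) {
  with_seed(seed, {
    n <- params$n_genes
    genes <- sprintf("G%05d", seq_len(n))
    counts <- round(params$group_props * n)
    grp <- rep("NONE", n)
    planted <- sample.int(n, sum(counts))
    grp[planted] <- rep(names(counts), counts)
    draw_effect <- function(dir, k) {
      switch(dir,
             up = stats::runif(k, params$up_range[1], params$up_range[2]),
             down = stats::runif(k, params$down_range[1], params$down_range[2]),
             constant = rep(1, k))
    }
    e1 <- rep(1, n); e2 <- rep(1, n)
    for (g in names(GROUP_DIRECTIONS)) {
      idx <- which(grp == g)
      if (length(idx) == 0) next
      e1[idx] <- draw_effect(GROUP_DIRECTIONS[[g]][1], length(idx))
      e2[idx] <- draw_effect(GROUP_DIRECTIONS[[g]][2], length(idx))
    }
    base <- stats::rlnorm(n, params$baseline_meanlog, params$baseline_sdlog)
    means <- cbind(CON = base, MASA = base * e1, WD = base * e1 * e2)
    nr <- params$n_rats
    cols <- as.vector(outer(TIMEPOINTS, seq_len(nr),
                            function(tp, r) paste0(tp, "_", r)))
    vals <- matrix(0, n, length(cols), dimnames = list(genes, cols))
    for (tp in TIMEPOINTS) {
      for (r in seq_len(nr)) {
        noise <- if (params$sigma > 0) exp(stats::rnorm(n, 0, params$sigma)) else 1
        vals[, paste0(tp, "_", r)] <- means[, tp] * noise
      }
    }
    truth <- data.frame(gene = genes, group = grp, e1 = e1, e2 = e2,
                        stringsAsFactors = FALSE)
    attr(truth, "params") <- params
    attr(truth, "seed") <- seed
    class(truth) <- c("synthetic_truth", "data.frame")
    list(em = expr_matrix(vals), truth = truth)
  })
}

#' Generate a modular interaction network for a synthetic truth
#'
#' Stochastic block model on the gene set: a gene's module is its planted
#' trajectory group; NONE genes form a background block whose pairs only
#' ever use the between-module probability. Each within-module pair is an
#' edge with probability `p_in`, every other pair with `p_out`. Qualifying
#' edges receive a combined score drawn uniformly from [400, 999]; in
#' addition, non-edges become sub-threshold decoy edges (score uniform in
#' [100, 399]) at rate `p_decoy`, so the downstream score filter is always
#' exercised.
#'
#' @param truth a `synthetic_truth` from [generate_expression()].
#' @param p_in within-module edge probability (0 <= p_out <= p_in <= 1).
#' @param p_out between-module edge probability.
#' @param p_decoy decoy rate among non-edges (default 0.05).
#' @param seed RNG seed.
#' @return data.frame with `node_a`, `node_b`, `combined_score` (both real
#'   and decoy edges; apply [read_string_links()] semantics or filter on
#'   score >= 400 to recover the real network).
#' @export
generate_network <- function(truth, p_in = 0.3, p_out = 0.03,
                             p_decoy = 0.05, seed = 1) {
  if (!(p_out >= 0 && p_in <= 1 && p_out <= p_in))
    stopf("need 0 <= p_out <= p_in <= 1")
  if (p_decoy < 0 || p_decoy > 1) stopf("p_decoy must be in [0, 1]")
  with_seed(seed, {
    genes <- truth$gene
    mod <- ifelse(truth$group == "NONE", "BG", truth$group)
    n <- length(genes)
    i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
    j <- sequence((n - 1L):1L, from = 2:n)
    same <- mod[i] == mod[j] & mod[i] != "BG"
    p <- ifelse(same, p_in, p_out)
    is_edge <- stats::runif(length(i)) < p
    is_decoy <- !is_edge & stats::runif(length(i)) < p_decoy
    sc <- integer(length(i))
    sc[is_edge] <- sample(400:999, sum(is_edge), replace = TRUE)
    sc[is_decoy] <- sample(100:399, sum(is_decoy), replace = TRUE)
    keep <- is_edge | is_decoy
    data.frame(node_a = genes[i[keep]], node_b = genes[j[keep]],
               combined_score = sc[keep], stringsAsFactors = FALSE)
  })
}

#' Plant a curated gene set on a network
#'
#' Samples `size` network nodes either uniformly or with probability
#' proportional to degree^beta (beta > 0 plants hub enrichment, the signal
#' the centrality-tier test is meant to detect). Off-network extra symbols
#' can be added to emulate a curated list much larger than its mapped
#' portion.
#'
#' @param net an igraph network.
#' @param rule `"uniform"` or `"degree"`.
#' @param size number of network nodes to plant (<= node count).
#' @param beta degree-bias exponent (>= 0; only used for `rule="degree"`).
#' @param n_extras off-network symbols appended (named OFFNET_xxxx).
#' @param seed RNG seed.
#' @return a [curated_gene_set()].
#' @export
plant_curated_set <- function(net, rule = c("uniform", "degree"), size,
                              beta = 2, n_extras = 0, seed = 1) {
  rule <- match.arg(rule)
  if (beta < 0) stopf("beta must be >= 0")
  nodes <- igraph::V(net)$name
  if (size > length(nodes)) stopf("size exceeds node count")
  with_seed(seed, {
    picked <- if (rule == "uniform") {
      sample(nodes, size)
    } else {
      sample(nodes, size, prob = igraph::degree(net)^beta)
    }
    extras <- if (n_extras > 0) sprintf("OFFNET_%05d", seq_len(n_extras)) else character(0)
    curated_gene_set(c(picked, extras),
                     stats::setNames(as.integer(size + n_extras), "SYN"))
  })
}

#' Generate and write a complete synthetic study bundle
#'
#' Produces expression table, interaction links, curated gene list and a
#' ground-truth sidecar in one directory, each stage's file a valid input
#' to the corresponding reader. Byte-identical for identical config+seed.
#'
#' @param dir output directory (created if needed).
#' @param params expression parameters from [synth_params()].
#' @param p_in,p_out,p_decoy network block-model parameters
#'   (see [generate_network()]).
#' @param score_min score filter used when inducing the ground-truth
#'   network for curated planting (default 400).
#' @param curated_rule,curated_size,curated_beta,curated_extras curated
#'   planting (see [plant_curated_set()]); `curated_size = NULL` defaults
#'   to 20% of ground-truth network nodes.
#' @param seed master seed; each stochastic component consumes a derived
#'   labeled sub-seed.
#' @return list with file `paths`, the `truth` table, the [expr_matrix()],
#'   edge table and curated set (invisibly reusable without re-reading).
#' @export
generate_study <- function(dir,
                           params = synth_params(),
                           p_in = 0.3, p_out = 0.03, p_decoy = 0.05,
                           score_min = 400,
                           curated_rule = "degree", curated_size = NULL,
                           curated_beta = 2, curated_extras = 0,
                           seed = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ex <- generate_expression(params, seed = derive_seed(seed, "expression"))
  edges <- generate_network(ex$truth, p_in = p_in, p_out = p_out,
                            p_decoy = p_decoy, seed = derive_seed(seed, "network"))
  seeds <- ex$truth$gene[ex$truth$group != "NONE"]
  qual <- edges[edges$combined_score >= score_min, , drop = FALSE]
  net <- build_network(qual, seeds,
                       groups = stats::setNames(ex$truth$group, ex$truth$gene))
  if (is.null(curated_size))
    curated_size <- max(1L, floor(0.2 * igraph::vcount(net)))
  curated <- plant_curated_set(net, rule = curated_rule, size = curated_size,
                               beta = curated_beta, n_extras = curated_extras,
                               seed = derive_seed(seed, "curated"))
  paths <- list(expression = file.path(dir, "expression.tsv"),
                links = file.path(dir, "links.tsv"),
                gene_set = file.path(dir, "curated_genes.txt"),
                truth = file.path(dir, "truth.tsv"))
  write_expression_table(ex$em, paths$expression)
  write_string_links(edges, paths$links)
  writeLines(paste(curated$symbols, "SYN"), paths$gene_set)
  utils::write.table(
    data.frame(gene = ex$truth$gene, group = ex$truth$group,
               e1 = sprintf("%.17g", ex$truth$e1),
               e2 = sprintf("%.17g", ex$truth$e2)),
    paths$truth, sep = "\t", quote = FALSE, row.names = FALSE)
  list(paths = paths, truth = ex$truth, em = ex$em, edges = edges,
       curated = curated, network = net)
}
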