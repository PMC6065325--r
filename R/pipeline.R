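#' Default pipeline thresholds
#'
#' Every tunable of the analysis in one place: ANOVA screening level,
#' fold-change direction thresholds, interaction-score cutoff, top
#' centrality tier fraction, zero-handling pseudocount.
#'
#' @param alpha ANOVA screening level (default 0.05, uncorrected).
#' @param up_thr,down_thr fold-change direction thresholds (1.1 / 0.9;
#'   boundary values classify as constant).
#' @param score_min inclusive interaction-score cutoff (default 400).
#' @param top_frac top centrality tier fraction (default 0.1).
#' @param pseudocount added to abundances before ratios (default 0:
#'   genes with any zero are excluded instead).
#' @return named list of thresholds.
#' @export
pipeline_thresholds <- function(alpha = 0.05, up_thr = 1.1, down_thr = 0.9,
                                score_min = 400, top_frac = 0.1,
                                pseudocount = 0) {
  stopifnot(alpha > 0, up_thr > down_thr, down_thr > 0,
            score_min >= 0, top_frac > 0, top_frac < 1, pseudocount >= 0)
  list(alpha = alpha, up_thr = up_thr, down_thr = down_thr,
       score_min = score_min, top_frac = top_frac, pseudocount = pseudocount)
}

#' Classify stage: expression table to patterned-gene table
#'
#' Reads the expression table, applies the ANOVA pre-filter, computes
#' per-rat ratios, classifies genes into pattern groups by per-rat
#' unanimity and writes `classified_genes.tsv` (all screened genes,
#' including NONE) and `group_census.tsv`.
#'
#' @param expression_path input expression TSV.
#' @param out_dir output directory.
#' @param thresholds from [pipeline_thresholds()].
#' @return invisibly, the classified data.frame.
#' @export
stage_classify <- function(expression_path, out_dir,
                           thresholds = pipeline_thresholds()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  em <- read_expression_table(expression_path)
  kept <- anova_filter(em, alpha = thresholds$alpha)
  if (length(kept) == 0) stopf("classify stage: no gene passes the ANOVA filter")
  prof <- ratio_profiles(em, genes = kept, pseudocount = thresholds$pseudocount)
  cls <- classify_genes(prof, up_thr = thresholds$up_thr,
                        down_thr = thresholds$down_thr)
  out <- cls
  out$norm_masa <- sprintf("%.17g", out$norm_masa)
  out$norm_wd <- sprintf("%.17g", out$norm_wd)
  utils::write.table(out, file.path(out_dir, "classified_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  census <- group_census(cls$group)
  utils::write.table(data.frame(group = names(census), n_genes = census),
                     file.path(out_dir, "group_census.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(cls)
}

read_classified <- function(out_dir) {
  utils::read.delim(file.path(out_dir, "classified_genes.tsv"),
                    stringsAsFactors = FALSE)
}

#' Network stage: induced network, centrality, link partition
#'
#' Reads the score-filtered interaction table and the classify stage's
#' output, induces the network on the patterned (non-NONE) genes, and
#' writes `network_edges.tsv`, `centrality.tsv` and `link_stats.json`
#' (within/between counts, likelihood score with its Mann-Whitney p, and
#' the label-permutation empirical p).
#'
#' @param links_path interaction table path.
#' @param out_dir directory holding the classify outputs; network outputs
#'   are written next to them.
#' @param thresholds from [pipeline_thresholds()].
#' @param n_perm label permutations for the empirical null (default 1000).
#' @param seed RNG seed for the permutation null.
#' @param id_map optional named identifier map (see [read_id_map()]).
#' @return invisibly, a list with the igraph network and centrality table.
#' @export
stage_network <- function(links_path, out_dir,
                          thresholds = pipeline_thresholds(),
                          n_perm = 1000, seed = 1, id_map = NULL) {
  cls <- read_classified(out_dir)
  seeds <- cls$gene[cls$group != "NONE"]
  edges <- read_string_links(links_path, score_min = thresholds$score_min,
                             id_map = id_map)
  net <- build_network(edges, seeds,
                       groups = stats::setNames(cls$group, cls$gene))
  utils::write.table(
    as.data.frame(igraph::as_edgelist(net)) |>
      stats::setNames(c("node_a", "node_b")),
    file.path(out_dir, "network_edges.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  bc <- betweenness_centrality(net)
  bc_out <- bc
  bc_out$bc_raw <- sprintf("%.17g", bc_out$bc_raw)
  bc_out$bc <- sprintf("%.17g", bc_out$bc)
  utils::write.table(bc_out, file.path(out_dir, "centrality.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  lp <- count_links_by_group(net)
  ls <- likelihood_score(net)
  pn <- permutation_null(net, n_perm = n_perm, seed = derive_seed(seed, "permnull"))
  stats_json <- list(
    n_nodes = igraph::vcount(net), n_links = igraph::ecount(net),
    within_total = lp$within_total, between_total = lp$between_total,
    within_pct = 100 * lp$within_total / igraph::ecount(net),
    likelihood_score = ls$score, mwu_p = ls$mwu_p,
    permutation_p = pn$p_empirical, n_perm = n_perm)
  jsonlite::write_json(stats_json, file.path(out_dir, "link_stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(network = net, centrality = bc, link_stats = stats_json))
}

read_centrality <- function(out_dir) {
  bc <- utils::read.delim(file.path(out_dir, "centrality.tsv"),
                          stringsAsFactors = FALSE)
  class(bc) <- c("centrality_table", "data.frame")
  bc
}

#' Enrichment stage: curated set mapping and top-tier tests
#'
#' Reads the curated gene list and the network stage's centrality table,
#' and writes `enrichment.json` with the mapping rate, curated/other mean
#' betweenness and MWU p, top-tier fold-enrichment and hypergeometric p.
#'
#' @param gene_set_path curated gene list path.
#' @param out_dir directory holding the network outputs.
#' @param thresholds from [pipeline_thresholds()].
#' @param id_map optional named identifier map.
#' @return invisibly, the enrichment list.
#' @export
stage_enrich <- function(gene_set_path, out_dir,
                         thresholds = pipeline_thresholds(), id_map = NULL) {
  curated <- read_gene_set(gene_set_path, id_map = id_map)
  bc <- read_centrality(out_dir)
  flags <- stats::setNames(bc$node %in% curated$symbols, bc$node)
  K <- sum(flags); N <- nrow(bc)
  if (K == 0) stopf("enrich stage: no curated gene maps onto the network")
  tier <- top_fraction(bc, thresholds$top_frac)
  k <- sum(flags[tier]); m <- length(tier)
  cmp <- compare_centrality(bc, flags)
  res <- list(N = N, K = K, m = m, k = k,
              mapping_rate = K / length(curated$symbols),
              fold_enrichment = fold_enrichment(k, m, K, N),
              hypergeom_p = hypergeom_enrichment(k, m, K, N),
              mean_bc_curated = cmp$mean_curated,
              mean_bc_other = cmp$mean_other,
              bc_mwu_p = cmp$mwu_p)
  jsonlite::write_json(res, file.path(out_dir, "enrichment.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

#' Report stage: ranked candidate table and run summary
#'
#' Joins the top centrality tier to groups, curated flags and normalized
#' ratios, writing `candidates.tsv` and a machine-readable `summary.json`
#' aggregating every stage's headline numbers.
#'
#' @param gene_set_path curated gene list path (for the flags).
#' @param out_dir directory holding all prior stage outputs.
#' @param thresholds from [pipeline_thresholds()].
#' @param id_map optional named identifier map.
#' @return invisibly, the candidate data.frame.
#' @export
stage_report <- function(gene_set_path, out_dir,
                         thresholds = pipeline_thresholds(), id_map = NULL) {
  cls <- read_classified(out_dir)
  bc <- read_centrality(out_dir)
  curated <- read_gene_set(gene_set_path, id_map = id_map)
  flags <- stats::setNames(bc$node %in% curated$symbols, bc$node)
  cand <- select_candidates(bc, cls, flags, frac = thresholds$top_frac)
  write_candidate_table(cand, file.path(out_dir, "candidates.tsv"))
  census <- utils::read.delim(file.path(out_dir, "group_census.tsv"))
  summary <- list(
    thresholds = thresholds,
    group_census = stats::setNames(as.list(census$n_genes), census$group),
    link_stats = jsonlite::read_json(file.path(out_dir, "link_stats.json")),
    enrichment = jsonlite::read_json(file.path(out_dir, "enrichment.json")),
    n_candidates = nrow(cand),
    top_candidates = utils::head(cand$gene, 3))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(cand)
}

#' Run the full prioritization pipeline
#'
#' Chains all stages: (optional) synthetic-bundle generation, pattern
#' classification, network construction and topology, curated-set
#' enrichment, and the ranked candidate report. Either provide the three
#' input files, or `synthesis = TRUE` to generate a synthetic bundle under
#' `out_dir/inputs` first. All stochastic steps (generator, permutation
#' null) consume sub-seeds derived from the single `seed`, so a rerun with
#' the same configuration is byte-identical.
#'
#' @param out_dir output directory.
#' @param expression,links,gene_set input file paths (required unless
#'   `synthesis = TRUE`).
#' @param id_map optional path to a symbol/protein-ID mapping TSV.
#' @param synthesis generate inputs with [generate_study()]?
#' @param synthesis_args list of arguments passed on to [generate_study()].
#' @param thresholds from [pipeline_thresholds()].
#' @param n_perm label permutations for the null (default 1000).
#' @param seed master seed.
#' @return invisibly, list with the summary and the candidate table.
#' @export
run_pipeline <- function(out_dir,
                         expression = NULL, links = NULL, gene_set = NULL,
                         id_map = NULL,
                         synthesis = FALSE, synthesis_args = list(),
                         thresholds = pipeline_thresholds(),
                         n_perm = 1000, seed = 1) {
  have_inputs <- !is.null(expression) || !is.null(links) || !is.null(gene_set)
  if (synthesis && have_inputs)
    stopf("give either input paths or synthesis = TRUE, not both")
  if (!synthesis && (is.null(expression) || is.null(links) || is.null(gene_set)))
    stopf("expression, links and gene_set paths are all required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (synthesis) {
    bundle <- do.call(generate_study,
                      c(list(dir = file.path(out_dir, "inputs"),
                             seed = derive_seed(seed, "study")),
                        synthesis_args))
    expression <- bundle$paths$expression
    links <- bundle$paths$links
    gene_set <- bundle$paths$gene_set
  }
  map <- if (!is.null(id_map)) read_id_map(id_map) else NULL
  stage_classify(expression, out_dir, thresholds)
  stage_network(links, out_dir, thresholds, n_perm = n_perm,
                seed = seed, id_map = map)
  stage_enrich(gene_set, out_dir, thresholds, id_map = map)
  cand <- stage_report(gene_set, out_dir, thresholds, id_map = map)
  summary <- jsonlite::read_json(file.path(out_dir, "summary.json"))
  invisible(list(summary = summary, candidates = cand))
}
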