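#' Map a curated gene set onto the network
#'
#' @param net an igraph network with named vertices (identifiers already
#'   normalized).
#' @param curated a [curated_gene_set()].
#' @return list with `flags` (named logical over nodes) and `mapping_rate`
#'   (mapped nodes / curated list size, a fraction).
#' @export
map_gene_set <- function(net, curated) {
  stopifnot(inherits(curated, "curated_gene_set"))
  nodes <- igraph::V(net)$name
  flags <- stats::setNames(nodes %in% curated$symbols, nodes)
  list(flags = flags, mapping_rate = sum(flags) / length(curated$symbols))
}

#' Compare centrality between curated and other genes
#'
#' Mean normalized betweenness in each class plus a two-sided
#' Mann-Whitney U p-value.
#'
#' @param bc_table a `centrality_table` from [betweenness_centrality()].
#' @param flags named logical vector over the same nodes (curated = TRUE).
#' @param mode passed to [mann_whitney_u()] (default `"auto"`).
#' @return list with `mean_curated`, `mean_other`, `mwu_p`.
#' @export
compare_centrality <- function(bc_table, flags, mode = "auto") {
  f <- flags[bc_table$node]
  if (anyNA(f)) stopf("flags missing for some nodes")
  if (!any(f) || all(f)) stopf("need at least one curated and one other gene")
  x <- bc_table$bc[f]; y <- bc_table$bc[!f]
  list(mean_curated = mean(x), mean_other = mean(y),
       mwu_p = mann_whitney_u(x, y, mode = mode)$p_value)
}

#' Top centrality tier
#'
#' The m = floor(frac * N) nodes (at least 1) with the largest normalized
#' betweenness, under the centrality table's tie rule (higher degree, then
#' lexicographic ID); boundary ties beyond m are excluded so the tier size
#' is exactly m.
#'
#' @param bc_table a `centrality_table`.
#' @param frac tier fraction in (0, 1) (default 0.1).
#' @return character vector of tier node IDs (in rank order).
#' @export
top_fraction <- function(bc_table, frac = 0.1) {
  if (!(frac > 0 && frac < 1)) stopf("frac must be in (0, 1)")
  N <- nrow(bc_table)
  if (N == 0) stopf("empty centrality table")
  m <- max(1L, floor(frac * N))
  bc_table$node[order(bc_table$rank)][seq_len(m)]
}

#' Fold-enrichment of curated genes in the top tier
#'
#' (k/m) / (K/N): the curated proportion in the tier relative to the
#' curated proportion in the whole network.
#'
#' @param k curated nodes in the tier.
#' @param m tier size.
#' @param K curated nodes in the network.
#' @param N network size.
#' @return dimensionless fold-enrichment.
#' @export
fold_enrichment <- function(k, m, K, N) {
  if (m <= 0 || K <= 0) stopf("fold enrichment undefined for m = 0 or K = 0")
  if (k > min(m, K) || m > N || K > N) stopf("inconsistent enrichment counts")
  (k / m) / (K / N)
}

#' Hypergeometric over-representation test for the top tier
#'
#' One-sided P(X >= k) for X ~ Hypergeometric(N, K, m), the standard
#' over-representation direction; delegates to [hypergeom_sf()].
#'
#' @inheritParams fold_enrichment
#' @return p-value in (0, 1].
#' @export
hypergeom_enrichment <- function(k, m, K, N) hypergeom_sf(k, N, K, m)

#' Full enrichment result for a curated set on a network
#'
#' Composes mapping, centrality comparison, top-tier fold-enrichment and
#' the hypergeometric test into one record.
#'
#' @param net an igraph network.
#' @param bc_table its `centrality_table`.
#' @param curated a [curated_gene_set()].
#' @param frac top-tier fraction (default 0.1).
#' @return object of class `enrichment_result`: list with `N`, `K`, `m`,
#'   `k`, `mapping_rate`, `fold_enrichment`, `hypergeom_p`, `mean_curated`,
#'   `mean_other`, `bc_mwu_p`.
#' @export
enrichment_result <- function(net, bc_table, curated, frac = 0.1) {
  mp <- map_gene_set(net, curated)
  N <- nrow(bc_table)
  K <- sum(mp$flags)
  if (K == 0) stopf("no curated gene maps onto the network")
  tier <- top_fraction(bc_table, frac)
  m <- length(tier)
  k <- sum(mp$flags[tier])
  cmp <- if (K < N) {
    compare_centrality(bc_table, mp$flags)
  } else {
    # every node curated: the centrality contrast is undefined
    list(mean_curated = mean(bc_table$bc), mean_other = NA_real_, mwu_p = NA_real_)
  }
  structure(list(N = N, K = K, m = m, k = k,
                 mapping_rate = mp$mapping_rate,
                 fold_enrichment = fold_enrichment(k, m, K, N),
                 hypergeom_p = hypergeom_enrichment(k, m, K, N),
                 mean_curated = cmp$mean_curated,
                 mean_other = cmp$mean_other,
                 bc_mwu_p = cmp$mwu_p,
                 flags = mp$flags),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "enrichment_result: %d/%d curated in network (mapping rate %.1f%%)\n",
    x$K, x$N, 100 * x$mapping_rate))
  cat(sprintf("  top tier: %d of %d curated; fold-enrichment %.3f (hypergeom p = %.3g)\n",
              x$k, x$m, x$fold_enrichment, x$hypergeom_p))
  cat(sprintf("  mean BC curated %.4f vs other %.4f (MWU p = %.3g)\n",
              x$mean_curated, x$mean_other, x$bc_mwu_p))
  invisible(x)
}

#' Select ranked top-tier candidate genes
#'
#' Joins the top centrality tier to pattern groups, curated flags and the
#' normalized MASA/WD summary ratios, producing the ranked candidate
#' report consumed by [write_candidate_table()].
#'
#' @param bc_table a `centrality_table` for the network.
#' @param classified data.frame from [classify_genes()] (columns `gene`,
#'   `group`, `norm_masa`, `norm_wd`).
#' @param flags named logical curated flags from [map_gene_set()].
#' @param frac top-tier fraction (default 0.1).
#' @return data.frame with columns `rank`, `gene`, `bc`, `curated_flag`,
#'   `group`, `norm_masa`, `norm_wd`, ranks contiguous from 1.
#' @export
select_candidates <- function(bc_table, classified, flags, frac = 0.1) {
  tier <- top_fraction(bc_table, frac)
  idx <- match(tier, normalize_id(classified$gene))
  if (anyNA(idx))
    stopf("no ratio profile for node(s): %s", paste(tier[is.na(idx)], collapse = ", "))
  fl <- flags[tier]
  if (anyNA(fl)) stopf("no curated flag for node(s): %s",
                       paste(tier[is.na(fl)], collapse = ", "))
  data.frame(rank = seq_along(tier),
             gene = tier,
             bc = bc_table$bc[match(tier, bc_table$node)],
             curated_flag = unname(fl),
             group = classified$group[idx],
             norm_masa = classified$norm_masa[idx],
             norm_wd = classified$norm_wd[idx],
             stringsAsFactors = FALSE)
}
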