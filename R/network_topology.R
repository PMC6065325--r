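#' Build the induced functional-association network on seed genes
#'
#' Restricts a score-filtered edge list to the patterned "seed" genes,
#' simplifies it (no self-loops, no parallel edges) and drops seeds with no
#' qualifying edge among the other seeds — the step that shrinks the
#' patterned gene list to the connected node set actually analysed.
#'
#' @param edges data.frame with `node_a`, `node_b` (already score-filtered,
#'   e.g. from [read_string_links()]).
#' @param seed_genes character vector of node identifiers to induce on.
#' @param groups optional named character vector gene -> pattern group.
#' @param curated optional character vector of curated gene symbols; stored
#'   as a logical vertex attribute.
#' @return an igraph object (undirected, simple) with vertex attributes
#'   `group` and `curated`.
#' @export
build_network <- function(edges, seed_genes, groups = NULL, curated = NULL) {
  seed_genes <- unique(normalize_id(seed_genes))
  a <- normalize_id(edges$node_a); b <- normalize_id(edges$node_b)
  keep <- a %in% seed_genes & b %in% seed_genes & a != b
  if (!any(keep)) stopf("no edges among the seed genes: induced network is empty")
  g <- igraph::graph_from_data_frame(
    data.frame(from = a[keep], to = b[keep], stringsAsFactors = FALSE),
    directed = FALSE)
  g <- igraph::simplify(g)
  nodes <- igraph::V(g)$name
  grp <- rep(NA_character_, length(nodes))
  if (!is.null(groups)) {
    names(groups) <- normalize_id(names(groups))
    grp <- unname(groups[nodes])
  }
  igraph::V(g)$group <- grp
  igraph::V(g)$curated <- if (is.null(curated)) rep(FALSE, length(nodes))
                          else nodes %in% normalize_id(curated)
  g
}

# Adjacency list of integer neighbor indices.
adj_index_list <- function(net) {
  lapply(igraph::as_adj_list(net, mode = "all"), as.integer)
}

rank_nodes <- function(node, bc, degree) {
  # tie rule: larger bc, then larger degree, then lexicographic ID
  ord <- order(-bc, -degree, node)
  rk <- integer(length(node)); rk[ord] <- seq_along(node)
  rk
}

#' Betweenness centrality of every node
#'
#' Shortest-path betweenness computed by Brandes' dependency accumulation
#' over single-source BFS (edges are unweighted; interaction scores act
#' only as the upstream edge filter). Raw BC for node v is the sum over
#' unordered node pairs (s, t), s != v != t, of the fraction of shortest
#' s-t paths passing through v; pairs in other components contribute 0.
#' Normalized BC divides by (n-1)(n-2)/2 with n the total node count, so a
#' star center scores 1. Ranks break ties by higher degree, then
#' lexicographic ID.
#'
#' @param net an igraph network from [build_network()].
#' @return object of class `centrality_table`: data.frame with columns
#'   `node`, `degree`, `bc_raw`, `bc` (normalized), `rank`, ordered by rank.
#' @export
betweenness_centrality <- function(net) {
  n <- igraph::vcount(net)
  nodes <- igraph::V(net)$name
  adj <- adj_index_list(net)
  bc <- numeric(n)
  for (s in seq_len(n)) {
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(-1L, n); dist[s] <- 0L
    preds <- vector("list", n)
    queue <- integer(n); queue[1] <- s
    head <- 1L; tail <- 1L
    while (head <= tail) {
      v <- queue[head]; head <- head + 1L
      dv <- dist[v]
      for (w in adj[[v]]) {
        if (dist[w] < 0L) {
          tail <- tail + 1L; queue[tail] <- w
          dist[w] <- dv + 1L
        }
        if (dist[w] == dv + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (w in queue[tail:1]) {          # reverse BFS order: farthest first
      coeff <- (1 + delta[w]) / sigma[w]
      for (v in preds[[w]]) delta[v] <- delta[v] + sigma[v] * coeff
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  bc_raw <- bc / 2                       # each unordered pair counted twice
  norm <- if (n >= 3) (n - 1) * (n - 2) / 2 else Inf
  bc_n <- bc_raw / norm
  deg <- as.integer(igraph::degree(net))
  out <- data.frame(node = nodes, degree = deg, bc_raw = bc_raw, bc = bc_n,
                    rank = rank_nodes(nodes, bc_n, deg),
                    stringsAsFactors = FALSE)
  out <- out[order(out$rank), ]
  rownames(out) <- NULL
  class(out) <- c("centrality_table", "data.frame")
  out
}

#' Betweenness centrality by exhaustive shortest-path enumeration
#'
#' Independent oracle for [betweenness_centrality()]: for every node pair
#' all shortest paths are enumerated explicitly by walking the BFS
#' predecessor DAG, and each interior node of each path receives
#' 1/(number of shortest paths for that pair). Same normalization and tie
#' rule. Restricted to small graphs.
#'
#' @param net an igraph network.
#' @param max_nodes refuse graphs larger than this (default 12).
#' @return a `centrality_table` (see [betweenness_centrality()]).
#' @export
brute_force_betweenness <- function(net, max_nodes = 12) {
  n <- igraph::vcount(net)
  if (n > max_nodes) stopf("brute-force oracle limited to %d nodes", max_nodes)
  nodes <- igraph::V(net)$name
  adj <- adj_index_list(net)
  bc_raw <- numeric(n)
  bfs_preds <- function(s) {
    dist <- rep(-1L, n); dist[s] <- 0L
    preds <- vector("list", n)
    q <- s
    while (length(q) > 0) {
      v <- q[1]; q <- q[-1]
      for (w in adj[[v]]) {
        if (dist[w] < 0L) { dist[w] <- dist[v] + 1L; q <- c(q, w) }
        if (dist[w] == dist[v] + 1L) preds[[w]] <- c(preds[[w]], v)
      }
    }
    list(dist = dist, preds = preds)
  }
  all_paths <- function(preds, s, t) {
    if (t == s) return(list(s))
    out <- list()
    for (p in preds[[t]]) {
      for (pp in all_paths(preds, s, p)) out <- c(out, list(c(pp, t)))
    }
    out
  }
  for (s in seq_len(n - 1)) {
    info <- bfs_preds(s)
    for (t in (s + 1):n) {
      if (info$dist[t] < 0L) next
      paths <- all_paths(info$preds, s, t)
      w <- 1 / length(paths)
      for (p in paths) {
        interior <- p[-c(1, length(p))]
        bc_raw[interior] <- bc_raw[interior] + w
      }
    }
  }
  norm <- if (n >= 3) (n - 1) * (n - 2) / 2 else Inf
  deg <- as.integer(igraph::degree(net))
  bc_n <- bc_raw / norm
  out <- data.frame(node = nodes, degree = deg, bc_raw = bc_raw, bc = bc_n,
                    rank = rank_nodes(nodes, bc_n, deg),
                    stringsAsFactors = FALSE)
  out <- out[order(out$rank), ]
  rownames(out) <- NULL
  class(out) <- c("centrality_table", "data.frame")
  out
}

node_groups <- function(net) {
  grp <- igraph::V(net)$group
  if (is.null(grp) || anyNA(grp))
    stopf("every network node needs a group label for link partitioning")
  grp
}

edge_endpoint_idx <- function(net) {
  el <- igraph::as_edgelist(net, names = FALSE)
  list(a = el[, 1], b = el[, 2])
}

#' Count network links within and between pattern groups
#'
#' @param net a group-labeled igraph network.
#' @return object of class `link_partition`: list with `counts` (symmetric
#'   group x group matrix; diagonal = within-group link counts),
#'   `within_total`, `between_total`.
#' @export
count_links_by_group <- function(net) {
  grp <- node_groups(net)
  lev <- if (all(grp %in% PATTERN_GROUPS)) PATTERN_GROUPS else sort(unique(grp))
  e <- edge_endpoint_idx(net)
  ga <- factor(grp[e$a], levels = lev)
  gb <- factor(grp[e$b], levels = lev)
  counts <- matrix(0L, length(lev), length(lev), dimnames = list(lev, lev))
  for (i in seq_along(ga)) {
    counts[ga[i], gb[i]] <- counts[ga[i], gb[i]] + 1L
    if (ga[i] != gb[i]) counts[gb[i], ga[i]] <- counts[gb[i], ga[i]] + 1L
  }
  within_total <- sum(diag(counts))
  structure(list(counts = counts,
                 within_total = within_total,
                 between_total = igraph::ecount(net) - within_total),
            class = "link_partition")
}

#' @export
print.link_partition <- function(x, ...) {
  tot <- x$within_total + x$between_total
  cat(sprintf("link_partition: %d links, %d within (%.1f%%), %d between\n",
              tot, x$within_total, 100 * x$within_total / tot, x$between_total))
  invisible(x)
}

#' Observed within-group neighbor fraction per gene
#'
#' observed_i = (number of neighbors of i in i's group) / degree(i).
#'
#' @param net a group-labeled igraph network (all degrees >= 1).
#' @return named numeric vector over nodes.
#' @export
within_fraction_per_gene <- function(net) {
  grp <- node_groups(net)
  deg <- igraph::degree(net)
  if (any(deg < 1)) stopf("isolated node present; build_network drops these")
  e <- edge_endpoint_idx(net)
  same <- grp[e$a] == grp[e$b]
  cnt <- tabulate(c(e$a[same], e$b[same]), nbins = igraph::vcount(net))
  stats::setNames(cnt / deg, igraph::V(net)$name)
}

#' Expected within-group neighbor fraction per gene
#'
#' Random-neighbor null: a random other node is a same-group neighbor with
#' probability (n_g - 1)/(N - 1), where n_g is the size of the gene's group
#' among the N network nodes.
#'
#' @param net a group-labeled igraph network.
#' @return named numeric vector over nodes.
#' @export
expected_within_fraction <- function(net) {
  grp <- node_groups(net)
  N <- igraph::vcount(net)
  sizes <- table(grp)
  stats::setNames((as.numeric(sizes[grp]) - 1) / (N - 1), igraph::V(net)$name)
}

#' Within-group link likelihood score
#'
#' The ratio of the mean observed within-group neighbor fraction to its
#' random-labeling expectation, with a two-sided Mann-Whitney U test
#' comparing the two per-gene vectors (unpaired by default; set
#' `paired = TRUE` for a Wilcoxon signed-rank alternative).
#'
#' @param net a group-labeled igraph network.
#' @param paired use a paired signed-rank test instead of the unpaired MWU.
#' @return list with `score`, `mwu_p`, `observed`, `expected`.
#' @export
likelihood_score <- function(net, paired = FALSE) {
  obs <- within_fraction_per_gene(net)
  expd <- expected_within_fraction(net)
  if (mean(expd) == 0) stopf("expected within-fraction is identically zero")
  p <- if (paired) {
    stats::wilcox.test(obs, expd, paired = TRUE, exact = FALSE)$p.value
  } else {
    mann_whitney_u(obs, expd, mode = "normal")$p_value
  }
  list(score = mean(obs) / mean(expd), mwu_p = p,
       observed = obs, expected = expd)
}

# likelihood score from precomputed edge indices, degrees and a label vector
score_for_labels <- function(e, deg, labels, N) {
  same <- labels[e$a] == labels[e$b]
  cnt <- tabulate(c(e$a[same], e$b[same]), nbins = N)
  obs <- cnt / deg
  sizes <- table(labels)
  expd <- (as.numeric(sizes[labels]) - 1) / (N - 1)
  mean(obs) / mean(expd)
}

#' Permutation null for the likelihood score
#'
#' Permutes group labels over nodes (preserving group sizes), recomputes
#' the likelihood score each time, and reports the empirical upper-tail
#' p-value (1 + #\{null >= observed\})/(n_perm + 1).
#'
#' @param net a group-labeled igraph network.
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed; the same seed reproduces the same null vector.
#' @return list with `null` (numeric vector of permuted scores),
#'   `observed` and `p_empirical`.
#' @export
permutation_null <- function(net, n_perm = 1000, seed = 1) {
  if (n_perm < 100) stopf("n_perm must be >= 100 for a usable null")
  grp <- node_groups(net)
  N <- igraph::vcount(net)
  deg <- igraph::degree(net)
  e <- edge_endpoint_idx(net)
  observed <- score_for_labels(e, deg, grp, N)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      score_for_labels(e, deg, sample(grp), N)
    }, 0)
  })
  list(null = null, observed = observed,
       p_empirical = (1 + sum(null >= observed)) / (n_perm + 1))
}
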