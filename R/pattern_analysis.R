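#' Pre-filter genes by one-way ANOVA across timepoints
#'
#' Retains genes whose abundances differ across the three timepoint groups
#' at p < alpha (uncorrected, as is usual for this screening step), using
#' [one_way_anova()]. Genes with zero within-group variance but unequal
#' means are retained (p treated as 0); genes with all values identical are
#' dropped (p = 1).
#'
#' @param em an [expr_matrix()].
#' @param alpha significance level (default 0.05).
#' @return character vector of retained gene IDs.
#' @export
anova_filter <- function(em, alpha = 0.05) {
  stopifnot(inherits(em, "expr_matrix"))
  con <- tp_values(em, "CON"); masa <- tp_values(em, "MASA"); wd <- tp_values(em, "WD")
  p <- vapply(seq_len(nrow(em$values)), function(i) {
    one_way_anova(list(con[i, ], masa[i, ], wd[i, ]))$p_value
  }, 0)
  rownames(em$values)[p < alpha]
}

#' Per-rat abundance ratio profiles
#'
#' For each gene and rat computes r1 = MASA/CON and r2 = WD/MASA, plus the
#' reported summary columns norm_masa = mean over rats of MASA/CON and
#' norm_wd = mean over rats of WD/CON (both relative to CON, the form the
#' candidate tables print; the classification's second direction uses
#' WD/MASA = norm_wd-style ratio divided by the MASA ratio per rat).
#'
#' Genes with a zero abundance at any timepoint are excluded before ratio
#' computation when `pseudocount = 0`, keeping all ratios finite and
#' positive; a positive pseudocount is added to every value instead.
#'
#' @param em an [expr_matrix()].
#' @param genes optional subset of gene IDs (e.g. the [anova_filter()]
#'   output); default all genes.
#' @param pseudocount nonnegative value added to all abundances (default 0).
#' @return object of class `ratio_profiles`: list with `gene`, matrices
#'   `r1`, `r2` (genes x rats) and data.frame `norm` (gene, norm_masa,
#'   norm_wd).
#' @export
ratio_profiles <- function(em, genes = NULL, pseudocount = 0) {
  stopifnot(inherits(em, "expr_matrix"))
  if (pseudocount < 0) stopf("pseudocount must be nonnegative")
  v <- em$values
  if (!is.null(genes)) {
    miss <- setdiff(genes, rownames(v))
    if (length(miss) > 0) stopf("unknown gene(s): %s", paste(miss, collapse = ", "))
    v <- v[genes, , drop = FALSE]
  }
  v <- v + pseudocount
  em2 <- em; em2$values <- v
  con <- tp_values(em2, "CON"); masa <- tp_values(em2, "MASA"); wd <- tp_values(em2, "WD")
  ok <- rowSums(con == 0 | masa == 0 | wd == 0) == 0
  con <- con[ok, , drop = FALSE]; masa <- masa[ok, , drop = FALSE]; wd <- wd[ok, , drop = FALSE]
  r1 <- masa / con
  r2 <- wd / masa
  norm <- data.frame(gene = rownames(con),
                     norm_masa = rowMeans(masa / con),
                     norm_wd = rowMeans(wd / con),
                     stringsAsFactors = FALSE)
  structure(list(gene = rownames(con), r1 = r1, r2 = r2, norm = norm,
                 n_excluded = sum(!ok)),
            class = "ratio_profiles")
}

#' Classify a fold-change ratio as up, constant or down
#'
#' A ratio above `up_thr` is "up", below `down_thr` is "down", otherwise
#' "constant". Boundary values classify as constant (the thresholds are
#' strict: change must exceed 1.1-fold or fall below 0.9-fold).
#'
#' @param ratio positive numeric vector of abundance ratios.
#' @param up_thr upper threshold (default 1.1).
#' @param down_thr lower threshold (default 0.9).
#' @return character vector in `{"up","constant","down"}`.
#' @export
classify_direction <- function(ratio, up_thr = 1.1, down_thr = 0.9) {
  if (!(up_thr > down_thr) || down_thr <= 0)
    stopf("need up_thr > down_thr > 0")
  if (anyNA(ratio) || any(ratio <= 0))
    stopf("ratios must be positive and non-missing")
  out <- rep("constant", length(ratio))
  out[ratio > up_thr] <- "up"
  out[ratio < down_thr] <- "down"
  out
}

PATTERN_GROUPS <- c("G1", "G2", "G3", "G4", "G5", "G6")

#' Classify a (MASA/CON, WD/MASA) ratio pair into a pattern group
#'
#' The six trajectory groups are defined by the direction of the first
#' ratio (MASA/CON) followed by the second (WD/MASA): G1 = up-up,
#' G2 = up-down, G3 = constant-up, G4 = constant-down, G5 = down-up,
#' G6 = down-down. The three remaining direction pairs with a constant
#' second step — (up, constant), (down, constant), (constant, constant) —
#' are not trajectory groups and map to NONE.
#'
#' @param r1 positive numeric vector, MASA/CON ratios.
#' @param r2 positive numeric vector, WD/MASA ratios.
#' @inheritParams classify_direction
#' @return character vector in `{"G1",...,"G6","NONE"}`.
#' @export
classify_pattern <- function(r1, r2, up_thr = 1.1, down_thr = 0.9) {
  d1 <- classify_direction(r1, up_thr, down_thr)
  d2 <- classify_direction(r2, up_thr, down_thr)
  key <- paste(d1, d2, sep = "-")
  map <- c("up-up" = "G1", "up-down" = "G2",
           "constant-up" = "G3", "constant-down" = "G4",
           "down-up" = "G5", "down-down" = "G6",
           "up-constant" = "NONE", "down-constant" = "NONE",
           "constant-constant" = "NONE")
  unname(map[key])
}

#' Consensus pattern group across rats
#'
#' A gene carries a pattern only when every rat shows the same non-NONE
#' group; any disagreement, or a NONE in any rat, yields NONE.
#'
#' @param per_rat_groups character vector of per-rat groups for one gene,
#'   or a genes x rats character matrix.
#' @return a single group (vector input) or one group per row (matrix).
#' @export
consensus_pattern <- function(per_rat_groups) {
  if (is.matrix(per_rat_groups)) {
    return(apply(per_rat_groups, 1, consensus_pattern))
  }
  if (length(per_rat_groups) == 0) stopf("no per-rat groups given")
  g <- unique(per_rat_groups)
  if (length(g) == 1 && g != "NONE") g else "NONE"
}

#' Classify all genes in a ratio-profile set
#'
#' Applies [classify_pattern()] per rat and takes the unanimity consensus
#' (default), or classifies the rat-mean ratios directly
#' (`method = "mean"`, using norm_masa and norm_wd/norm_masa).
#'
#' @param profiles a [ratio_profiles()] object.
#' @inheritParams classify_direction
#' @param method `"consensus"` (per-rat unanimity, default) or `"mean"`.
#' @return data.frame with columns `gene`, `group`, `norm_masa`, `norm_wd`.
#' @export
classify_genes <- function(profiles, up_thr = 1.1, down_thr = 0.9,
                           method = c("consensus", "mean")) {
  stopifnot(inherits(profiles, "ratio_profiles"))
  method <- match.arg(method)
  if (method == "consensus") {
    per_rat <- matrix("NONE", nrow = length(profiles$gene), ncol = ncol(profiles$r1))
    for (j in seq_len(ncol(profiles$r1))) {
      per_rat[, j] <- classify_pattern(profiles$r1[, j], profiles$r2[, j],
                                       up_thr, down_thr)
    }
    grp <- consensus_pattern(per_rat)
  } else {
    grp <- classify_pattern(profiles$norm$norm_masa,
                            profiles$norm$norm_wd / profiles$norm$norm_masa,
                            up_thr, down_thr)
  }
  data.frame(gene = profiles$gene, group = unname(grp),
             norm_masa = profiles$norm$norm_masa,
             norm_wd = profiles$norm$norm_wd,
             stringsAsFactors = FALSE)
}

#' Census of pattern groups
#'
#' @param groups character vector of group labels (`"G1"`..`"G6"`, `"NONE"`).
#' @return named integer vector over G1..G6 (NONE excluded; zero counts
#'   kept).
#' @export
group_census <- function(groups) {
  tab <- table(factor(groups, levels = PATTERN_GROUPS))
  stats::setNames(as.integer(tab), PATTERN_GROUPS)
}
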