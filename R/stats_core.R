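#' Mann-Whitney U test
#'
#' Two-sample rank-sum test. In `exact` mode the full permutation
#' distribution of U (all ways of assigning the pooled values to the two
#' samples) is computed — by the rank-sum counting recursion when the
#' pooled values are tie-free, by explicit enumeration otherwise — and the
#' two-sided p is twice the smaller tail probability, capped at 1. In
#' `normal` mode the large-sample normal approximation is used with tie
#' correction and a 0.5 continuity correction. `auto` picks `exact` when
#' the combined sample size is at most 12 and there are no ties, `normal`
#' otherwise.
#'
#' @param x,y numeric samples (each nonempty).
#' @param mode one of `"auto"`, `"exact"`, `"normal"`.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return list with `statistic` (U for the first sample), `p_value`,
#'   `method` and sample sizes `n1`, `n2`.
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "normal"),
                           alternative = c("two.sided", "less", "greater")) {
  mode <- match.arg(mode)
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0) stopf("both samples must be nonempty")
  if (anyNA(c(x, y))) stopf("missing values in samples")
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(pooled) > 0
  if (mode == "auto") mode <- if (n1 + n2 <= 12 && !has_ties) "exact" else "normal"

  if (mode == "exact") {
    if (!has_ties) {
      # counting recursion: ways to pick n1 of the ranks 1..n with each
      # possible rank sum; equivalent to full enumeration, feasible at n ~ 30
      n <- n1 + n2
      smax <- sum((n - n1 + 1):n)
      ways <- matrix(0, n1 + 1, smax + 1)   # ways[j+1, s+1]: j ranks, sum s
      ways[1, 1] <- 1
      for (v in seq_len(n)) {
        for (j in min(v, n1):1) {
          s <- smax:v
          ways[j + 1, s + 1] <- ways[j + 1, s + 1] + ways[j, s - v + 1]
        }
      }
      counts <- ways[n1 + 1, ]
      u_vals <- (seq_len(smax + 1) - 1) - n1 * (n1 + 1) / 2
      total <- sum(counts)
      p_le <- sum(counts[u_vals <= u_obs]) / total
      p_ge <- sum(counts[u_vals >= u_obs]) / total
    } else {
      if (n1 + n2 > 16)
        stopf("exact mode with ties limited to combined n <= 16; use mode='normal'")
      combos <- utils::combn(n1 + n2, n1)
      u_all <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
      p_le <- mean(u_all <= u_obs)
      p_ge <- mean(u_all >= u_obs)
    }
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_le, p_ge)),
                less = p_le,
                greater = p_ge)
    method <- "exact"
  } else {
    n <- n1 + n2
    mu <- n1 * n2 / 2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      # all values identical: no evidence either way
      p <- 1
    } else {
      sigma <- sqrt(sigma2)
      z2 <- (abs(u_obs - mu) - 0.5) / sigma
      p <- switch(alternative,
                  two.sided = min(1, 2 * stats::pnorm(-max(z2, 0))),
                  less = stats::pnorm((u_obs - mu + 0.5) / sigma),
                  greater = stats::pnorm(-(u_obs - mu - 0.5) / sigma))
    }
    method <- "normal-approximation"
  }
  list(statistic = u_obs, p_value = p, method = method, n1 = n1, n2 = n2)
}

#' Hypergeometric upper-tail probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, m): k successes among m draws
#' without replacement from a population of N containing K successes.
#' Computed in log space from binomial coefficients (lgamma) for stability
#' at population sizes in the hundreds.
#'
#' @param k observed successes.
#' @param N population size.
#' @param K successes in the population.
#' @param m number of draws.
#' @return P(X >= k), in (0, 1].
#' @export
hypergeom_sf <- function(k, N, K, m) {
  if (any(c(k, N, K, m) < 0) || K > N || m > N)
    stopf("inconsistent hypergeometric counts (k=%s, N=%s, K=%s, m=%s)", k, N, K, m)
  if (k > min(m, K))
    stopf("k = %s exceeds min(m, K) = %s", k, min(m, K))
  lo <- max(0, m + K - N)
  if (k <= lo) return(1.0)
  j <- k:min(m, K)
  logden <- lchoose(N, m)
  logterms <- lchoose(K, j) + lchoose(N - K, m - j) - logden
  mx <- max(logterms)
  min(1.0, exp(mx + log(sum(exp(logterms - mx)))))
}

#' One-way analysis of variance
#'
#' F-test for equality of group means: F = MSB/MSW on (g-1, n-g) degrees
#' of freedom, upper-tail p from the F distribution. Degenerate inputs are
#' resolved explicitly: zero within-group variance with unequal means gives
#' p = 0 (the gene is certainly retained by a p < alpha filter); all values
#' identical gives F = 0, p = 1.
#'
#' @param groups list of numeric vectors, one per group (>= 2 groups, each
#'   with >= 2 values).
#' @return list with `statistic` (F), `p_value`, `df` (length-2), `method`.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stopf("one_way_anova needs a list of >= 2 groups")
  sizes <- lengths(groups)
  if (any(sizes < 2)) stopf("every group needs >= 2 values")
  all_v <- unlist(groups, use.names = FALSE)
  if (anyNA(all_v)) stopf("missing values in ANOVA input")
  n <- length(all_v); g <- length(groups)
  grand <- mean(all_v)
  means <- vapply(groups, mean, 0)
  ssb <- sum(sizes * (means - grand)^2)
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 0))
  df <- c(g - 1L, n - g)
  if (ssw == 0) {
    if (ssb == 0)
      return(list(statistic = 0, p_value = 1, df = df, method = "degenerate"))
    return(list(statistic = Inf, p_value = 0, df = df, method = "degenerate"))
  }
  f <- (ssb / df[1]) / (ssw / df[2])
  list(statistic = f, p_value = stats::pf(f, df[1], df[2], lower.tail = FALSE),
       df = df, method = "f-test")
}
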