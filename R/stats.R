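#' Exact median test for association-score cohorts
#'
#' Operationalizes the exact comparison of a protein-pair score cohort with
#' the negative-control cohort as Mood's median test: all scores are pooled,
#' dichotomized at the pooled grand median (ties at the median count as
#' "below"), and the resulting 2x2 table (cohort x above/below) is tested
#' with the one-sided hypergeometric (Fisher) tail.  The null is equality of
#' the cohort medians; the alternative `greater` asks whether the pair
#' median exceeds the negative-control median.
#'
#' @param pair,neg numeric score vectors (non-empty, finite).
#' @param alternative only `"greater"` is meaningful for association
#'   screening; `"less"` and `"two.sided"` are provided for completeness.
#' @return list with `p_value`, the 2x2 `table`, and `degenerate` flag
#'   (TRUE when all scores are identical; then `p_value = 1`).
#' @examples
#' median_association_test(c(2, 3, 4, 5), c(0, 0, 0, 1))$p_value  # 1/70
#' @export
median_association_test <- function(pair, neg,
                                    alternative = c("greater", "less",
                                                    "two.sided")) {
  alternative <- match.arg(alternative)
  pair <- pair[is.finite(pair)]; neg <- neg[is.finite(neg)]
  if (!length(pair) || !length(neg)) stop("both cohorts must be non-empty")
  pooled <- c(pair, neg)
  med <- stats::median(pooled)
  a <- sum(pair > med)           # pair above
  c_ <- sum(neg > med)           # neg above
  tab <- matrix(c(a, length(pair) - a, c_, length(neg) - c_), nrow = 2,
                byrow = TRUE,
                dimnames = list(c("pair", "neg"), c("above", "below")))
  k <- a + c_                    # total above
  degenerate <- k == 0 || k == length(pooled)
  m <- length(pair); n <- length(neg)
  # X ~ Hypergeometric(m, n, k): pair-cohort count above the pooled median
  p_greater <- stats::phyper(a - 1, m, n, k, lower.tail = FALSE)
  p_less <- stats::phyper(a, m, n, k)
  p <- switch(alternative,
              greater = p_greater,
              less = p_less,
              two.sided = min(1, 2 * min(p_greater, p_less)))
  list(p_value = p, table = tab, degenerate = degenerate)
}

# Exact null distribution of twice the positive-rank sum (Pratt handling):
# ranks are midranks of |d| including zeros; zeros are then discarded but
# keep inflating the remaining ranks.  Returns P(2*W+ = i) at f[i + 1].
signed_rank_null <- function(ranks2) {
  maxs <- sum(ranks2)
  f <- numeric(maxs + 1); f[1] <- 1
  for (r in ranks2) {
    g <- f
    g[(r + 1):(maxs + 1)] <- g[(r + 1):(maxs + 1)] + f[1:(maxs + 1 - r)]
    f <- g
  }
  f / 2^length(ranks2)
}

#' Paired (coupled) near-vs-far signed-rank test
#'
#' One-sample Wilcoxon signed-rank test on the per-cell score differences
#' `s1 - s2`, with Pratt handling of zero differences (zeros enter the
#' ranking of |d| and are then discarded).  The null distribution is exact
#' (convolution over the realized ranks, so ties are handled exactly) for
#' up to `exact_max` non-zero differences, and a normal approximation with
#' continuity correction above.  All three alternatives are returned.
#'
#' @param s1,s2 paired score vectors (near / far), equal length.
#' @param exact_max largest number of non-zero differences for which the
#'   exact distribution is used (default 25).
#' @return list with `p_two_sided`, `p_greater`, `p_less`, statistic `w`
#'   (positive-rank sum), `n_nonzero`, `degenerate` flag, `method`.
#' @examples
#' near_far_coupled_test(1:6 + 10, rep(10, 6))$p_greater  # 1/64
#' @export
near_far_coupled_test <- function(s1, s2, exact_max = 25L) {
  if (length(s1) != length(s2)) stop("paired vectors must have equal length")
  ok <- is.finite(s1) & is.finite(s2)
  d <- s1[ok] - s2[ok]
  if (!length(d)) stop("no finite pairs")
  if (all(d == 0))
    return(list(p_two_sided = 1, p_greater = 1, p_less = 1, w = 0,
                n_nonzero = 0L, degenerate = TRUE, method = "degenerate"))
  r <- rank(abs(d))            # includes zeros (Pratt)
  nz <- d != 0
  w <- sum(r[d > 0])
  rnz2 <- round(2 * r[nz])
  if (sum(nz) <= exact_max) {
    f <- signed_rank_null(rnz2)
    w2 <- round(2 * w)
    idx <- seq_along(f) - 1L
    p_greater <- sum(f[idx >= w2])
    p_less <- sum(f[idx <= w2])
    method <- "exact"
  } else {
    mu <- sum(r[nz]) / 2
    sigma <- sqrt(sum(r[nz]^2) / 4)
    p_greater <- stats::pnorm((w - 0.5 - mu) / sigma, lower.tail = FALSE)
    p_less <- stats::pnorm((w + 0.5 - mu) / sigma)
    method <- "normal_approx"
  }
  list(p_two_sided = min(1, 2 * min(p_greater, p_less)),
       p_greater = p_greater, p_less = p_less,
       w = w, n_nonzero = sum(nz), degenerate = FALSE, method = method)
}

# Exact distribution of the rank sum of group 1: number of size-n1 subsets
# of the (doubled, integer) midranks attaining each sum, by dynamic
# programming.  Returns matrix-free list(p at sum = i -> f[[n1]][i + 1]).
rank_sum_null <- function(ranks2, n1) {
  maxs <- sum(ranks2)
  # f[[k + 1]][s + 1] = number of k-subsets with sum s
  f <- vector("list", n1 + 1L)
  f[[1]] <- c(1, numeric(maxs))
  for (k in seq_len(n1)) f[[k + 1]] <- numeric(maxs + 1)
  for (r in ranks2) {
    for (k in rev(seq_len(n1))) {
      shifted <- c(numeric(r), f[[k]][1:(maxs + 1 - r)])
      f[[k + 1]] <- f[[k + 1]] + shifted
    }
  }
  f[[n1 + 1]] / choose(length(ranks2), n1)
}

#' Unpaired (uncoupled) near-vs-far rank-sum test
#'
#' Two-sample Mann--Whitney/rank-sum test of equality of medians against
#' all three alternatives.  Exact (tie-exact, by enumeration over midrank
#' subsets) for pooled n up to `exact_max`; beyond that a normal
#' approximation on the rank sum with the finite-population variance of the
#' realized midranks (which absorbs tie corrections) and continuity
#' correction.
#'
#' @param s1,s2 score vectors (near / far), each length >= 1.
#' @param exact_max largest pooled size for the exact distribution.
#' @return list with `p_two_sided`, `p_greater` (s1 shifted up), `p_less`,
#'   rank-sum statistic `w` for `s1`, and `method`.
#' @examples
#' near_far_uncoupled_test(c(10, 11, 12), c(1, 2, 3))$p_greater  # 0.05
#' @export
near_far_uncoupled_test <- function(s1, s2, exact_max = 30L) {
  s1 <- s1[is.finite(s1)]; s2 <- s2[is.finite(s2)]
  if (!length(s1) || !length(s2)) stop("both samples must be non-empty")
  n1 <- length(s1); n <- n1 + length(s2)
  r <- rank(c(s1, s2))
  w <- sum(r[seq_len(n1)])
  r2 <- round(2 * r)
  w2 <- round(2 * w)
  if (n <= exact_max) {
    f <- rank_sum_null(r2, n1)
    idx <- seq_along(f) - 1L
    p_greater <- sum(f[idx >= w2])
    p_less <- sum(f[idx <= w2])
    method <- "exact"
  } else {
    mu <- n1 * mean(r)
    sigma <- sqrt(n1 * (n - n1) / (n - 1) * mean((r - mean(r))^2))
    p_greater <- stats::pnorm((w - 0.5 - mu) / sigma, lower.tail = FALSE)
    p_less <- stats::pnorm((w + 0.5 - mu) / sigma)
    method <- "normal_approx"
  }
  list(p_two_sided = min(1, 2 * min(p_greater, p_less)),
       p_greater = p_greater, p_less = p_less, w = w, method = method)
}

#' Benjamini--Hochberg adjustment helper
#'
#' Raw p-values with fixed thresholds are the default throughout; this
#' optional helper adjusts a vector of per-pair p-values when a
#' false-discovery-rate view is wanted instead.
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values.
#' @export
adjust_bh <- function(p) stats::p.adjust(p, method = "BH")
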