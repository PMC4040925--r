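# Brute-force oracles, independent of the implementations they check.

# Mood construction by enumeration: all C(n, n1) assignments of the pooled
# scores to the "pair" cohort are equally likely under H0 given the pooled
# data; p = fraction of assignments with at least the observed pair-above
# count.
oracle_median_test <- function(pair, neg) {
  pooled <- c(pair, neg)
  med <- median(pooled)
  above <- pooled > med
  n1 <- length(pair)
  a_obs <- sum(pair > med)
  sets <- combn(length(pooled), n1)
  mean(colSums(matrix(above[sets], nrow = n1)) >= a_obs)
}

# signed-rank with Pratt zeros by full enumeration of sign assignments of
# the non-zero differences (zero ranks fixed at zero contribution)
oracle_signed_rank <- function(d) {
  r <- rank(abs(d))
  nz <- which(d != 0)
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), length(nz))))
  w_all <- signs %*% r[nz]
  list(greater = mean(w_all >= w_obs - 1e-9),
       less = mean(w_all <= w_obs + 1e-9))
}

# rank-sum by full enumeration of group-1 subsets of the pooled midranks
oracle_rank_sum <- function(s1, s2) {
  r <- rank(c(s1, s2))
  n1 <- length(s1)
  w_obs <- sum(r[seq_len(n1)])
  sets <- combn(length(r), n1)
  w_all <- colSums(matrix(r[sets], nrow = n1))
  list(greater = mean(w_all >= w_obs - 1e-9),
       less = mean(w_all <= w_obs + 1e-9))
}

# maximal cliques >= min_size by exhaustive subset search over bit masks
oracle_cliques <- function(nodes, edges, min_size = 3) {
  n <- length(nodes)
  adj <- integer(n)  # adjacency bit masks
  ia <- match(edges$protein_a, nodes); ib <- match(edges$protein_b, nodes)
  for (k in seq_along(ia)) {
    adj[ia[k]] <- bitwOr(adj[ia[k]], bitwShiftL(1L, ib[k] - 1L))
    adj[ib[k]] <- bitwOr(adj[ib[k]], bitwShiftL(1L, ia[k] - 1L))
  }
  bits <- bitwShiftL(1L, seq_len(n) - 1L)
  out <- list()
  for (mask in seq_len(2^n - 1)) {
    members <- which(bitwAnd(mask, bits) > 0)
    if (length(members) < min_size) next
    # clique: every member adjacent to all other members
    if (!all(vapply(members, function(i)
      bitwAnd(adj[i], mask) == mask - bits[i], logical(1)))) next
    # maximal: no outside vertex adjacent to every member
    outside <- setdiff(seq_len(n), members)
    if (any(vapply(outside, function(v)
      bitwAnd(adj[v], mask) == mask, logical(1)))) next
    out[[length(out) + 1L]] <- sort(nodes[members])
  }
  out[order(vapply(out, paste, character(1), collapse = "|"))]
}
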