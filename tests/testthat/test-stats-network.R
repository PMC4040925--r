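# Exact nonparametric tests against the brute-force oracles defined in
# helper-oracles.R; network construction and inference logic.

# --- median (Mood/Fisher) test ------------------------------------------

test_that("median test reproduces exact hand-enumerated tables", {
  expect_equal(median_association_test(c(2, 3, 4, 5), c(0, 0, 0, 1))$p_value,
               1 / 70)
  r <- median_association_test(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(r$p_value, 53 / 70)
  # extreme separation saturates the one-sided tail
  expect_lt(median_association_test(rnorm(30, 50), rnorm(30))$p_value, 1e-4)
  # all identical: degenerate, p = 1
  dg <- median_association_test(rep(2, 5), rep(2, 6))
  expect_true(dg$degenerate)
  expect_equal(dg$p_value, 1)
})

test_that("median test agrees with the enumeration oracle on small cohorts", {
  set.seed(42)
  for (rep in 1:25) {
    n1 <- sample(2:7, 1); n2 <- sample(2:7, 1)
    if (n1 + n2 > 12) next
    # half the cases with heavy ties
    pair <- if (rep %% 2) rnorm(n1) else sample(0:2, n1, replace = TRUE)
    neg <- if (rep %% 2) rnorm(n2) else sample(0:2, n2, replace = TRUE)
    expect_equal(median_association_test(pair, neg)$p_value,
                 oracle_median_test(pair, neg), tolerance = 1e-12)
  }
})

# --- signed-rank (coupled) test -----------------------------------------

test_that("coupled test reproduces exact signed-rank enumerations", {
  # all positive differences 1..6
  r <- near_far_coupled_test(c(1, 2, 3, 4, 5, 6) + 10, rep(10, 6))
  expect_equal(r$p_greater, 1 / 64)
  # symmetric differences: two-sided p = 1
  r2 <- near_far_coupled_test(c(1, 2, 3, -1, -2, -3), rep(0, 6))
  expect_equal(r2$p_two_sided, 1)
  # identical vectors: degenerate
  r3 <- near_far_coupled_test(1:8, 1:8)
  expect_true(r3$degenerate)
  expect_equal(r3$p_two_sided, 1)
})

test_that("coupled test matches the sign-enumeration oracle (ties, zeros)", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(4:10, 1)
    d <- if (rep %% 2) rnorm(n) else sample(-2:2, n, replace = TRUE)
    if (all(d == 0)) d[1] <- 1
    got <- near_far_coupled_test(d, rep(0, n))
    want <- oracle_signed_rank(d)
    expect_equal(got$p_greater, want$greater, tolerance = 1e-12)
    expect_equal(got$p_less, want$less, tolerance = 1e-12)
  }
})

test_that("coupled test switches to a sane normal approximation at large n", {
  set.seed(12)
  d <- rnorm(60, 0.8)
  r <- near_far_coupled_test(d, rep(0, 60))
  expect_equal(r$method, "normal_approx")
  expect_true(r$p_greater < 0.05)
  expect_true(r$p_greater > 0 && r$p_less > 0)
})

# --- rank-sum (uncoupled) test ------------------------------------------

test_that("uncoupled test reproduces exact rank enumerations", {
  expect_equal(near_far_uncoupled_test(c(10, 11, 12), c(1, 2, 3))$p_greater,
               1 / 20)
  r <- near_far_uncoupled_test(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(r$p_two_sided, 1)
  expect_error(near_far_uncoupled_test(numeric(0), 1:3), "non-empty")
})

test_that("uncoupled test matches the permutation oracle at n = 8", {
  set.seed(31)
  for (rep in 1:20) {
    n1 <- sample(2:6, 1); n2 <- 8 - n1
    s1 <- if (rep %% 2) rnorm(n1) else sample(1:3, n1, replace = TRUE)
    s2 <- if (rep %% 2) rnorm(n2) else sample(1:3, n2, replace = TRUE)
    got <- near_far_uncoupled_test(s1, s2)
    want <- oracle_rank_sum(s1, s2)
    expect_equal(got$p_greater, want$greater, tolerance = 1e-12)
    expect_equal(got$p_less, want$less, tolerance = 1e-12)
  }
})

# --- network construction and inference ---------------------------------

test_that("build_network applies strict thresholds and rejects duplicates", {
  rec <- data.frame(protein_a = c("A", "B", "C"),
                    protein_b = c("B", "C", "A"),
                    p_primary = c(1e-4, 5e-5, 1e-6),
                    p_secondary = c(0.001, 0.5, 0.001))
  net <- build_network(rec, p_primary = 1e-4, p_secondary = 0.02)
  # A-B is exactly at threshold: excluded (strict <); B-C fails secondary
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$protein_a, "A")
  expect_equal(net$edges$protein_b, "C")
  # secondary column absent: primary only
  net2 <- build_network(rec[, 1:3], p_primary = 1e-4)
  expect_equal(nrow(net2$edges), 2)
  dup <- rbind(rec, data.frame(protein_a = "B", protein_b = "A",
                               p_primary = 1e-9, p_secondary = 1e-9))
  expect_error(build_network(dup), "duplicate")
})

test_that("fixture network yields exactly the two known ternary complexes", {
  fx <- make_network_fixture()
  net <- as_association_network(fx$nodes, fx$edges)
  cl <- find_ternary_complexes(net)
  expect_equal(cl, list(c("CAS", "FAK", "paxillin"),
                        c("ILK", "PINCH", "alpha-parvin")))
})

test_that("clique finder matches exhaustive search on random small graphs", {
  set.seed(19)
  for (rep in 1:30) {
    n <- sample(3:6, 1)
    nodes <- LETTERS[1:n]
    pairs <- t(combn(nodes, 2))
    keep <- runif(nrow(pairs)) < 0.5
    if (!any(keep)) next
    edges <- data.frame(protein_a = pairs[keep, 1],
                        protein_b = pairs[keep, 2])
    net <- as_association_network(nodes, edges)
    for (ms in 2:3)
      expect_equal(find_ternary_complexes(net, min_size = ms),
                   oracle_cliques(nodes, edges, min_size = ms))
  }
  # complete graph on 4 nodes: one maximal clique of size 4
  k4 <- t(combn(LETTERS[1:4], 2))
  net4 <- as_association_network(LETTERS[1:4],
                                 data.frame(protein_a = k4[, 1],
                                            protein_b = k4[, 2]))
  expect_equal(find_ternary_complexes(net4), list(c("A", "B", "C", "D")))
  # empty graph
  net0 <- as_association_network(LETTERS[1:4],
                                 data.frame(protein_a = character(0),
                                            protein_b = character(0)))
  expect_equal(find_ternary_complexes(net0), list())
})

test_that("mutual exclusivity records match the fixture biology", {
  fx <- make_network_fixture()
  net <- as_association_network(fx$nodes, fx$edges)
  mx <- infer_mutual_exclusivity(net)
  keys <- vapply(mx, function(r)
    paste(r$hub, paste(r$partners, collapse = "+")), character(1))
  # vinculin and FAK both bind paxillin but not each other
  expect_true("paxillin FAK+vinculin" %in% keys)
  # VASP's three partners are pairwise unassociated
  expect_true("VASP alpha-actinin+vinculin+zyxin" %in% keys)
  # zyxin's partners VASP and CAS are not associated
  expect_true("zyxin CAS+VASP" %in% keys)
  # a triangle has no mutually exclusive partners
  tri <- t(combn(LETTERS[1:3], 2))
  net3 <- as_association_network(LETTERS[1:3],
                                 data.frame(protein_a = tri[, 1],
                                            protein_b = tri[, 2]))
  expect_equal(infer_mutual_exclusivity(net3), list())
})

test_that("co-dynamics distance z-scores with n-1 and is affine invariant", {
  prof <- data.frame(protein = c("A", "B", "C"),
                     median_half_time = c(10, 20, 30),
                     median_mobile_fraction = c(0.5, 0.7, 0.9))
  d <- co_dynamics_distance(prof)
  expect_equal(d["A", "B"], sqrt(2), tolerance = 1e-12)
  expect_equal(d["A", "C"], 2 * sqrt(2), tolerance = 1e-12)
  expect_equal(diag(d), c(A = 0, B = 0, C = 0))
  expect_equal(d, t(d))
  # seconds -> minutes rescaling leaves distances unchanged
  prof2 <- prof; prof2$median_half_time <- prof$median_half_time / 60 + 5
  expect_equal(co_dynamics_distance(prof2), d, tolerance = 1e-12)
  # identical dynamics: distance zero
  prof3 <- data.frame(protein = c("A", "B", "C"),
                      median_half_time = c(10, 10, 30),
                      median_mobile_fraction = c(0.5, 0.5, 0.9))
  expect_equal(co_dynamics_distance(prof3)["A", "B"], 0)
  prof4 <- prof; prof4$median_mobile_fraction <- 0.5
  expect_error(co_dynamics_distance(prof4), "zero variance")
})
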