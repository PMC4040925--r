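# Multi-tau correlator and curve summaries.

# Independent brute-force direct-lag correlator: same estimator definition,
# written as explicit loops over lags (no rebinning).
brute_force_correlate <- function(x, y, dt, max_k) {
  sapply(seq_len(max_k), function(k) {
    n <- length(x)
    i1 <- 1:(n - k); i2 <- (k + 1):n
    f <- mean(x[i1] * y[i2]) / (mean(x[i1]) * mean(y[i2])) - 1
    b <- mean(y[i1] * x[i2]) / (mean(y[i1]) * mean(x[i2])) - 1
    if (identical(x, y)) f else (f + b) / 2
  })
}

test_that("multitau agrees with the brute-force direct-lag correlator", {
  set.seed(11)
  n <- 8192
  x <- rpois(n, 3); y <- rpois(n, 2) + as.integer(x > 4)  # correlated pair
  tx <- intensity_trace(x, 1e-4, "G")
  ty <- intensity_trace(y, 1e-4, "R")
  for (pair in list(list(tx, tx), list(tx, ty))) {
    cv <- multitau_correlate(pair[[1]], pair[[2]], bins_per_stage = 16)
    # stage-0 lags (first 16) are un-rebinned: exact agreement required
    bf <- brute_force_correlate(pair[[1]]$counts, pair[[2]]$counts, 1e-4, 16)
    expect_lt(max(abs(cv$g[1:16] - bf)), 1e-12)
  }
})

test_that("constant traces give exactly zero correlation", {
  tr <- intensity_trace(rep(7, 4096), 1e-4, "G")
  cv <- multitau_correlate(tr, tr)
  expect_true(all(abs(cv$g) < 1e-14))
})

test_that("independent Poisson traces stay below the shot-noise floor", {
  set.seed(5)
  n <- 65536
  tx <- intensity_trace(rpois(n, 4), 1e-5, "G")
  ty <- intensity_trace(rpois(n, 4), 1e-5, "R")
  cv <- multitau_correlate(tx, ty)
  early <- cv$lag <= 1e-3
  expect_true(all(abs(cv$g[early]) <= 4 / sqrt(n)))
})

test_that("correlation is invariant to positive scaling of the traces", {
  set.seed(9)
  x <- rpois(4096, 5)
  t1 <- intensity_trace(x, 1e-4, "G")
  t2 <- intensity_trace(3.7 * x, 1e-4, "G")
  expect_equal(multitau_correlate(t1, t1)$g, multitau_correlate(t2, t2)$g,
               tolerance = 1e-12)
})

test_that("correlator rejects malformed input", {
  a <- intensity_trace(rpois(100, 2) + 1, 1e-4, "G")
  b <- intensity_trace(rpois(50, 2) + 1, 1e-4, "R")
  expect_error(multitau_correlate(a, b), "different lengths")
  d <- intensity_trace(rpois(100, 2) + 1, 2e-4, "R")
  expect_error(multitau_correlate(a, d), "bin widths")
  z <- intensity_trace(rep(0, 100), 1e-4, "R")
  expect_error(multitau_correlate(z, z), "zero-mean")
  expect_error(multitau_correlate(a, a, bins_per_stage = 7), "even")
})

test_that("average_curves: identity, symmetry, variance reduction", {
  lag <- exp(seq(log(1e-5), log(1), length.out = 50))
  c1 <- closed_form_fcs_curve(5, 1e-3, 10, 0, lag)
  expect_equal(average_curves(list(c1))$g, c1$g)
  c_neg <- correlation_curve(lag, -c1$g, "GG")
  expect_true(all(abs(average_curves(list(c1, c_neg))$g) < 1e-15))
  expect_error(average_curves(list()), "empty")
  c_short <- closed_form_fcs_curve(5, 1e-3, 10, 0, lag[-1])
  expect_error(average_curves(list(c1, c_short)), "grid")

  # averaging 10 replicate noisy curves shrinks the amplitude-window MAD
  set.seed(21)
  noisy <- lapply(1:10, function(i)
    correlation_curve(lag, c1$g + rnorm(50, 0, 0.01), "GG"))
  aw <- c(1e-5, 1e-4); ow <- c(0.15, 0.9)
  mad_one <- summarize_curve(noisy[[1]], aw, ow)$mad_amp
  mad_avg <- summarize_curve(average_curves(noisy), aw, ow)$mad_amp
  expect_lt(mad_avg, 0.7 * mad_one)
})

test_that("summarize_curve computes hand-checked medians and MAD", {
  # 3 amplitude points {0.04, 0.05, 0.06}, 3 offset points {0, 0.01, 0.02}
  lag <- c(1e-5, 2e-5, 3e-5, 0.2, 0.3, 0.4)
  g <- c(0.04, 0.05, 0.06, 0.00, 0.01, 0.02)
  s <- summarize_curve(correlation_curve(lag, g, "GG"),
                       amp_window = c(1e-5, 3e-5),
                       offset_window = c(0.2, 0.4), min_points = 3)
  expect_equal(s$amplitude, 0.05)
  expect_equal(s$offset, 0.01)
  expect_equal(s$mad_amp, 0.01)
  expect_equal(s$G0, 0.04)

  # flat curve: amplitude - offset = 0, MAD = 0
  sf <- summarize_curve(correlation_curve(lag, rep(0.3, 6), "GG"),
                        c(1e-5, 3e-5), c(0.2, 0.4), min_points = 3)
  expect_equal(sf$amplitude - sf$offset, 0)
  expect_equal(sf$mad_amp, 0)

  # RG clamping: slightly negative cross amplitude is set to zero
  g2 <- c(0.001, 0.002, 0.002, 0.005, 0.005, 0.005)  # amp - off = -0.003
  srg <- summarize_curve(correlation_curve(lag, g2, "RG"),
                         c(1e-5, 3e-5), c(0.2, 0.4), min_points = 3)
  expect_equal(srg$amplitude - srg$offset, -0.003)
  expect_equal(srg$G0, 0)
  # same curve as autocorrelation is not clamped
  sgg <- summarize_curve(correlation_curve(lag, g2, "GG"),
                         c(1e-5, 3e-5), c(0.2, 0.4), min_points = 3)
  expect_equal(sgg$G0, -0.003)
})

test_that("summarize_curve is shift invariant in the numerator and errors on
           uncovered windows", {
  lag <- exp(seq(log(1e-5), log(1), length.out = 60))
  set.seed(3)
  g <- 0.1 / (1 + lag / 1e-3) + rnorm(60, 0, 0.002)
  cv <- correlation_curve(lag, g, "RG")
  cv_shift <- correlation_curve(lag, g + 0.42, "RG")
  aw <- c(1e-5, 1e-4); ow <- c(0.15, 0.9)
  s1 <- summarize_curve(cv, aw, ow); s2 <- summarize_curve(cv_shift, aw, ow)
  expect_equal(s1$amplitude - s1$offset, s2$amplitude - s2$offset,
               tolerance = 1e-12)
  expect_equal(s1$mad_amp, s2$mad_amp, tolerance = 1e-12)
  expect_error(summarize_curve(cv, c(1e-9, 2e-9), ow), "window")
})

test_that("curve CSV round trip is lossless", {
  lag <- exp(seq(log(1e-6), log(1), length.out = 40))
  cv <- closed_form_fcs_curve(7, 2e-4, 8, 1e-4, lag, channel_pair = "RG")
  path <- tempfile(fileext = ".csv")
  write_curve_csv(cv, path)
  cv2 <- read_curve_csv(path)
  expect_equal(cv2$lag, cv$lag)
  expect_equal(cv2$g, cv$g)
  expect_equal(cv2$channel_pair, "RG")
})
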