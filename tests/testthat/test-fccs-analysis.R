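# Particle numbers, Ka, association score, QC rules, concentrations.

test_that("particle numbers follow the amplitude identities", {
  np <- particle_numbers(0.1, 0.1, 0.01)
  expect_equal(np$n_gg, 10)
  expect_equal(np$n_rr, 10)
  expect_equal(np$n_rg, 1)
  expect_equal(particle_numbers(0.2, 0.1, 0)$n_rg, 0)
  expect_error(particle_numbers(0, 0.1, 0), "infinite N")
  expect_error(particle_numbers(0.1, 0.1, -0.01), "clamped")
})

test_that("apparent Ka reproduces the hand-evaluated example", {
  ka <- apparent_ka(10, 10, 1, calibration_set(v_g = 0.38, v_r = 0.67,
                                               v_rg = 0.34, phi = 0.53))
  # [RG] = 1/(0.34*0.53); [R_T] = 10/(0.67*0.53); [G_T] = 10/0.38
  expect_equal(ka$rg, 1 / (0.34 * 0.53), tolerance = 1e-12)
  expect_equal(ka$ka_fl, 0.0118, tolerance = 2e-3)
  expect_false(ka$negative_ka)
  # M^-1 conversion: 1 fl per particle = N_A * 1e-15 M^-1
  expect_equal(ka$ka_M / ka$ka_fl, 6.02214076e23 * 1e-15)
})

test_that("Ka edge cases: zero complexes, negative branch, monotonicity", {
  cal <- calibration_set()
  expect_equal(apparent_ka(10, 10, 0, cal)$ka_fl, 0)
  # complexes exceeding a total concentration flips the negative-Ka flag
  over <- apparent_ka(10, 10, 9.99, cal)
  expect_true(over$negative_ka)
  expect_true(is.na(over$ka_fl))
  # monotone in N_RG where defined
  kas <- vapply(seq(0.1, 2, by = 0.1),
                function(n) apparent_ka(10, 10, n, cal)$ka_fl, numeric(1))
  expect_true(all(diff(kas) > 0))
})

test_that("association score matches the hand computation and invariances", {
  lag <- c(1e-5, 2e-5, 3e-5, 0.2, 0.3, 0.4)
  g <- c(0.04, 0.05, 0.06, 0.00, 0.01, 0.02)
  aw <- c(1e-5, 3e-5); ow <- c(0.2, 0.4)
  s <- summarize_curve(correlation_curve(lag, g, "RG"), aw, ow, min_points = 3)
  expect_equal(association_score(s)$score, 4)  # (0.05 - 0.01)/0.01
  # scale by 3 and shift by +0.5: identical score
  s2 <- summarize_curve(correlation_curve(lag, 3 * g + 0.5, "RG"), aw, ow,
                        min_points = 3)
  expect_equal(association_score(s2)$score, 4, tolerance = 1e-12)
  # amp == off gives score 0; MAD = 0 flags undefined
  g0 <- c(0.01, 0.02, 0.03, 0.01, 0.02, 0.03)
  s3 <- summarize_curve(correlation_curve(lag, g0, "RG"), aw, ow,
                        min_points = 3)
  expect_equal(association_score(s3)$score, 0)
  flat <- summarize_curve(correlation_curve(lag, rep(1, 6), "RG"), aw, ow,
                          min_points = 3)
  expect_true(association_score(flat)$undefined)
})

make_summary <- function(offset, pair = "GG") {
  lag <- c(1e-5, 2e-5, 3e-5, 0.2, 0.3, 0.4)
  summarize_curve(correlation_curve(lag, c(0.2, 0.21, 0.22,
                                           offset + c(-0.001, 0, 0.001)),
                                    pair),
                  c(1e-5, 3e-5), c(0.2, 0.4), min_points = 3)
}

test_that("QC boundaries are inclusive exactly as printed", {
  ok <- make_summary(0)
  # clean measurement passes
  v <- qc_filter(ok, ok, c_g = 5000, c_r = 5000, c_d = 300,
                 n_gg = 4, n_rr = 4)
  expect_true(v$pass)

  # (i) CPM at exactly 215 Hz is excluded; just above passes
  v215 <- qc_filter(ok, ok, c_g = 300 + 215 * 4, c_r = 5000, c_d = 300,
                    n_gg = 4, n_rr = 4)
  expect_false(v215$pass); expect_true("cpm_fail" %in% v215$flags)
  v216 <- qc_filter(ok, ok, c_g = 300 + 216 * 4, c_r = 5000, c_d = 300,
                    n_gg = 4, n_rr = 4)
  expect_false("cpm_fail" %in% v216$flags)

  # (ii) offsets exactly at 0.0025 / -0.002 are excluded; inside passes
  for (off in c(0.0025, -0.002)) {
    vb <- qc_filter(make_summary(off), ok, 5000, 5000, 300, 4, 4)
    expect_true("offset_fail" %in% vb$flags)
  }
  vin <- qc_filter(make_summary(0.00249), make_summary(-0.00199),
                   5000, 5000, 300, 4, 4)
  expect_false("offset_fail" %in% vin$flags)

  # (iii) bleedthrough ratio exactly 20 is excluded; just below passes
  v20 <- qc_filter(ok, ok, c_g = 300 + 20 * 1000, c_r = 1300, c_d = 300,
                   n_gg = 100, n_rr = 4)
  expect_true("bleedthrough_fail" %in% v20$flags)
  v19 <- qc_filter(ok, ok, c_g = 300 + 19 * 1000, c_r = 1300, c_d = 300,
                   n_gg = 100, n_rr = 4)
  expect_false("bleedthrough_fail" %in% v19$flags)

  # (iv) negative Ka; and undefined ratio when C_R <= C_D
  vka <- qc_filter(ok, ok, 5000, 5000, 300, 4, 4, negative_ka = TRUE)
  expect_true("negative_ka" %in% vka$flags)
  vud <- qc_filter(ok, ok, 5000, 200, 300, 4, 4)
  expect_true("bleedthrough_undefined" %in% vud$flags)
})

test_that("median Ka over simulated cells recovers the ground truth", {
  # mixture with [R] = [G] = 20 /fl free and [RG] = 30 /fl:
  # Ka_true = 30/(20*20) = 0.075 fl
  free_c <- 20; rg_c <- 30
  cal <- calibration_set(v_g = desk$veff, v_r = desk$veff, v_rg = desk$veff,
                         phi = 1, dark_rate = 0)
  kas <- vapply(1:10, function(i) {
    p <- suppressWarnings(sim_params(
      conc_r = free_c, conc_g = free_c, conc_rg = rg_c,
      d_r = desk$D, d_g = desk$D, d_rg = desk$D,
      w0_g = desk$w0, w0_r = desk$w0, z0_g = desk$z0, z0_r = desk$z0,
      brightness_g = 5e4, brightness_r = 5e4,
      bin_width = desk$bin, duration = 2.5, n_traces = 2, seed = 40 + i))
    m <- analyze_fccs_measurement(
      simulate_ffs_traces(p), calib = cal,
      thresholds = qc_thresholds(offset_high = 0.05, offset_low = -0.05),
      amp_window = c(2e-4, 1e-3), offset_window = desk$offset_window,
      max_lag = desk$max_lag)
    m$ka_fl
  }, numeric(1))
  expect_lt(abs(median(kas, na.rm = TRUE) - 0.075) / 0.075, 0.25)
})

test_that("concentration conversion hits the Avogadro arithmetic", {
  expect_equal(concentration_report(1, 1)$nM, 1.66, tolerance = 1e-3)
  expect_equal(concentration_report(0, 2)$nM, 0)
  expect_equal(concentration_report(10, 0.38)$nM, 43.7, tolerance = 1e-3)
  expect_error(concentration_report(-1, 1), ">= 0")
  expect_error(concentration_report(1, 0), "> 0")
})
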