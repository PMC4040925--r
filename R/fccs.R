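#' Particle numbers from correlation amplitudes
#'
#' With baseline-free amplitudes, the autocorrelation amplitude is the
#' inverse particle number in that channel's volume and the
#' cross-correlation amplitude gives the complex count:
#' `N_GG = 1/G0_GG`, `N_RR = 1/G0_RR`, `N_RG = G0_RG * N_RR * N_GG`.
#'
#' @param g0_gg,g0_rr auto-amplitudes (> 0).
#' @param g0_rg cross-amplitude (>= 0, clamped upstream).
#' @return list with `n_gg`, `n_rr`, `n_rg`.
#' @export
particle_numbers <- function(g0_gg, g0_rr, g0_rg) {
  if (g0_gg <= 0 || g0_rr <= 0)
    stop("auto-correlation amplitudes must be > 0 (infinite N otherwise)")
  if (g0_rg < 0) stop("cross amplitude must be clamped to >= 0")
  n_gg <- 1 / g0_gg
  n_rr <- 1 / g0_rr
  list(n_gg = n_gg, n_rr = n_rr, n_rg = g0_rg * n_rr * n_gg)
}

# particles/fl -> nM (1 fl = 1e-15 L)
PER_FL_TO_NM <- 1 / (6.02214076e23 * 1e-15) * 1e9

#' Concentration from a particle number and a volume
#'
#' @param n particle count (>= 0).
#' @param v volume in fl (> 0).
#' @return list with `per_fl` (particles/fl) and `nM`.
#' @examples
#' concentration_report(1, 1)$nM  # ~1.66 nM
#' @export
concentration_report <- function(n, v) {
  if (n < 0) stop("n must be >= 0")
  if (v <= 0) stop("v must be > 0")
  per_fl <- n / v
  list(per_fl = per_fl, nM = per_fl * PER_FL_TO_NM)
}

#' Apparent association constant from FCCS particle numbers
#'
#' Converts particle numbers to concentrations using the per-channel
#' volumes, divides the red-containing counts by the maturation factor
#' `phi` to compensate for dark (immature) red fluorophores, and forms
#' \deqn{K_a = \frac{[RG]}{[R][G]}
#'   = \frac{N_{RG}/(V_{RG}\phi)}{\{N_{RR}/(V_R\phi) - N_{RG}/(V_{RG}\phi)\}
#'     \{N_{GG}/V_G - N_{RG}/(V_{RG}\phi)\}}.}
#' `phi = 1` recovers the uncorrected form.
#'
#' @param n_gg,n_rr,n_rg particle numbers (see [particle_numbers()]).
#' @param calib a [calibration_set].
#' @return list with concentrations (`rg`, `r_total`, `g_total`, `r_free`,
#'   `g_free`, particles/fl), `ka_fl` (fl), `ka_M` (M^-1), and
#'   `negative_ka` flag.  A free concentration <= 0 with complexes present
#'   flags the measurement invalid (`negative_ka = TRUE`, `ka_fl = NA`):
#'   the cross-correlation curve was too noisy.
#' @export
apparent_ka <- function(n_gg, n_rr, n_rg, calib = calibration_set()) {
  stopifnot(inherits(calib, "calibration_set"))
  if (n_gg <= 0 || n_rr <= 0 || n_rg < 0) stop("invalid particle numbers")
  rg <- n_rg / (calib$v_rg * calib$phi)
  r_total <- n_rr / (calib$v_r * calib$phi)
  g_total <- n_gg / calib$v_g
  r_free <- r_total - rg
  g_free <- g_total - rg
  out <- list(rg = rg, r_total = r_total, g_total = g_total,
              r_free = r_free, g_free = g_free)
  if (n_rg == 0) {
    out$ka_fl <- 0
    out$negative_ka <- FALSE
  } else if (r_free <= 0 || g_free <= 0) {
    out$ka_fl <- NA_real_
    out$negative_ka <- TRUE
  } else {
    out$ka_fl <- rg / (r_free * g_free)
    out$negative_ka <- FALSE
  }
  # fl per particle -> M^-1 (multiply by Avogadro's number * 1e-15 L/fl)
  out$ka_M <- if (is.na(out$ka_fl)) NA_real_ else
    out$ka_fl * 6.02214076e23 * 1e-15
  out
}

#' Association score of a cross-correlation curve
#'
#' The unclamped amplitude--offset difference in units of the robust noise
#' of the amplitude window: `(amplitude - offset) / MAD(amplitude points)`.
#' Scale- and shift-invariant in the curve; may be negative.
#'
#' @param summary_rg a [summarize_curve()] result for the RG curve.
#' @return list with `score` and `undefined` flag (`TRUE` when the MAD is
#'   zero, in which case the measurement is excluded from cohorts).
#' @export
association_score <- function(summary_rg) {
  stopifnot(inherits(summary_rg, "curve_summary"))
  if (summary_rg$mad_amp == 0)
    return(list(score = NA_real_, undefined = TRUE))
  list(score = (summary_rg$amplitude - summary_rg$offset) / summary_rg$mad_amp,
       undefined = FALSE)
}

#' Default quality-control thresholds
#'
#' @param min_cpm minimum counts-per-molecule (Hz); measurements at or
#'   below are excluded (boundary inclusive).
#' @param offset_high,offset_low inclusive offset bounds for the
#'   auto-correlation curves.
#' @param max_bleed_ratio inclusive upper bound on
#'   `(C_G - C_D)/(C_R - C_D)`, guarding against green-to-red bleedthrough.
#' @return list of thresholds.
#' @export
qc_thresholds <- function(min_cpm = 215, offset_high = 0.0025,
                          offset_low = -0.002, max_bleed_ratio = 20) {
  list(min_cpm = min_cpm, offset_high = offset_high,
       offset_low = offset_low, max_bleed_ratio = max_bleed_ratio)
}

#' Quality-control verdict for an FCCS measurement
#'
#' Applies the four exclusion criteria: (i) counts-per-molecule
#' `(C - C_D)/N` at or below the minimum in either channel; (ii) an
#' auto-curve offset at or outside the inclusive bounds; (iii) a
#' green-over-red background-corrected count-rate ratio at or above the
#' bleedthrough bound; (iv) a negative apparent Ka.  All boundaries are
#' inclusive.
#'
#' @param summary_gg,summary_rr auto-curve [summarize_curve()] results.
#' @param c_g,c_r channel count rates (counts/s).
#' @param c_d detector dark rate (counts/s).
#' @param n_gg,n_rr particle numbers.
#' @param negative_ka flag from [apparent_ka()].
#' @param thresholds a [qc_thresholds()] list.
#' @param check_cross_offset also apply criterion (ii) to the cross curve
#'   (off by default; supply the RG summary via `summary_rg`).
#' @param summary_rg optional RG summary, used only when
#'   `check_cross_offset` is TRUE.
#' @return list with `pass` and character vector `flags` (empty when clean);
#'   flags from `cpm_fail`, `offset_fail`, `bleedthrough_fail`,
#'   `bleedthrough_undefined`, `negative_ka`.
#' @export
qc_filter <- function(summary_gg, summary_rr, c_g, c_r, c_d,
                      n_gg, n_rr, negative_ka = FALSE,
                      thresholds = qc_thresholds(),
                      check_cross_offset = FALSE, summary_rg = NULL) {
  flags <- character(0)
  cpm_g <- (c_g - c_d) / n_gg
  cpm_r <- (c_r - c_d) / n_rr
  if (cpm_g <= thresholds$min_cpm || cpm_r <= thresholds$min_cpm)
    flags <- c(flags, "cpm_fail")
  offs <- c(summary_gg$offset, summary_rr$offset)
  if (check_cross_offset && !is.null(summary_rg))
    offs <- c(offs, summary_rg$offset)
  if (any(offs >= thresholds$offset_high | offs <= thresholds$offset_low))
    flags <- c(flags, "offset_fail")
  if (c_r <= c_d) {
    flags <- c(flags, "bleedthrough_undefined")
  } else if ((c_g - c_d) / (c_r - c_d) >= thresholds$max_bleed_ratio) {
    flags <- c(flags, "bleedthrough_fail")
  }
  if (isTRUE(negative_ka)) flags <- c(flags, "negative_ka")
  list(pass = length(flags) == 0L, flags = flags)
}

#' Analyze one FCCS measurement end-to-end
#'
#' Correlates the trace replicates (GG, RR, RG), averages them, summarizes
#' the three curves, derives particle numbers, Ka, the association score
#' and the QC verdict.
#'
#' @param traces list of trace pairs, each a list with `green` and `red`
#'   [intensity_trace]s (as returned by [simulate_ffs_traces()] or read
#'   from files).
#' @param calib a [calibration_set].
#' @param thresholds a [qc_thresholds()] list.
#' @param amp_window,offset_window lag windows for [summarize_curve()].
#' @param bins_per_stage,max_lag correlator grid, see [multitau_correlate()].
#' @param metadata named list stored verbatim in the result (protein pair,
#'   cell id, cell line, location, treatment).
#' @return object of class `fccs_measurement`: curve summaries, particle
#'   numbers, concentrations, `ka_fl`, `score`, `qc` verdict, metadata.
#' @export
analyze_fccs_measurement <- function(traces, calib = calibration_set(),
                                     thresholds = qc_thresholds(),
                                     amp_window = c(25.6e-6, 81.92e-6),
                                     offset_window = c(157.3e-3, 838.9e-3),
                                     bins_per_stage = 16L, max_lag = 1.1,
                                     metadata = list()) {
  if (!length(traces)) stop("no traces supplied")
  corr <- function(fx, fy) average_curves(lapply(traces, function(tp)
    multitau_correlate(tp[[fx]], tp[[fy]], bins_per_stage, max_lag)))
  gg <- corr("green", "green")
  rr <- corr("red", "red")
  rg <- corr("green", "red")
  s_gg <- summarize_curve(gg, amp_window, offset_window)
  s_rr <- summarize_curve(rr, amp_window, offset_window)
  s_rg <- summarize_curve(rg, amp_window, offset_window)
  np <- particle_numbers(s_gg$G0, s_rr$G0, s_rg$G0)
  ka <- apparent_ka(np$n_gg, np$n_rr, np$n_rg, calib)
  sc <- association_score(s_rg)
  c_g <- mean(vapply(traces, function(tp) tp$green$count_rate, numeric(1)))
  c_r <- mean(vapply(traces, function(tp) tp$red$count_rate, numeric(1)))
  c_d <- calib$dark_rate
  qc <- qc_filter(s_gg, s_rr, c_g, c_r, c_d, np$n_gg, np$n_rr,
                  negative_ka = ka$negative_ka, thresholds = thresholds)
  structure(list(summary_gg = s_gg, summary_rr = s_rr, summary_rg = s_rg,
                 curves = list(gg = gg, rr = rr, rg = rg),
                 n_gg = np$n_gg, n_rr = np$n_rr, n_rg = np$n_rg,
                 concentrations = ka[c("rg", "r_total", "g_total",
                                       "r_free", "g_free")],
                 ka_fl = ka$ka_fl, ka_M = ka$ka_M,
                 score = sc$score, score_undefined = sc$undefined,
                 c_g = c_g, c_r = c_r, c_d = c_d,
                 qc = qc, metadata = metadata),
            class = "fccs_measurement")
}

#' @export
print.fccs_measurement <- function(x, ...) {
  cat(sprintf(
    "<fccs_measurement> N_GG %.1f, N_RR %.1f, N_RG %.2f | Ka %.3g fl | score %.2f | QC %s\n",
    x$n_gg, x$n_rr, x$n_rg, x$ka_fl, x$score,
    if (x$qc$pass) "pass" else paste(x$qc$flags, collapse = ",")))
  invisible(x)
}
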