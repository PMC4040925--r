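#' Fit the single-component diffusion model to an autocorrelation curve
#'
#' Nonlinear least squares of
#' \eqn{g(\tau) = \frac{1}{N(1+\tau/\tau_D)\sqrt{1+\tau/(s^2\tau_D)}} + G_\infty}
#' (baseline-free convention).  The structural parameter can be fixed;
#' fitted structural parameters are highly degenerate with \eqn{\tau_D} on
#' noisy curves and fixing s hardly changes the fitted dwell time.
#'
#' @param curve a [correlation_curve] (autocorrelation).
#' @param fix_s optional fixed structural parameter; `NULL` fits it.
#' @param min_points minimum number of curve points.
#' @return object of class `fcs_fit`: `n`, `tau_d`, `s`, `g_inf`,
#'   `r_squared`, `converged`, `flags`.
#' @examples
#' lag <- exp(seq(log(1e-6), log(1), length.out = 60))
#' cv <- closed_form_fcs_curve(5, 1e-4, 10, 0, lag)
#' fit_fcs(cv, fix_s = 10)
#' @export
fit_fcs <- function(curve, fix_s = NULL, min_points = 20L) {
  stopifnot(inherits(curve, "correlation_curve"))
  if (length(curve$lag) < min_points)
    stop("curve has fewer than ", min_points, " points")
  lag <- curve$lag; g <- curve$g
  bad <- function(flags) structure(
    list(n = NA_real_, tau_d = NA_real_, s = NA_real_, g_inf = NA_real_,
         r_squared = NA_real_, converged = FALSE, flags = flags),
    class = "fcs_fit")

  # scale-free starting values
  g_inf0 <- stats::median(tail(g, max(3L, length(g) %/% 10L)))
  amp0 <- g[1] - g_inf0
  if (!is.finite(amp0) || amp0 <= 0) return(bad("degenerate_amplitude"))
  half <- which(g - g_inf0 <= amp0 / 2)
  tau0 <- if (length(half)) lag[half[1]] else stats::median(lag)
  df <- data.frame(lag = lag, g = g)
  ctrl <- nls.control(maxiter = 500, warnOnly = FALSE, scaleOffset = 1)

  fit <- tryCatch({
    if (is.null(fix_s)) {
      nls(g ~ 1 / (N * (1 + lag / tauD) * sqrt(1 + lag / (s^2 * tauD))) + Ginf,
          data = df,
          start = list(N = 1 / amp0, tauD = tau0, s = 5, Ginf = g_inf0),
          lower = c(N = 1e-8, tauD = 1e-12, s = 0.1, Ginf = -1),
          algorithm = "port", control = ctrl)
    } else {
      s_fixed <- fix_s
      nls(g ~ 1 / (N * (1 + lag / tauD) * sqrt(1 + lag / (s_fixed^2 * tauD))) + Ginf,
          data = df,
          start = list(N = 1 / amp0, tauD = tau0, Ginf = g_inf0),
          lower = c(N = 1e-8, tauD = 1e-12, Ginf = -1),
          algorithm = "port", control = ctrl)
    }
  }, error = function(e) NULL)
  if (is.null(fit)) return(bad("no_convergence"))
  cf <- coef(fit)
  res <- g - predict(fit)
  ss_tot <- sum((g - mean(g))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_
  structure(list(n = unname(cf["N"]), tau_d = unname(cf["tauD"]),
                 s = if (is.null(fix_s)) unname(cf["s"]) else fix_s,
                 g_inf = unname(cf["Ginf"]),
                 r_squared = r2, converged = TRUE, flags = character(0)),
            class = "fcs_fit")
}

#' @export
print.fcs_fit <- function(x, ...) {
  if (x$converged)
    cat(sprintf("<fcs_fit> N %.3g, tau_D %.3g s, s %.3g, G_inf %.2g (R^2 %.4f)\n",
                x$n, x$tau_d, x$s, x$g_inf, x$r_squared))
  else cat("<fcs_fit> failed:", paste(x$flags, collapse = ","), "\n")
  invisible(x)
}

#' Normalize a raw FRAP trace
#'
#' Background-subtracts the ROI trace with its in-cell background trace,
#' then maps the pre-bleach level to 1 and the first post-bleach value to
#' 0: `I(t) = (I_un(t) - I_un(bleach)) / (I_pre - I_un(bleach))`, where
#' `I_pre` is the mean of the `n_premean` background-subtracted frames
#' immediately before bleaching.  The time axis is re-zeroed at the first
#' post-bleach frame.
#'
#' @param intensity,background raw ROI and background traces (same length).
#' @param time_s frame times (s).
#' @param bleach_frame index of the first post-bleach frame (default: frame
#'   `n_prebleach + 1`).
#' @param n_prebleach number of pre-bleach frames (>= `n_premean`).
#' @param n_premean frames averaged for the pre-bleach level (default 9,
#'   the frames before the bleach excluding the very first of 10).
#' @return data.frame with `time_s` (0 at the bleach frame) and `i_norm`
#'   for the post-bleach frames, plus attributes `i_pre` and `i_bleach`.
#' @export
normalize_frap <- function(intensity, background, time_s,
                           bleach_frame = NULL, n_prebleach = 10L,
                           n_premean = 9L) {
  n <- length(intensity)
  if (length(background) != n || length(time_s) != n)
    stop("intensity, background and time_s must have equal lengths")
  if (is.null(bleach_frame)) bleach_frame <- n_prebleach + 1L
  if (bleach_frame <= n_premean || bleach_frame > n)
    stop("bleach_frame must leave >= ", n_premean,
         " pre-bleach frames and lie inside the trace")
  iun <- intensity - background
  pre_idx <- (bleach_frame - n_premean):(bleach_frame - 1L)
  i_pre <- mean(iun[pre_idx])
  i_bleach <- iun[bleach_frame]
  if (i_pre <= i_bleach)
    stop("no dynamic range: pre-bleach level (", signif(i_pre, 4),
         ") does not exceed bleach level (", signif(i_bleach, 4), ")")
  post <- bleach_frame:n
  out <- data.frame(time_s = time_s[post] - time_s[bleach_frame],
                    i_norm = (iun[post] - i_bleach) / (i_pre - i_bleach))
  attr(out, "i_pre") <- i_pre
  attr(out, "i_bleach") <- i_bleach
  out
}

#' Fit the mono-exponential recovery model to a normalized FRAP curve
#'
#' `I(t) = M * (1 - exp(-rate * t))` with mobile fraction `M` in [0, 1.5]
#' and `rate > 0`; the half-time is `-log(0.5)/rate`.  The coefficient of
#' determination is computed about the mean of the normalized post-bleach
#' points; fits with `R^2 <= r2_min` are marked invalid and excluded from
#' downstream dynamics profiles.
#'
#' @param norm data.frame from [normalize_frap()] (`time_s`, `i_norm`).
#' @param r2_min exclusion bound on R^2 (inclusive; default 0.7).
#' @param min_points minimum post-bleach points.
#' @return object of class `frap_fit`: `mobile_fraction`, `rate`,
#'   `half_time`, `r_squared`, `valid`, `converged`.
#' @export
fit_frap <- function(norm, r2_min = 0.7, min_points = 20L) {
  stopifnot(is.data.frame(norm), all(c("time_s", "i_norm") %in% names(norm)))
  if (nrow(norm) < min_points)
    stop("need >= ", min_points, " post-bleach points")
  t <- norm$time_s; y <- norm$i_norm
  bad <- structure(list(mobile_fraction = NA_real_, rate = NA_real_,
                        half_time = NA_real_, r_squared = NA_real_,
                        valid = FALSE, converged = FALSE),
                   class = "frap_fit")
  # plateau-based starting values
  m0 <- mean(tail(y, max(3L, length(y) %/% 10L)))
  m0 <- min(max(m0, 0.05), 1.5)
  half_idx <- which(y >= m0 / 2 & t > 0)
  tau0 <- if (length(half_idx)) max(t[half_idx[1]], diff(range(t)) / 100)
          else diff(range(t)) / 4
  fit <- tryCatch(
    nls(y ~ M * (1 - exp(-rate * t)), data = data.frame(t = t, y = y),
        start = list(M = m0, rate = log(2) / tau0),
        lower = c(M = 0, rate = 1e-8), upper = c(M = 1.5, rate = Inf),
        algorithm = "port",
        control = nls.control(maxiter = 500, scaleOffset = 1)),
    error = function(e) NULL)
  if (is.null(fit)) return(bad)
  cf <- coef(fit)
  res <- y - predict(fit)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_
  structure(list(mobile_fraction = unname(cf["M"]), rate = unname(cf["rate"]),
                 half_time = -log(0.5) / unname(cf["rate"]),
                 r_squared = r2,
                 valid = is.finite(r2) && r2 > r2_min,
                 converged = TRUE),
            class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  if (x$converged)
    cat(sprintf("<frap_fit> M %.3f, tau_1/2 %.3g s (R^2 %.3f, %s)\n",
                x$mobile_fraction, x$half_time, x$r_squared,
                if (x$valid) "valid" else "excluded"))
  else cat("<frap_fit> failed to converge\n")
  invisible(x)
}

#' Per-protein dynamics profile
#'
#' Aggregates valid fits into per-protein medians (with raw MADs) of the
#' FRAP half-time, mobile fraction and cytosolic dwell time.  Proteins with
#' fewer than `min_fits` valid fits are dropped with a warning.
#'
#' @param fits data.frame with columns `protein`, and any of `half_time`,
#'   `mobile_fraction`, `tau_d`, plus logical `valid`.
#' @param min_fits minimum number of valid fits per protein (default 3).
#' @return data.frame, one row per retained protein, with median and MAD
#'   columns for each available quantity.
#' @export
dynamics_profile <- function(fits, min_fits = 3L) {
  stopifnot(is.data.frame(fits), "protein" %in% names(fits))
  if (!"valid" %in% names(fits)) fits$valid <- TRUE
  fits <- fits[fits$valid & !is.na(fits$protein), , drop = FALSE]
  vars <- intersect(c("half_time", "mobile_fraction", "tau_d"), names(fits))
  if (!length(vars)) stop("no dynamics columns found")
  out <- list()
  for (p in sort_c(unique(fits$protein))) {
    sub <- fits[fits$protein == p, , drop = FALSE]
    if (nrow(sub) < min_fits) {
      warning("protein ", p, " has only ", nrow(sub),
              " valid fit(s); excluded from profile")
      next
    }
    row <- list(protein = p, n = nrow(sub))
    for (v in vars) {
      x <- sub[[v]][is.finite(sub[[v]])]
      row[[paste0("median_", v)]] <- stats::median(x)
      row[[paste0("mad_", v)]] <- raw_mad(x)
    }
    out[[p]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(data.frame())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
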