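#' Construct a correlation curve
#'
#' Curves store the *fluctuation* part of the normalized correlation,
#' \eqn{g(\tau) = \langle\delta I_x(t)\,\delta I_y(t+\tau)\rangle /
#' (\langle I_x\rangle\langle I_y\rangle)}, i.e. the conventional
#' \eqn{G(\tau)} minus its baseline of 1.  With this convention the particle
#' number is `1/g(0)` and well-behaved offsets sit near 0.
#'
#' @param lag strictly increasing lag values in seconds.
#' @param g correlation values (unitless, baseline-free).
#' @param channel_pair one of `"GG"`, `"RR"`, `"RG"`.
#' @param n_traces number of traces averaged into this curve.
#' @return object of class `correlation_curve`.
#' @export
correlation_curve <- function(lag, g, channel_pair = c("GG", "RR", "RG"),
                              n_traces = 1L) {
  channel_pair <- match.arg(channel_pair)
  lag <- as.numeric(lag); g <- as.numeric(g)
  if (length(lag) != length(g)) stop("lag and g lengths differ")
  if (length(lag) < 2) stop("curve needs at least 2 points")
  if (any(diff(lag) <= 0)) stop("lags must be strictly increasing")
  if (!all(is.finite(lag)) || !all(is.finite(g))) stop("non-finite curve values")
  structure(list(lag = lag, g = g, channel_pair = channel_pair,
                 n_traces = as.integer(n_traces)),
            class = "correlation_curve")
}

#' @export
print.correlation_curve <- function(x, ...) {
  cat(sprintf("<correlation_curve> %s: %d lags in [%.3g, %.3g] s, %d trace(s)\n",
              x$channel_pair, length(x$lag), min(x$lag), max(x$lag), x$n_traces))
  invisible(x)
}

#' Multi-tau correlation of two intensity traces
#'
#' Computes the normalized fluctuation correlation on a quasi-logarithmic
#' multi-tau grid: within each stage lags advance linearly in units of the
#' current bin width; after each stage the traces are rebinned pairwise
#' (means) and the bin width doubles.  For `x != y` the cross-correlation is
#' the symmetric average of the (x,y) and (y,x) estimates.
#'
#' The estimator uses symmetric (window-local monitor) normalization, the
#' standard choice in hardware correlators because it suppresses the
#' long-lag bias of whole-trace mean normalization:
#' `mean(x[1:(n-k)] * y[(1+k):n]) / (mean(x[1:(n-k)]) * mean(y[(1+k):n])) - 1`.
#'
#' @param trace_x,trace_y [intensity_trace]s of equal length and bin width.
#' @param bins_per_stage even number of linear lags per stage (default 16).
#' @param max_lag largest lag (s) to evaluate; default 1.1 s so the offset
#'   window of [summarize_curve()] is covered on a 10 s trace.
#' @return a [correlation_curve] (`GG`/`RR` for autocorrelation, `RG` for
#'   cross-correlation).
#' @examples
#' set.seed(1)
#' g <- intensity_trace(rpois(2e4, 5), 1e-4, "G")
#' multitau_correlate(g, g)
#' @export
multitau_correlate <- function(trace_x, trace_y, bins_per_stage = 16L,
                               max_lag = 1.1) {
  stopifnot(inherits(trace_x, "intensity_trace"),
            inherits(trace_y, "intensity_trace"))
  if (length(trace_x$counts) != length(trace_y$counts))
    stop("traces have different lengths")
  if (trace_x$bin_width != trace_y$bin_width)
    stop("traces have different bin widths")
  m <- as.integer(bins_per_stage)
  if (m < 2L || m %% 2L != 0L) stop("bins_per_stage must be even and >= 2")
  x <- trace_x$counts; y <- trace_y$counts
  if (mean(x) == 0 || mean(y) == 0)
    stop("zero-mean channel: normalization undefined")
  auto <- identical(trace_x$counts, trace_y$counts) &&
    trace_x$channel == trace_y$channel
  pair <- if (auto) paste0(trace_x$channel, trace_x$channel) else "RG"

  lags <- numeric(0); gs <- numeric(0)
  dt <- trace_x$bin_width; stage <- 0L
  repeat {
    ks <- if (stage == 0L) seq_len(m) else (m %/% 2L + 1L):m
    n <- length(x)
    done <- FALSE
    for (k in ks) {
      lag <- k * dt
      if (lag > max_lag || n - k < 2L) { done <- TRUE; break }
      i1 <- seq_len(n - k); i2 <- (k + 1L):n
      g1 <- mean(x[i1] * y[i2]) / (mean(x[i1]) * mean(y[i2])) - 1
      if (!auto) {
        g2 <- mean(y[i1] * x[i2]) / (mean(y[i1]) * mean(x[i2])) - 1
        g1 <- (g1 + g2) / 2
      }
      lags <- c(lags, lag)
      gs <- c(gs, g1)
    }
    if (done) break
    # pairwise rebinning; drop a trailing odd element
    n2 <- length(x) %/% 2L
    if (n2 < m) break
    idx <- seq_len(2L * n2)
    x <- (x[idx][c(TRUE, FALSE)] + x[idx][c(FALSE, TRUE)]) / 2
    y <- (y[idx][c(TRUE, FALSE)] + y[idx][c(FALSE, TRUE)]) / 2
    dt <- 2 * dt
    stage <- stage + 1L
  }
  if (length(lags) < 2) stop("trace too short for requested grid")
  correlation_curve(lags, gs, pair, n_traces = 1L)
}

#' Pointwise average of replicate correlation curves
#'
#' Replicates acquired sequentially from the same spot are correlated
#' individually and averaged pointwise, which suppresses slow drifts between
#' traces relative to correlating the concatenated trace.
#'
#' @param curves list of [correlation_curve]s on identical grids with the
#'   same channel pair.
#' @return a [correlation_curve] whose `n_traces` is the total count.
#' @export
average_curves <- function(curves) {
  if (!length(curves)) stop("empty curve list")
  ref <- curves[[1]]
  for (cv in curves) {
    stopifnot(inherits(cv, "correlation_curve"))
    if (!isTRUE(all.equal(cv$lag, ref$lag)) || cv$channel_pair != ref$channel_pair)
      stop("curves must share one lag grid and channel pair")
  }
  g <- rowMeans(vapply(curves, `[[`, numeric(length(ref$g)), "g"))
  correlation_curve(ref$lag, g, ref$channel_pair,
                    n_traces = sum(vapply(curves, `[[`, integer(1), "n_traces")))
}

#' Amplitude/offset summary of a correlation curve
#'
#' The amplitude is the median of `g` over the amplitude lag window and the
#' offset the median over the (much later) offset window; the spread is the
#' raw MAD (median absolute deviation about the median, no consistency
#' constant) of the amplitude-window points.  For cross-correlation (`RG`)
#' curves the baseline-corrected amplitude `G0` is clamped at zero: a
#' slightly negative cross-amplitude means no detectable co-diffusion.
#' Autocorrelation amplitudes are left unclamped.
#'
#' Both windows are closed intervals; defaults are the standard scoring
#' windows (41-point and 21-point regions of a 0.2-us-based vendor grid, but
#' the windows, not the point counts, are definitional here).
#'
#' @param curve a [correlation_curve].
#' @param amp_window,offset_window closed lag intervals in seconds.
#' @param min_points minimum points required inside each window.
#' @return object of class `curve_summary`: `amplitude` (median over the
#'   amplitude window), `offset`, `mad_amp`, `G0` (clamped for RG),
#'   `n_amp`, `n_off`, `channel_pair`.
#' @export
summarize_curve <- function(curve,
                            amp_window = c(25.6e-6, 81.92e-6),
                            offset_window = c(157.3e-3, 838.9e-3),
                            min_points = 5L) {
  stopifnot(inherits(curve, "correlation_curve"))
  ai <- curve$lag >= amp_window[1] & curve$lag <= amp_window[2]
  oi <- curve$lag >= offset_window[1] & curve$lag <= offset_window[2]
  if (sum(ai) < min_points)
    stop("amplitude window [", amp_window[1], ", ", amp_window[2],
         "] s covers only ", sum(ai), " grid points (need ", min_points, ")")
  if (sum(oi) < min_points)
    stop("offset window [", offset_window[1], ", ", offset_window[2],
         "] s covers only ", sum(oi), " grid points (need ", min_points, ")")
  amp <- stats::median(curve$g[ai])
  off <- stats::median(curve$g[oi])
  madv <- raw_mad(curve$g[ai])
  G0 <- amp - off
  if (curve$channel_pair == "RG") G0 <- max(G0, 0)
  structure(list(amplitude = amp, offset = off, mad_amp = madv, G0 = G0,
                 n_amp = sum(ai), n_off = sum(oi),
                 channel_pair = curve$channel_pair),
            class = "curve_summary")
}

#' @export
print.curve_summary <- function(x, ...) {
  cat(sprintf("<curve_summary> %s: amplitude %.4g, offset %.4g, MAD %.3g, G0 %.4g\n",
              x$channel_pair, x$amplitude, x$offset, x$mad_amp, x$G0))
  invisible(x)
}

#' Read / write a correlation-curve CSV
#'
#' Columns `lag_s`, `g_value`; the channel pair travels in a comment-free
#' extra column `channel_pair` (constant).
#'
#' @param path file path.
#' @return a [correlation_curve].
#' @export
read_curve_csv <- function(path) {
  df <- read_checked_csv(path, c("lag_s", "g_value"))
  pair <- if ("channel_pair" %in% names(df)) as.character(df$channel_pair[1]) else "GG"
  nt <- if ("n_traces" %in% names(df)) as.integer(df$n_traces[1]) else 1L
  correlation_curve(df$lag_s, df$g_value, pair, n_traces = nt)
}

#' @rdname read_curve_csv
#' @param curve a [correlation_curve] to write.
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "correlation_curve"))
  df <- data.frame(lag_s = curve$lag, g_value = curve$g,
                   channel_pair = curve$channel_pair, n_traces = curve$n_traces)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
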