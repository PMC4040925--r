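#' Parameters for the Brownian photon-trace simulator
#'
#' The simulator propagates three species — unbound red, unbound green, and
#' red--green complex — by free diffusion through a periodic cubic box and
#' generates binned photon counts for two confocal detection volumes
#' (3D Gaussians).  It is the package's physics oracle: traces made here are
#' pushed through the same correlator, calibration and Ka machinery as real
#' data, with known ground truth.
#'
#' @param conc_r,conc_g,conc_rg species concentrations in particles per
#'   femtoliter (1 fl = 1 um^3).
#' @param d_r,d_g,d_rg diffusion coefficients in cm^2/s.
#' @param w0_g,w0_r radial 1/e^2 detection radii (um).
#' @param z0_g,z0_r axial radii (um).
#' @param offset separation of the two detection-volume centers along x (um).
#' @param brightness_g,brightness_r molecular brightness at beam center
#'   (counts/s per fluorophore).
#' @param dark_red_frac fraction of red fluorophores that are immature
#'   (dark), applied per particle at creation.
#' @param bleedthrough fraction of expected green counts added to the red
#'   channel before the Poisson draw.
#' @param dark_rate detector dark count rate (counts/s, both channels).
#' @param bin_width photon binning time (s).
#' @param duration length of one trace (s).
#' @param n_traces number of sequentially acquired traces per measurement.
#' @param box edge of the periodic cubic box (um); must be >= 8 * max axial
#'   radius so boundary artifacts are negligible.
#' @param seed integer seed; same seed gives bit-identical traces.
#' @return object of class `sim_params`.
#' @export
sim_params <- function(conc_r = 10, conc_g = 10, conc_rg = 0,
                       d_r = 2e-7, d_g = 2e-7, d_rg = 1.2e-7,
                       w0_g = 0.19, w0_r = 0.23, z0_g = 1.9, z0_r = 2.3,
                       offset = 0,
                       brightness_g = 3e4, brightness_r = 3e4,
                       dark_red_frac = 0, bleedthrough = 0,
                       dark_rate = 0, bin_width = 2e-6, duration = 10,
                       n_traces = 10L, box = 8 * max(z0_g, z0_r),
                       seed = 1L) {
  p <- list(conc = c(r = conc_r, g = conc_g, rg = conc_rg),
            D = c(r = d_r, g = d_g, rg = d_rg),
            w0_g = w0_g, w0_r = w0_r, z0_g = z0_g, z0_r = z0_r,
            offset = offset,
            brightness_g = brightness_g, brightness_r = brightness_r,
            dark_red_frac = dark_red_frac, bleedthrough = bleedthrough,
            dark_rate = dark_rate, bin_width = bin_width,
            duration = duration, n_traces = as.integer(n_traces),
            box = box, seed = as.integer(seed))
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  if (any(p$conc < 0)) stop("concentrations must be >= 0")
  if (any(p$D <= 0)) stop("diffusion coefficients must be > 0")
  if (p$bin_width <= 0 || p$duration <= 0) stop("times must be > 0")
  if (p$n_traces < 1) stop("n_traces must be >= 1")
  for (f in c("dark_red_frac", "bleedthrough"))
    if (p[[f]] < 0 || p[[f]] > 1) stop(f, " must lie in [0, 1]")
  if (p$dark_rate < 0) stop("dark_rate must be >= 0")
  zmax <- max(p$z0_g, p$z0_r)
  if (p$box < 8 * zmax)
    stop("box edge (", p$box, " um) must be >= 8 * max axial radius (",
         8 * zmax, " um) to avoid boundary artifacts")
  invisible(p)
}

#' Simulate two-channel photon traces
#'
#' @param params a [sim_params] object.
#' @return list of length `params$n_traces`; each element is a list with
#'   [intensity_trace]s `green` and `red`.  Particle positions are redrawn
#'   for each trace (sequential acquisitions are independent).
#' @details A warning is raised when the bin width exceeds a tenth of the
#'   fastest diffusion time `w0^2/(4D)`, where the discrete-step
#'   approximation starts to distort the correlation decay.
#' @examples
#' p <- sim_params(conc_r = 0, conc_g = 0, dark_rate = 1000,
#'                 bin_width = 1e-3, duration = 0.5, n_traces = 1)
#' tr <- simulate_ffs_traces(p)[[1]]
#' mean(tr$green$counts)  # ~1 dark count per bin
#' @export
simulate_ffs_traces <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  d_um <- params$D * 1e8  # cm^2/s -> um^2/s
  d_present <- d_um[params$conc > 0]
  tau_fast <- if (length(d_present))
    min(params$w0_g, params$w0_r)^2 / (4 * max(d_present)) else Inf
  if (params$bin_width > tau_fast / 10)
    warning(sprintf(
      "bin width %.3g s exceeds tau_D/10 of the fastest species (%.3g s)",
      params$bin_width, tau_fast / 10))
  n_bins <- max(2L, as.integer(round(params$duration / params$bin_width)))
  vol <- params$box^3  # um^3 == fl
  set.seed(params$seed)
  lapply(seq_len(params$n_traces), function(i) {
    np <- rpois(3, params$conc * vol)  # order: r, g, rg
    m <- cpp_simulate_trace_pair(
      n_bins, params$bin_width, as.integer(np), d_um,
      params$w0_g, params$z0_g, params$w0_r, params$z0_r, params$offset,
      params$brightness_g, params$brightness_r,
      params$dark_red_frac, params$bleedthrough, params$dark_rate, params$box)
    list(green = intensity_trace(m[, 1], params$bin_width, "G",
                                 dark_rate = params$dark_rate),
         red   = intensity_trace(m[, 2], params$bin_width, "R",
                                 dark_rate = params$dark_rate))
  })
}

#' Closed-form single-component FCS autocorrelation
#'
#' Evaluates the free-diffusion model for a 3D-Gaussian volume,
#' \deqn{g(\tau) = \frac{1}{N}\,\frac{1}{1+\tau/\tau_D}\,
#'   \frac{1}{\sqrt{1+\tau/(s^2\tau_D)}} + G_\infty,}
#' in the package's baseline-free convention (the conventional
#' \eqn{G(\tau)} equals this plus 1).
#'
#' @param N mean particle number in the effective volume (> 0).
#' @param tau_d diffusion (dwell) time in s (> 0).
#' @param s structural parameter, axial/radial aspect ratio (> 0).
#' @param g_inf additive offset.
#' @param lag lag grid in seconds.
#' @param channel_pair stored channel-pair label.
#' @return a [correlation_curve].
#' @export
closed_form_fcs_curve <- function(N, tau_d, s, g_inf = 0, lag,
                                  channel_pair = "GG") {
  if (N <= 0 || tau_d <= 0 || s <= 0)
    stop("N, tau_d and s must be > 0")
  g <- 1 / N / (1 + lag / tau_d) / sqrt(1 + lag / (s^2 * tau_d)) + g_inf
  correlation_curve(lag, g, channel_pair)
}

#' Parameters for the FRAP curve generator
#'
#' @param mobile_fraction true mobile fraction M in [0, 1].
#' @param half_time true recovery half-time (s, > 0).
#' @param frame_interval imaging interval (s).
#' @param n_prebleach number of pre-bleach frames.
#' @param post_duration post-bleach acquisition length (s; protocols run at
#'   least 180 s so slow components plateau).
#' @param pre_level mean pre-bleach intensity (a.u.).
#' @param background background level (a.u.).
#' @param noise_sd additive Gaussian noise sd (a.u., >= 0).
#' @param bleach_floor residual normalized intensity immediately after
#'   bleaching (0 = complete bleach of the structure).
#' @param seed integer seed.
#' @return object of class `frap_sim_params`.
#' @export
frap_sim_params <- function(mobile_fraction = 0.8, half_time = 30,
                            frame_interval = 3, n_prebleach = 10L,
                            post_duration = 180, pre_level = 100,
                            background = 10, noise_sd = 1,
                            bleach_floor = 0, seed = 1L) {
  if (mobile_fraction < 0 || mobile_fraction > 1)
    stop("mobile_fraction must lie in [0, 1]")
  if (half_time <= 0) stop("half_time must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (post_duration <= 0 || frame_interval <= 0) stop("times must be > 0")
  structure(list(mobile_fraction = mobile_fraction, half_time = half_time,
                 frame_interval = frame_interval,
                 n_prebleach = as.integer(n_prebleach),
                 post_duration = post_duration, pre_level = pre_level,
                 background = background, noise_sd = noise_sd,
                 bleach_floor = bleach_floor, seed = as.integer(seed)),
            class = "frap_sim_params")
}

#' Simulate a raw FRAP trace with background
#'
#' Pre-bleach frames sit at the pre-bleach level; from the bleach frame on,
#' the raw intensity follows
#' `background + (pre - background) * (floor + (1 - floor) * M * (1 - exp(-rate * t)))`
#' with `rate = -log(0.5) / half_time` and `t = 0` at the first post-bleach
#' frame.  Gaussian noise is added to the ROI trace.
#'
#' @param params a [frap_sim_params] object.
#' @return data.frame with `time_s`, `intensity`, `background` and attribute
#'   `bleach_frame` (index of the first post-bleach frame).
#' @export
simulate_frap_curve <- function(params) {
  stopifnot(inherits(params, "frap_sim_params"))
  set.seed(params$seed)
  n_post <- ceiling(params$post_duration / params$frame_interval) + 1L
  n <- params$n_prebleach + n_post
  time <- (seq_len(n) - 1) * params$frame_interval
  t_post <- (seq_len(n_post) - 1) * params$frame_interval
  rate <- -log(0.5) / params$half_time
  rec <- params$bleach_floor +
    (1 - params$bleach_floor) * params$mobile_fraction * (1 - exp(-rate * t_post))
  level <- c(rep(1, params$n_prebleach), rec)
  roi <- params$background + (params$pre_level - params$background) * level
  if (params$noise_sd > 0) roi <- roi + rnorm(n, 0, params$noise_sd)
  df <- data.frame(time_s = time, intensity = roi,
                   background = rep(params$background, n))
  attr(df, "bleach_frame") <- params$n_prebleach + 1L
  df
}

#' Canonical 13-protein adhesome network fixture
#'
#' Thirteen core components of cell--matrix adhesion sites and the eleven
#' pairwise cytosolic physical associations recoverable from published
#' cross-correlation screens of this system.  Greek-letter names are stored
#' ASCII-safe (`alpha-parvin`, `alpha-actinin`).
#'
#' @return list with `nodes` (character, length 13) and `edges`
#'   (data.frame `protein_a`, `protein_b`, 11 rows, endpoints sorted within
#'   each row, rows sorted).
#' @export
make_network_fixture <- function() {
  nodes <- sort_c(c("alpha-actinin", "alpha-parvin", "CAS", "CSK", "FAK",
                  "ILK", "paxillin", "PINCH", "talin", "tensin", "VASP",
                  "vinculin", "zyxin"))
  e <- rbind(
    c("ILK", "PINCH"),
    c("ILK", "alpha-parvin"),
    c("PINCH", "alpha-parvin"),
    c("CAS", "FAK"),
    c("CAS", "paxillin"),
    c("FAK", "paxillin"),
    c("paxillin", "vinculin"),
    c("VASP", "zyxin"),
    c("VASP", "alpha-actinin"),
    c("VASP", "vinculin"),
    c("CAS", "zyxin"))
  e <- t(apply(e, 1, sort_c))
  edges <- data.frame(protein_a = e[, 1], protein_b = e[, 2],
                      stringsAsFactors = FALSE)
  edges <- edges[order_c(edges$protein_a, edges$protein_b), , drop = FALSE]
  rownames(edges) <- NULL
  stopifnot(all(edges$protein_a %in% nodes), all(edges$protein_b %in% nodes),
            all(edges$protein_a != edges$protein_b))
  list(nodes = nodes, edges = edges)
}

#' Simulate association-score cohorts
#'
#' Draws a negative-control cohort located at 0 and a protein-pair cohort
#' located at `shift`, both from a heavy-tailed location-scale t
#' distribution (per-cell association scores are markedly non-normal, which
#' is why the pipeline's tests are nonparametric).
#'
#' @param n_pair,n_neg cohort sizes (>= 5).
#' @param shift location of the pair cohort (score units).
#' @param spread scale of both cohorts (score units, > 0).
#' @param df t degrees of freedom (default 3: heavy tails, finite variance).
#' @param seed integer seed.
#' @return list with numeric vectors `pair` and `neg`.
#' @export
simulate_score_cohorts <- function(n_pair, n_neg, shift = 0, spread = 1,
                                   df = 3, seed = 1L) {
  if (n_pair < 5 || n_neg < 5) stop("cohort sizes must be >= 5")
  if (spread <= 0) stop("spread must be > 0")
  set.seed(as.integer(seed))
  list(pair = shift + spread * rt(n_pair, df),
       neg = spread * rt(n_neg, df))
}
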