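#' Andrade-type viscosity model for water
#'
#' \eqn{\eta(T) = A \cdot 10^{B/(T-C)}}, the standard three-parameter fit
#' for liquid water.  Defaults are the usual handbook constants.
#'
#' @param A prefactor (Pa s).
#' @param B,C model constants (K); the model is singular at `T = C`.
#' @return object of class `viscosity_model`.
#' @export
viscosity_model <- function(A = 2.414e-5, B = 247.8, C = 140) {
  if (A <= 0 || B <= 0) stop("A and B must be > 0")
  structure(list(A = A, B = B, C = C), class = "viscosity_model")
}

#' Viscosity of water at a temperature
#'
#' @param T_k absolute temperature (K), must exceed the model's `C`.
#' @param model a [viscosity_model].
#' @return viscosity in Pa s.
#' @examples
#' water_viscosity(298.15)  # ~8.9e-4 Pa s
#' @export
water_viscosity <- function(T_k, model = viscosity_model()) {
  stopifnot(inherits(model, "viscosity_model"))
  if (any(T_k <= model$C))
    stop("temperature must exceed the model singularity at C = ", model$C, " K")
  model$A * 10^(model$B / (T_k - model$C))
}

#' Reference dye for detection-volume calibration
#'
#' @param name dye name (provenance only).
#' @param d_ref literature diffusion coefficient at `t_ref` (cm^2/s).
#' @param t_ref reference temperature (K).
#' @return object of class `dye_reference`.
#' @export
dye_reference <- function(name, d_ref, t_ref = 298.15) {
  if (d_ref <= 0) stop("d_ref must be > 0")
  structure(list(name = name, d_ref = d_ref, t_ref = t_ref),
            class = "dye_reference")
}

#' Temperature-scale a diffusion coefficient
#'
#' Stokes--Einstein scaling
#' \eqn{D(T_2) = D(T_1)\,(T_2/T_1)\,\eta(T_1)/\eta(T_2)}.
#'
#' @param ref a [dye_reference].
#' @param t_target target temperature (K).
#' @param model a [viscosity_model].
#' @return diffusion coefficient at `t_target` (cm^2/s).
#' @examples
#' og <- dye_reference("Oregon green", 4.11e-6)
#' scale_diffusion(og, 310.15)  # ~5.51e-6 cm^2/s
#' @export
scale_diffusion <- function(ref, t_target, model = viscosity_model()) {
  stopifnot(inherits(ref, "dye_reference"))
  ref$d_ref * (t_target / ref$t_ref) *
    water_viscosity(ref$t_ref, model) / water_viscosity(t_target, model)
}

#' Beam waist from a dye dwell time
#'
#' \eqn{\omega_0 = \sqrt{4 D \tau_D}}.
#'
#' @param tau_d fitted dwell time of the reference dye (s).
#' @param D its diffusion coefficient at measurement temperature (cm^2/s).
#' @return radial 1/e^2 radius in cm.
#' @export
beam_waist <- function(tau_d, D) {
  if (tau_d <= 0 || D <= 0) stop("tau_d and D must be > 0")
  sqrt(4 * D * tau_d)
}

#' Effective confocal volume
#'
#' \eqn{V_{eff} = \pi^{3/2}\,\omega_0^2\, z_0} with \eqn{z_0 = s\,\omega_0}.
#'
#' @param w0 radial radius in cm.
#' @param s structural parameter (axial/radial ratio).
#' @return effective volume in femtoliters (1 fl = 1e-12 cm^3).
#' @export
effective_volume <- function(w0, s) {
  if (w0 <= 0 || s <= 0) stop("w0 and s must be > 0")
  pi^(3 / 2) * w0^2 * (s * w0) / 1e-12
}

#' Red-fluorophore maturation factor
#'
#' From a 1:1 red--green tandem construct, the apparent red/green particle
#' ratio corrected for the different detection volumes:
#' \eqn{\phi = (N_{red}/N_{green}) \cdot V_G/V_R}.  Values below 1 quantify
#' the dark (immature) red fraction.
#'
#' @param particle_ratio measured `N_red / N_green` from the tandem construct.
#' @param v_g,v_r green and red effective volumes (fl).
#' @return the unitless factor.
#' @examples
#' maturation_factor(0.94, 0.38, 0.67)  # ~0.53
#' @export
maturation_factor <- function(particle_ratio, v_g, v_r) {
  if (particle_ratio <= 0 || v_g <= 0 || v_r <= 0)
    stop("inputs must be > 0")
  particle_ratio * v_g / v_r
}

#' Overlap volume from tandem-construct particle numbers
#'
#' For a construct in which every particle carries both fluorophores, the
#' overlap volume is estimated from each channel and averaged:
#' \eqn{V_{RG}^{G} = N_{RG} V_G / (\phi N_{GG})} and
#' \eqn{V_{RG}^{R} = N_{RG} V_R / N_{RR}}.
#'
#' @param n_rg,n_gg,n_rr particle numbers from the tandem measurement.
#' @param v_g,v_r channel effective volumes (fl).
#' @param phi maturation factor.
#' @return mean of the two channel estimates (fl); warns if a channel
#'   estimate exceeds its own channel volume (unphysical for a tandem).
#' @export
overlap_volume <- function(n_rg, n_gg, n_rr, v_g, v_r, phi) {
  if (any(c(n_rg, n_gg, n_rr, v_g, v_r, phi) <= 0)) stop("inputs must be > 0")
  v_green <- n_rg * v_g / (phi * n_gg)
  v_red <- n_rg * v_r / n_rr
  if (n_rg > n_gg / phi || n_rg > n_rr)
    warning("more complexes than particles in a channel: unphysical ",
            "for a tandem construct")
  (v_green + v_red) / 2
}

#' Instrument calibration set
#'
#' Bundles the constants every Ka computation needs.  Defaults are a
#' complete, internally consistent published calibration for a two-color
#' confocal setup (green/red effective volumes 0.38/0.67 fl, overlap volume
#' 0.34 fl, maturation factor 0.53, structural parameter 10); every field
#' can be overridden, or the whole set recomputed from dye references with
#' [calibrate_from_dyes()].
#'
#' @param v_g,v_r,v_rg effective and overlap volumes (fl).
#' @param phi maturation factor (0 < phi <= 1.5).
#' @param s structural parameter.
#' @param dark_rate detector dark count rate (counts/s).
#' @param provenance free-form list recorded alongside (dye names, dwell
#'   times, date).
#' @return object of class `calibration_set`.
#' @export
calibration_set <- function(v_g = 0.38, v_r = 0.67, v_rg = 0.34,
                            phi = 0.53, s = 10, dark_rate = 300,
                            provenance = list()) {
  if (v_g <= 0 || v_r <= 0 || v_rg <= 0) stop("volumes must be > 0")
  if (phi <= 0 || phi > 1.5) stop("phi must lie in (0, 1.5]")
  if (v_rg > max(v_g, v_r) * (1 + 1e-6))
    warning("overlap volume exceeds both channel volumes")
  structure(list(v_g = v_g, v_r = v_r, v_rg = v_rg, phi = phi, s = s,
                 dark_rate = dark_rate, provenance = provenance),
            class = "calibration_set")
}

#' @export
print.calibration_set <- function(x, ...) {
  cat(sprintf(
    "<calibration_set> V_G %.2f fl, V_R %.2f fl, V_RG %.2f fl, phi %.2f, s %.3g, dark %.0f Hz\n",
    x$v_g, x$v_r, x$v_rg, x$phi, x$s, x$dark_rate))
  invisible(x)
}

#' Recompute a calibration set from dye references
#'
#' Runs the full chain: temperature-scale each dye's diffusion coefficient,
#' derive the beam waists from the fitted dwell times, form the effective
#' volumes, the maturation factor from the tandem particle ratio, and the
#' overlap volume from the tandem particle numbers.
#'
#' @param green_dye,red_dye [dye_reference]s.
#' @param tau_d_g,tau_d_r fitted dye dwell times (s).
#' @param s structural parameter (fixed from tandem-construct fits).
#' @param temperature measurement temperature (K).
#' @param tandem_ratio tandem-construct `N_red / N_green`.
#' @param tandem_counts optional named list/vector with `n_rg`, `n_gg`,
#'   `n_rr` from the tandem FCCS measurement; if omitted, `v_rg` must be
#'   given.
#' @param v_rg optional externally determined overlap volume (fl).
#' @param dark_rate detector dark rate (counts/s).
#' @param model a [viscosity_model].
#' @return a [calibration_set] with provenance filled in.
#' @export
calibrate_from_dyes <- function(green_dye, red_dye, tau_d_g, tau_d_r,
                                s = 10, temperature = 310.15,
                                tandem_ratio = 0.94, tandem_counts = NULL,
                                v_rg = NULL, dark_rate = 300,
                                model = viscosity_model()) {
  d_g <- scale_diffusion(green_dye, temperature, model)
  d_r <- scale_diffusion(red_dye, temperature, model)
  v_g <- effective_volume(beam_waist(tau_d_g, d_g), s)
  v_r <- effective_volume(beam_waist(tau_d_r, d_r), s)
  phi <- maturation_factor(tandem_ratio, v_g, v_r)
  if (is.null(v_rg)) {
    if (is.null(tandem_counts))
      stop("either tandem_counts or v_rg must be supplied")
    tc <- as.list(tandem_counts)
    v_rg <- overlap_volume(tc$n_rg, tc$n_gg, tc$n_rr, v_g, v_r, phi)
  }
  calibration_set(v_g = v_g, v_r = v_r, v_rg = v_rg, phi = phi, s = s,
                  dark_rate = dark_rate,
                  provenance = list(green_dye = green_dye$name,
                                    red_dye = red_dye$name,
                                    tau_d_g = tau_d_g, tau_d_r = tau_d_r,
                                    temperature = temperature,
                                    d_g = d_g, d_r = d_r,
                                    tandem_ratio = tandem_ratio))
}

#' Serialize / deserialize a calibration set as JSON
#'
#' @param calib a [calibration_set].
#' @param path file path.
#' @return `read_calibration_json` returns a [calibration_set].
#' @export
write_calibration_json <- function(calib, path) {
  stopifnot(inherits(calib, "calibration_set"))
  jsonlite::write_json(unclass(calib), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_set(v_g = x$v_g, v_r = x$v_r, v_rg = x$v_rg, phi = x$phi,
                  s = x$s, dark_rate = x$dark_rate,
                  provenance = x$provenance %||% list())
}
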