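# Desk-scale simulation world shared by tests and the acceptance script.
#
# The physical regime is scaled down from a dye/protein FCCS experiment so a
# replicate runs in seconds on one CPU: a smaller axial ratio shrinks the
# periodic box (fewer particles), slower diffusion allows coarser photon
# bins, and trace durations are 2.5-10 s instead of 10 x 10 s.  The physics
# being tested (free diffusion through 3D-Gaussian volumes, Poisson
# photons) is unchanged; lag windows scale with the grid.

desk <- list(
  w0 = 0.2,            # um, both channels
  s = 1.5,             # structural parameter (axial/radial)
  D = 2e-8,            # cm^2/s -> tau_D = 5 ms
  bin = 2e-4,          # s
  amp_window = c(2e-4, 2e-3),     # s, early-lag plateau of the 5 ms decay
  offset_window = c(0.05, 0.45),  # s, >> tau_D
  max_lag = 0.5)
desk$z0 <- desk$s * desk$w0
desk$veff <- pi^1.5 * desk$w0^2 * desk$z0        # fl
desk$tau_d <- (desk$w0 * 1e-4)^2 / (4 * desk$D)  # s
desk$conc5 <- 5 / desk$veff                      # particles/fl giving N ~ 5

# species: "green" (single species autocorrelation), "complex" (all
# particles carry both labels), "independent" (uncorrelated red + green)
desk_params <- function(species = c("green", "complex", "independent"),
                        seed, duration = 10, n_traces = 1L,
                        brightness = 5e4, dark_red_frac = 0,
                        bleedthrough = 0, dark_rate = 0) {
  species <- match.arg(species)
  conc <- switch(species,
                 green = c(0, desk$conc5, 0),
                 complex = c(0, 0, desk$conc5),
                 independent = c(desk$conc5, desk$conc5, 0))
  suppressWarnings(sim_params(
    conc_r = conc[1], conc_g = conc[2], conc_rg = conc[3],
    d_r = desk$D, d_g = desk$D, d_rg = desk$D,
    w0_g = desk$w0, w0_r = desk$w0, z0_g = desk$z0, z0_r = desk$z0,
    brightness_g = brightness, brightness_r = brightness,
    dark_red_frac = dark_red_frac, bleedthrough = bleedthrough,
    dark_rate = dark_rate, bin_width = desk$bin, duration = duration,
    n_traces = n_traces, seed = seed))
}

desk_summarize <- function(curve)
  summarize_curve(curve, desk$amp_window, desk$offset_window)
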