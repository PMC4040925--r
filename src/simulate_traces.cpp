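#include <Rcpp.h>
using namespace Rcpp;

// Brownian-dynamics photon-trace generator for a two-color confocal setup.
//
// Three diffusing species (red-only, green-only, red--green complex) move by
// free diffusion in a periodic cubic box.  Each bin, every particle deposits
// an expected photon count into its channel(s) according to a 3D-Gaussian
// detection profile; bleedthrough and dark counts are added to the expected
// rates and the realized counts are Poisson draws.  All randomness comes from
// R's RNG stream, so set.seed() in R gives bit-identical output.
//
// Units at this interface: lengths in micrometers, D in um^2/s, time in s,
// brightness in counts/s at beam center.

// [[Rcpp::export]]
IntegerMatrix cpp_simulate_trace_pair(int n_bins, double dt,
                                      IntegerVector n_particles,
                                      NumericVector D_um2s,
                                      double w0_g, double z0_g,
                                      double w0_r, double z0_r,
                                      double offset_x,
                                      double bright_g, double bright_r,
                                      double dark_red_frac,
                                      double bleedthrough,
                                      double dark_rate,
                                      double box) {
  if (n_bins < 1) stop("n_bins must be >= 1");
  const double half = box / 2.0;
  NumericVector exG(n_bins, 0.0), exR(n_bins, 0.0);

  // gauss argument beyond which the contribution is < ~1e-15 of peak
  const double cutoff = 34.0;

  for (int sp = 0; sp < 3; ++sp) {
    const int np = n_particles[sp];
    if (np == 0) continue;
    const double sd = std::sqrt(2.0 * D_um2s[sp] * dt);
    const bool emits_g = (sp == 1 || sp == 2);
    const bool emits_r = (sp == 0 || sp == 2);
    for (int p = 0; p < np; ++p) {
      double x = R::runif(-half, half);
      double y = R::runif(-half, half);
      double z = R::runif(-half, half);
      // immature (dark) red fluorophore decided once per particle
      bool dark_red = false;
      if (emits_r && dark_red_frac > 0.0)
        dark_red = (R::unif_rand() < dark_red_frac);
      for (int b = 0; b < n_bins; ++b) {
        if (emits_g) {
          double a = 2.0 * (x * x + y * y) / (w0_g * w0_g)
                   + 2.0 * (z * z) / (z0_g * z0_g);
          if (a < cutoff) exG[b] += bright_g * std::exp(-a) * dt;
        }
        if (emits_r && !dark_red) {
          double dx = x - offset_x;
          double a = 2.0 * (dx * dx + y * y) / (w0_r * w0_r)
                   + 2.0 * (z * z) / (z0_r * z0_r);
          if (a < cutoff) exR[b] += bright_r * std::exp(-a) * dt;
        }
        // Brownian step with periodic wrap
        x += R::norm_rand() * sd;
        y += R::norm_rand() * sd;
        z += R::norm_rand() * sd;
        if (x >= half) x -= box; else if (x < -half) x += box;
        if (y >= half) y -= box; else if (y < -half) y += box;
        if (z >= half) z -= box; else if (z < -half) z += box;
      }
    }
  }

  IntegerMatrix out(n_bins, 2);
  const double dark = dark_rate * dt;
  for (int b = 0; b < n_bins; ++b) {
    double lam_g = exG[b] + dark;
    double lam_r = exR[b] + bleedthrough * exG[b] + dark;
    out(b, 0) = (int) R::rpois(lam_g);
    out(b, 1) = (int) R::rpois(lam_r);
  }
  return out;
}
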