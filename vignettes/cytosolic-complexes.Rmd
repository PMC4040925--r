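---
title: "Detecting cytosolic protein complexes by two-color FCCS: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting cytosolic protein complexes by two-color FCCS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fccsnet)
```

# The measurement model

Two proteins are tagged with spectrally distinct fluorophores (a green
monomeric GFP variant and a tandem red mKate2) and their fluorescence is
recorded from a diffraction-limited confocal volume in the cytosol. If the
proteins are physically associated they diffuse together, and the photon
fluctuations in the two channels co-vary. The normalized cross-correlation

$$g_{xy}(\tau) = \frac{\langle \delta I_x(t)\,\delta I_y(t+\tau)\rangle}
                      {\langle I_x\rangle \langle I_y\rangle}$$

has amplitude proportional to the concentration of double-labelled
complexes, while each autocorrelation amplitude is the inverse of the
particle number in that channel's effective volume, $N = 1/g(0)$. The
single-species autocorrelation of free diffusion through a 3D-Gaussian
volume is

$$g(\tau) = \frac{1}{N}\,\frac{1}{1+\tau/\tau_D}\,
            \frac{1}{\sqrt{1+\tau/(s^2\tau_D)}} + G_\infty ,$$

with dwell time $\tau_D = \omega_0^2/4D$ and structural parameter
$s = z_0/\omega_0$.

**Curve convention.** Correlation curves are stored *baseline-free*
($g = G - 1$ relative to the textbook definition that includes the
constant 1). All amplitude arithmetic ($N = 1/G_0$) requires the
baseline-free quantity, and the quality-control bounds on curve offsets
(a few $10^{-3}$) only make sense in this convention.

**Estimator.** The multi-tau correlator doubles the lag spacing every 16
lags after pairwise rebinning, covering microseconds to seconds in a few
hundred points. Each point uses *symmetric normalization* — the monitor
means are computed over exactly the samples entering the lagged product.
We chose this over whole-trace normalization after observing, on
simulated independent species, a systematic negative bias of the long-lag
estimate (and hence a spurious positive bias of amplitude-minus-offset
scores); symmetric normalization is also what hardware correlators
implement. Cross-correlations average the $(x,y)$ and $(y,x)$ estimates.

**Amplitude and offset windows.** Amplitudes are medians of the curve over
an early-lag window, minus the median over a much later offset window
(defaults $[25.6, 81.92]\,\mu s$ and $[157.3, 838.9]\,ms$, treated as
closed intervals; the vendor grid's "41 and 21 points" are a property of
one correlator, the windows are the definition). Windows are arguments of
`summarize_curve()` because a correlator with a different base bin (such
as the desk-scale simulations below) needs proportionally scaled windows.
Negative cross-amplitudes are clamped to zero for the $K_a$ pathway (no
detectable association), but the association score keeps the signed value.

# From amplitudes to an apparent association constant

Particle numbers $N_{GG} = 1/G_0^G$, $N_{RR} = 1/G_0^R$,
$N_{RG} = G_0^{RG} N_{RR} N_{GG}$ are converted to concentrations with
three calibration volumes and a maturation factor:

$$K_a = \frac{N_{RG}/(V_{RG}\phi)}
             {\{N_{RR}/(V_R\phi) - N_{RG}/(V_{RG}\phi)\}\,
              \{N_{GG}/V_G - N_{RG}/(V_{RG}\phi)\}}.$$

$\phi$ corrects for the slow maturation of the red fluorophore: a fraction
$1-\phi$ of red tags is dark, so red-containing particle numbers are
undercounted by $\phi$. It is measured with a 1:1 red--green tandem
construct as $\phi = (N_{red}/N_{green})\cdot V_G/V_R$.

$K_a$ is reported primarily in fl (volume per particle) — faithful to the
particle-number formulation — with the conversion to $M^{-1}$ by
$N_A \cdot 10^{-15}$. A negative free concentration means the
cross-correlation curve was too noisy; the measurement is flagged
(`negative_ka`) and excluded rather than reported.

## Calibration chain and its one ambiguity

Default constants ship as a complete published calibration
($V_G = 0.38$, $V_R = 0.67$, $V_{RG} = 0.34$ fl, $\phi = 0.53$, $s = 10$)
and can be recomputed from dye references with `calibrate_from_dyes()`:
viscosity $\eta(T) = A\cdot 10^{B/(T-C)}$, Stokes--Einstein temperature
scaling $D(T_2) = D(T_1)(T_2/T_1)\eta(T_1)/\eta(T_2)$, beam waist
$\omega_0 = \sqrt{4D\tau_D}$, volume $\pi^{3/2}\omega_0^2 z_0$. One
genuine ambiguity: the red dye's free-fit dwell time (24 μs) reproduces
$V_R = 0.67$ fl, whereas the fixed-$s$ refit (23.34 μs) gives 0.65 fl.
The dwell time is therefore an explicit input, never hard-coded; the
reference value 0.67 fl corresponds to 24 μs.

```{r calibration}
cal <- calibrate_from_dyes(
  green_dye = dye_reference("Oregon green", 4.11e-6),
  red_dye = dye_reference("Atto 655-maleimide", 4.09e-6),
  tau_d_g = 16.38e-6, tau_d_r = 24e-6, s = 10,
  tandem_ratio = 0.94, v_rg = 0.34)
cal
```

# Quality control

Four rules, all boundaries inclusive exactly as specified:
(i) counts-per-molecule $(C - C_D)/N \le 215$ Hz in either channel
(particle signal too weak); (ii) an autocorrelation offset
$\ge 0.0025$ or $\le -0.002$ (drift/movement); (iii)
$(C_G - C_D)/(C_R - C_D) \ge 20$ (green-to-red bleedthrough risk); (iv)
negative $K_a$. Whether rule (ii) should also cover the cross-curve is
ambiguous in its source ("in one or two of the channels"); we apply it to
the two auto-curves only, with a `check_cross_offset` switch.

# Cohort statistics

The per-cell **association score**
$(\tilde x_{amp} - \tilde x_{off})/\mathrm{MAD}(amp)$ uses the raw MAD
(no 1.4826 consistency factor). Score distributions are heavy-tailed, so
all tests are nonparametric and exact where feasible:

* **Pair vs negative control** — the stated test is an exact test of
  equality of medians. We operationalize it as Mood's median test: pool
  both cohorts, dichotomize at the pooled median (ties count "below"),
  and evaluate the one-sided hypergeometric tail of the 2×2 table. This
  is a documented construction choice: it is the standard exact test
  whose null hypothesis is exactly the stated one.
* **Near vs far, coupled** — one-sample Wilcoxon signed-rank on per-cell
  differences, Pratt handling of zero differences (zeros are ranked,
  then dropped), exact null by convolution over the realized mid-ranks
  (ties exact) up to $n = 25$, then a normal approximation with
  continuity correction. All three alternatives are reported.
* **Near vs far, uncoupled** — the source names a "two-samples Wilcoxon
  signed rank test", which does not exist for unpaired unequal samples;
  we implement the rank-sum (Mann--Whitney) test, exact by dynamic
  programming over mid-rank subsets up to pooled $n = 30$.

No multiple-testing correction is applied by default (fixed raw
thresholds are the convention here); `adjust_bh()` is available.

# Network inference

An edge requires $p < 10^{-4}$ in the primary cell line and, when a
second line was measured, $p < 0.02$ there too (strict inequalities).
Candidate ternary (and larger) complexes are maximal cliques of size
$\ge 3$; mutually exclusive interactions are, per hub, the maximal
independent sets of size $\ge 2$ within the hub's neighborhood. Both are
computed with igraph but verified in the test suite against exhaustive
subset search on every 6-node graph. All outputs are sorted with
C-locale (byte-order) collation so reports are identical across locales.

```{r network}
fx <- make_network_fixture()
net <- as_association_network(fx$nodes, fx$edges)
find_ternary_complexes(net)
```

The **co-dynamics distance** z-scores each protein's median FRAP
half-time and mobile fraction across proteins (sample sd, $n-1$) and
takes Euclidean distances; it is invariant to the units of either axis.

# FRAP model

Traces are background-subtracted with an in-cell background ROI,
normalized so the mean of the nine frames before bleaching is 1 and the
first post-bleach frame is 0, and fitted to
$I(t) = M(1 - e^{-\tau t})$ with $M \in [0, 1.5]$ (values slightly above
1 absorb normalization noise), $\tau_{1/2} = -\ln(0.5)/\tau$. $R^2$ is
computed about the mean of the normalized post-bleach points — a choice
we document because $R^2$ is not uniquely defined for nonlinear fits —
and fits with $R^2 \le 0.7$ are excluded. The acquisition protocol
implies ten pre-bleach frames of which nine enter the pre-bleach mean;
both counts are arguments.

# The synthetic world: what it emulates and what it does not

`simulate_ffs_traces()` propagates three species (free red, free green,
complex) by Brownian steps ($\sigma = \sqrt{2D\Delta t}$ per axis) in a
periodic box of edge $\ge 8 z_0$, deposits expected photon counts through
3D-Gaussian detection profiles, adds green→red bleedthrough and dark
counts to the expected rate, and draws Poisson counts per bin. A
dark-red fraction is assigned per particle at creation (maturation is
slow compared with a trace). All randomness flows from R's RNG via one
seed: the same seed reproduces traces bit-for-bit.

It does **not** model triplet blinking, photobleaching during
acquisition, detector afterpulsing or dead time, aggregates, or membrane
geometry — so a green physics test establishes correctness of the
correlation/amplitude/Ka arithmetic for ideal diffusing emitters, not
robustness to photophysics.

**Desk scaling.** The instrument world (axial ratio $s = 10$, dye
$D \approx 4\times10^{-6}$ cm²/s, 2 μs bins, 10×10 s traces) would need
tens of thousands of particles (the periodic box must stay $\ge 8z_0$)
and $5\times10^6$ bins per trace. Tests instead run a scaled world —
$\omega_0 = 0.2$ μm, $s = 1.5$, $D = 2\times10^{-8}$ cm²/s
($\tau_D = 5$ ms), 0.2 ms bins, 2.5--10 s traces, $N \approx 5$ — chosen
once so that one replicate costs seconds while keeping
$\tau_D/\Delta t = 25$ and thousands of transits per trace. Score tests
use low molecular brightness (1000 counts/s) because the defining regime
of the association score is shot-noise-dominated amplitude windows, as
in cells; amplitude-recovery tests use bright emitters (50 000 counts/s)
where curve shape matters. Lag windows scale with the grid
(amplitude $[0.2, 2]$ ms $< \tau_D$; offset $[50, 450]$ ms
$\gg \tau_D$).

Replicate-median recoveries in this world (test suite): $\tau_D$ within
a few percent (15% bound), $N$ within ~5%, tandem cross/auto amplitude
ratio within ~1%, median $K_a$ of a known mixture within ~10% (25%
bound), independent-species score median within 0.5 of zero.

# Numerical choices

* Fits use `nls(algorithm = "port")` with bounds and
  `scaleOffset = 1`, so noiseless round-trips (zero residual) converge
  cleanly to $10^{-6}$ relative error.
* Starting values are scale-free: amplitude from the first lag,
  $\tau_D$ from the half-amplitude lag, FRAP plateau from the last 10%
  of points, rate from the time to half-plateau.
* Medians of even counts are the mean of the central pair; no
  interpolation onto canonical grids.
* The exact signed-rank and rank-sum null distributions double the
  mid-ranks to work on integers; convolution is over the *realized*
  ranks, so ties need no separate correction.
* The box constraint (edge $\ge 8z_0$) keeps periodic self-interaction
  of the detection profile below $e^{-32}$ of the peak.

# Known limitations

* The simulator's per-bin position update means lags shorter than one
  bin are unavailable and the first lag carries slight motion blur;
  recovery tests therefore keep $\Delta t \le \tau_D/25$.
* The cross-correlation of truly independent species has residual
  finite-sample noise correlated across neighboring lags; single-cell
  scores scatter with MAD-normalized magnitudes of 1--2, and only cohort
  medians are interpreted.
* No two-component or anomalous-diffusion models; no FRET corrections;
  vendor raw formats are out of scope (CSV in, CSV/TSV/JSON/GraphML
  out).
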