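---
title: "Processing and quantifying cardiac 1H-MR spectra with cmrs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing and quantifying cardiac 1H-MR spectra with cmrs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmrs)
```

## The measurement problem

Single-voxel proton MR spectroscopy of the heart aims to quantify
intramyocardial creatine (Cr, N-methyl resonance at 3.027 ppm) and
triglycerides (TG, six resonances between 0.9 and 2.8 ppm) relative to
tissue water. The raw observation is a series of complex free induction
decays (FIDs), one per heartbeat-triggered excitation ("shot"), acquired on
a multi-element receive coil. Between excitation and a quantitative
concentration stand a chain of signal-processing and modeling steps, each of
which this package implements as a tested, composable function:

1. **Coil combination** (`svd_combine()`): each channel is phased
   (zeroth + first order, `autophase()`) and the channels are combined with
   the conjugate of the dominant left singular vector of the
   channels-by-data matrix. This is the matched filter; for equal-gain
   channels with independent noise the SNR gain approaches the square root
   of the channel count.
2. **Frequency realignment** (`realign_shots()`): shot-to-shot frequency
   drift is estimated by cross-correlating magnitude spectra against the
   median spectrum over the 0–6 ppm window and removed by a time-domain
   linear phase ramp.
3. **Retrospective gating** of free-breathing series
   (`gate_and_average()`), described below.
4. **Time-domain linear-combination fitting** (`fit_spectrum()`), described
   below, with Cramér–Rao lower bounds (CRLBs) per amplitude.
5. **Relaxation-corrected, water-referenced quantification**
   (`concentrations()`).

A synthetic-data module (`sim_scenario()`, `simulate_series()`) generates
multi-channel series with known ground truth so that every stage has a
parameter-recovery oracle; no scanner data is needed to validate the chain.

## The signal model

Each resonance is rendered in the time domain at unit amplitude,

* Lorentzian lines (Cr, trimethyl-amide, water) as
  $b(t) = e^{-\pi\,\mathrm{LW}\,t}\, e^{i 2\pi \Delta f t}$,
* Gaussian lines (the six TG components) as
  $b(t) = e^{-(\pi\,\mathrm{LW}\,t)^2 / (4 \ln 2)}\, e^{i 2\pi \Delta f t}$,

with $\Delta f = (\delta - \delta_\mathrm{ref})\, f_0$ the offset in Hz from
the carrier ($\delta_\mathrm{ref}$ = 4.7 ppm, water). In both cases LW is
exactly the spectral full width at half maximum of the real (absorption)
part, which is what `fwhm()` measures. The fitted model for the averaged
FID $y(t)$ is

$$
\hat y(t) \;=\; e^{i\varphi}\, e^{-\pi d t}
\sum_m a_m \, e^{i 2\pi \delta_{g(m)} t}\, b_m(t),
$$

with per-component amplitudes $a_m \ge 0$, one frequency shift
$\delta_g$ per metabolite group (Cr, TMA, FA, UFA, water; bounded to
±0.1 ppm), a single shared extra Lorentzian damping $d \in [0, 50]$ Hz and
a global zeroth-order phase $\varphi$. The least-squares problem over the
stacked real and imaginary parts is solved by bounded Levenberg–Marquardt
(`minpack.lm`) with an analytic Jacobian. CRLBs come from the Fisher
information $F = \sigma^{-2}\,\mathrm{Re}(J^{H} J)$ at the optimum, with
$\sigma$ estimated from the tail of the raw, unfiltered FID
(`estimate_noise_sd()`).

Modeling choices worth knowing:

* **Group-tied shifts** (default) rather than per-component shifts reduce
  collinearity among the overlapping TG Gaussians; `tie_shifts =
  "component"` is available.
* **Base linewidths** default to 6 Hz (Lorentzian singlets) and 25 Hz (TG
  Gaussians). These are modeling assumptions — physiological values are
  field-, shim- and subject-dependent — and are configurable in
  `build_basis()`.
* **Non-negative amplitudes** are a bound constraint; they stabilize
  low-SNR fits at the cost of a small positive bias exactly at zero
  amplitude.
* A **water component is always included** when fitting water-suppressed
  data inside `run_pipeline()`: suppression leaves a residual water line
  that is typically an order of magnitude larger than the metabolites, and
  leaving it unmodeled biases every amplitude. The default `build_basis()`
  set remains the eight metabolite components.
* Singlet approximation: Cr N-methyl and TMA are modeled as single
  Lorentzians; J-coupling evolution is out of scope, consistent with
  fitting only these resonances.

## Retrospective gating of free-breathing series

Breathing modulates the shot-to-shot phase, frequency and linewidth of the
spectrum. `characterize_shots()` measures all three (plus amplitude) on the
residual water peak of every shot; gating then proceeds in two stages:

1. **Adaptive linewidth threshold** (`auto_lw_threshold()`): starting from
   the threshold admitting the best quartile of shots by water linewidth,
   the threshold grows in 1 Hz steps; at each step the admitted shots are
   averaged and the fatty-acid SNR at 1.3 ppm is evaluated, and the step is
   kept only if the SNR did not decrease (ties broken toward the smaller
   resulting FA linewidth). The search stops at the first rejected step and
   the full (threshold, SNR, LW) trace is returned so alternatives can be
   audited.
2. **Phase gate** (`phase_gate()`): shots whose water phase deviates from
   the *circular* mean by more than $k \times$ SD (default $k = 0.6$) are
   rejected. The SD is estimated over the whole scan, not only the stage-1
   survivors (configurable). Under pure Gaussian phase corruption the
   rejected fraction is $2(1 - \Phi(k)) \approx 54.9\%$ at $k = 0.6$, which
   the test suite verifies on $10^4$ simulated shots.

Two deliberate design points:

* The stage-1 SNR score averages admitted shots after **frequency
  correction only**. The threshold is chosen before any phase handling has
  happened, and shot-by-shot phase correction is not part of the original
  procedure; if the score phased each shot first, phase-corrupted broad
  shots could never lower it and the threshold would never exclude them.
* After both stages, the accepted shots **are** phase- and
  frequency-corrected with their own per-shot estimates before averaging.
  This uses information the characterization stage already produced and
  makes the final average coherent; the bookkeeping identity
  `n_used + n_rejected_lw + n_rejected_phase = n_shots` holds on every run.

The processing order is phasing → coil combination → realignment → gating →
averaging → zero-filling → apodization → fitting. Realignment must precede
averaging to be meaningful, so it cannot literally follow the
zero-fill-then-realign listing order sometimes quoted for this chain;
zero-filling and apodization are display/fitting conditioning steps applied
to the averaged FID.

## Quantification

Corrected signals follow
$S^*_N = S_N \cdot \left[1 - e^{-\mathrm{TR}/T_{1,N}}\right]^{-1}
\cdot e^{\mathrm{TE}/T_{2,N}}$, with an additional
$e^{\mathrm{TM}/T_{1,N}}$ for STEAM acquisitions
(`relaxation_correct()`, `steam_tm_correct()`). Default in vivo relaxation
times (s): lipids $T_1 = 0.35$, $T_2 = 0.089$; water $T_1 = 1.20$,
$T_2 = 0.044$; creatine $T_1 = 1.00$, $T_2 = 0.135$. Unsaturated
fatty-acid components share the lipid constants (an assumption — no
separate UFA constants are established). Phantom mode skips the $T_1$ term
($T_1 \ll \mathrm{TR}$ there) and uses the phantom $T_2$ values (57.37 ms
fat, 249.5 ms water).

Concentrations are referenced to the non-suppressed water scan:

$$[\mathrm{Cr}] = \tfrac{2}{3}\,[W]\,\frac{S^*_\mathrm{Cr}}{S^*_W},\qquad
[\mathrm{FA}] = \tfrac{2}{28}\,[W]\,\frac{S^*_\mathrm{FA(1.3)}}{S^*_W},\qquad
[\mathrm{TG}] = \tfrac{2}{93}\,[W]\,\frac{S^*_\mathrm{TG}}{S^*_W},$$

with $[W] = 55.5 \times 0.727 \times 1000 = 40348.5$ µmol/g from the
assumed tissue water content. Three caveats are intentional:

* The FA quantity (proton factor 2/28) is the 1.3 ppm methylene component
  alone; the TG quantity (2/93) sums all six TG components. The two are
  deliberately distinct outputs even though both derive from lipid signal.
* The $[W]$ formula is implemented verbatim; its unit bookkeeping
  (mol/L × weight fraction × 1000 read as µmol/g) is dimensionally loose
  but is the established convention for this reference value.
* STEAM's intrinsic factor-2 stimulated-echo signal loss is *not*
  corrected by default (only TM is), mirroring standard practice; set
  `steam_halving_correction = TRUE` in `concentrations()` to compensate it.

The chemical-shift displacement error calculator (`csde()`) returns
$\Delta f / \mathrm{BW}$; with the water–methylene separation of 3.4 ppm at
123.2 MHz ($\Delta f \approx 418.9$ Hz) and pulse bandwidths of 1150, 1700
and 2200 Hz it gives 36%, 25% and 19% of the voxel dimension — the 3.4 ppm
separation (not 3.5) is what reproduces these figures. The fat-water
phantom calculator (`phantom_expected_ratio()`) evaluates
$100\, r_\mathrm{in}^2 \pi / (A_\mathrm{box} - r_\mathrm{out}^2 \pi)$,
which is 102.1% for the 7.5/8.5 mm tube in a 20 × 20 mm voxel
cross-section.

## The synthetic-data generator

`simulate_series()` renders each shot as the amplitude-weighted sum of the
component FIDs, applies per-shot Gaussian draws of phase, frequency offset
and additive Lorentzian linewidth (the "breathing" model), multiplies by
complex per-channel coil gains and adds white complex noise. The presets
(`preset_scenario()`) define the standard study conditions:

* breath-hold: 8 averages, phase SD 0.1 rad, frequency SD 1 Hz, linewidth
  jitter SD 0.5 Hz;
* free-breathing: 100 averages, phase SD 0.5 rad, frequency SD 3 Hz,
  linewidth jitter SD 3 Hz;
* default amplitudes placing the raw ratios near Cr/W ≈ 0.03% and
  TG/W ≈ 0.7% of the (unit) water amplitude — in-vivo-like orders of
  magnitude, stated as defaults rather than tissue truths;
* residual water at 5% of the water amplitude in suppressed scans (the
  gating stage tracks this line, so it is always present).

No published distribution exists for breathing-induced shot corruption;
independent Gaussians are the minimal choice and make the phase-gate
rejection fraction analytically checkable. What the generator does *not*
emulate: cardiac-motion voxel displacement, B0 drift, eddy currents,
J-coupling multiplets, non-flat pulse profiles, and correlated
(physiological) noise. Passing recovery tests on these simulations
therefore validates the estimator chain under its own model assumptions;
they do not certify performance against every in vivo artifact.

## Numerical conventions and degenerate inputs

* ppm axis: DFT bin at signed frequency $f$ maps to
  $\delta_\mathrm{ref} + f/f_0$; axes are reported in descending ppm.
* `autophase()` samples the spectral phase at local magnitude maxima above
  20% of the global maximum (with parabolic sub-bin refinement) rather than
  at every masked point: across a single line the dispersive lineshape
  phase swings antisymmetrically and would otherwise bias the first-order
  fit. With fewer than two peaks the first-order term is left at zero.
* `fwhm()` interpolates the half-maximum crossings linearly and errors on
  truncated peaks; `snr()` guards division by a numerically zero noise SD
  and returns `Inf` with a `zero_noise` attribute.
* Exclusion thresholds (water linewidth > 35 Hz, peak SNR < 5,
  `qc_filter()`) use strict inequalities, so values exactly at a threshold
  pass.
* The phase gate with zero phase variance rejects nothing; an empty
  post-gating shot set raises an explicit error rather than returning an
  empty average.
* Fits never fail silently: non-convergence is returned as
  `converged = FALSE`, and a numerically singular Fisher information is
  reported via the `ill_conditioned` flag (e.g. duplicated basis
  components).
* The on-disk container stores complex data as paired little-endian
  float64 arrays plus a JSON metadata header, making round trips bit-exact
  and the file readable from any language without a complex-number dialect.

## Problem sizes used in validation

The shipped test-suite simulations use: full 2048-point FIDs for single-fit
checks; 100-seed Monte Carlo for amplitude-bias calibration at spectral SNR
≈ 40; 500-seed Monte Carlo (512-point, single-component fits) for the
CRLB-versus-SD comparison; 200 draws for the coil-combination SNR-gain and
SNR-estimator calibrations; $10^4$ shots for the phase-gate tail
probability; and one 100-shot free-breathing plus one 8-shot breath-hold
synthetic subject for the end-to-end concentration recovery. These sizes
were chosen so Monte-Carlo error is comfortably below each assertion's
tolerance.

## Known limitations

* No baseline or macromolecule model: simulations contain none, and real
  short-TE spectra with macromolecular baselines would need an extended
  basis.
* No eddy-current correction or HLSVD water removal; residual water is
  *fitted*, not removed.
* First-order phase is estimated and applied during preprocessing, not
  refit during the linear-combination fit (only a global zeroth-order
  phase is a fit parameter).
* The ICC is the two-way mixed-effects, absolute-agreement, single
  measurement form ICC(A,1); other forms can differ noticeably for small
  cohorts and values are reported unclipped.
* Vendor raw formats are out of scope; the NIfTI-MRS mapping is a metadata
  name translation, not a file reader.
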