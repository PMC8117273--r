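# cmrs — processing and quantification of cardiac ¹H-MR spectroscopy

Single-voxel proton MR spectroscopy of the interventricular septum measures
myocardial creatine (Cr, 3.027 ppm) and triglycerides (TG, six resonances
at 0.9–2.8 ppm) relative to tissue water — biomarkers of cardiac energy and
lipid metabolism. Getting from heartbeat-triggered, multi-channel raw FIDs
to a concentration in µmol/g requires a chain of steps that this package
implements as tested R functions, for spectroscopists and methods
developers who want an auditable, scriptable pipeline:

* **Synthetic data with ground truth** — `sim_scenario()`,
  `simulate_series()`, `preset_scenario()`: multi-channel FID series with
  per-shot breathing corruption (Gaussian phase / frequency / linewidth
  draws), complex coil gains and white noise, plus the fat-water phantom
  scenario (`simulate_phantom_series()`).
* **Preprocessing** — automatic 0th/1st-order phasing (`autophase()`), SVD
  coil combination (`svd_combine()`), per-shot frequency realignment
  (`realign_shots()`), zero-filling and 10 Hz apodization, FWHM/SNR metrics
  and quality-control exclusions (water LW > 35 Hz, SNR < 5).
* **Retrospective gating** of free-breathing series — per-shot residual
  water characterization, an adaptive linewidth threshold that grows while
  the fatty-acid SNR does not decrease, and the 0.6 × SD phase-deviation
  gate (`gate_and_average()`), with complete rejection bookkeeping.
* **Time-domain linear-combination fitting** — the averaged FID is modeled
  as

  &nbsp;&nbsp;&nbsp;&nbsp;ŷ(t) = e<sup>iφ</sup> e<sup>−πdt</sup> Σ<sub>m</sub> a<sub>m</sub> e<sup>i2πδ<sub>g(m)</sub>t</sup> b<sub>m</sub>(t)

  over non-negative amplitudes, group-tied frequency shifts, a shared
  Lorentzian damping and a global phase, solved by bounded
  Levenberg–Marquardt with an analytic Jacobian; Cramér–Rao lower bounds
  per amplitude from the Fisher information (`fit_spectrum()`, `crlb()`).
* **Quantification** — relaxation corrections
  S\* = S · [1 − e^(−TR/T1)]⁻¹ · e^(TE/T2) (plus e^(TM/T1) for STEAM),
  water referencing [Cr] = 2/3 · [W] · S\*<sub>Cr</sub>/S\*<sub>W</sub>,
  [FA] = 2/28 · [W] · S\*<sub>FA1.3</sub>/S\*<sub>W</sub>,
  [TG] = 2/93 · [W] · S\*<sub>TG</sub>/S\*<sub>W</sub> with
  [W] = 55.5 × 0.727 × 1000; the chemical-shift-displacement calculator
  CSDE = Δf/BW and the phantom geometry ratio
  100 · r<sub>in</sub>²π / (A<sub>box</sub> − r<sub>out</sub>²π); and
  mono-exponential T2 estimation from multi-TE spectra (`estimate_t2()`).
* **Repeatability statistics** — Bland–Altman bias and 1.96 SD limits of
  agreement, test–retest ICC(A,1) from two-way ANOVA mean squares, and
  linear regression with Pearson r (`repeatability_report()`).

## Worked example

Simulate a free-breathing acquisition (100 shots, 4 channels, breathing
corruption) plus its non-suppressed water companion, run the full pipeline,
and compare against the generator's ground truth:

```r
library(cmrs)

sim  <- simulate_series(preset_scenario("fb", seed = 11))
simw <- simulate_series(preset_scenario("water", seed = 12))

res <- run_pipeline(default_config(mode = "fb"), series = sim$series,
                    water_series = simw$series)
res
#> <pipeline_result>
#> <gating_result> used 19 | rejected 55 (linewidth) + 26 (phase) | LW threshold 11.6 Hz
#> <concentration_report> PRESS sequence, [W] = 40348.5
#>   quantity signal_raw signal_corrected ratio_to_water_pct concentration_umol_g
#> 1       Cr  0.0005209        0.0009325            0.02017                5.427
#> 2       FA  0.0032120        0.0043940            0.09506                2.740
#> 3       TG  0.0076940        0.0105300            0.22770                1.976

round(true_concentrations(sim$truth$amplitudes, sim$series$acq), 2)
#>   Cr   FA   TG
#> 5.36 2.75 1.98
```

Reading the output: of the 100 free-breathing shots, 55 were rejected by
the adaptive water-linewidth threshold (11.6 Hz) and 26 by the 0.6 × SD
phase gate; the remaining 19 were phase/frequency-corrected and averaged.
The fitted, relaxation-corrected ratios give creatine at 0.020 % of water
(5.43 µmol/g), the 1.3 ppm fatty-acid peak at 2.74 µmol/g, and total
triglycerides at 1.98 µmol/g — within a few percent of the concentrations
implied by the simulation's true amplitudes.

The analytic calculators:

```r
round(100 * csde_ppm(4.7, 1.3, 123.2, c(PRESS = 1150, sLASER = 1700, STEAM = 2200)))
#>  PRESS sLASER  STEAM
#>     36     25     19
round(phantom_expected_ratio(phantom_geometry()), 1)
#> [1] 102.1
```

A command-line front-end with `simulate / preprocess / gate / fit /
quantify / stats / run` subcommands is installed at
`system.file("exec", "cmrs", package = "cmrs")`.

## On-disk container

`write_series()` / `read_series()` use a single-file layout: the magic
bytes `CMRSFID1`, a little-endian int32 header length, a JSON header (all
acquisition metadata, shot index, array dims), then the complex cube as two
little-endian float64 arrays (real part, imaginary part, column-major).
Round trips are bit-exact. `nifti_mrs_metadata()` maps the metadata to and
from NIfTI-MRS-style key names.

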