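#' Default resonance table for the cardiac 1H spectrum
#'
#' Creatine N-methyl (3.027 ppm) and trimethyl-amide (3.183 ppm) singlets
#' modeled as Lorentzians, triglycerides as six Gaussian components: fatty
#' acids (FA) at 0.9, 1.3 and 1.6 ppm and unsaturated fatty acids (UFA) at
#' 2.1, 2.3 and 2.8 ppm, plus water at 4.7 ppm.
#'
#' @return data.frame with columns `name`, `ppm`, `lineshape`, `lw_hz`,
#'   `group`.
#' @export
resonance_table <- function() {
  data.frame(
    name = c("water", "Cr", "TMA",
             "TG09", "TG13", "TG16", "TG21", "TG23", "TG28"),
    ppm = c(4.7, 3.027, 3.183, 0.9, 1.3, 1.6, 2.1, 2.3, 2.8),
    lineshape = c("lorentzian", "lorentzian", "lorentzian",
                  rep("gaussian", 6)),
    lw_hz = c(12, 6, 6, rep(25, 6)),
    group = c("water", "Cr", "TMA", "FA", "FA", "FA", "UFA", "UFA", "UFA"),
    stringsAsFactors = FALSE)
}

#' Simulation scenario for synthetic FID series
#'
#' Describes a ground-truth spectrum plus the acquisition corruption model:
#' complex coil sensitivities, white complex noise, and shot-to-shot
#' breathing-induced Gaussian fluctuations of phase, frequency and linewidth.
#'
#' Default amplitudes put the metabolites at in-vivo-like orders of magnitude
#' relative to water (Cr/W a few hundredths of a percent, TG/W under one
#' percent, raw ratios before relaxation correction); they are defaults, not
#' ground truths of any real tissue.
#'
#' @param amplitudes Named numeric vector of true component amplitudes
#'   (arbitrary units); names must exist in `components$name`.
#' @param components Resonance table (see [resonance_table()]); rows define
#'   center ppm, lineshape and intrinsic linewidth per component.
#' @param coil_sensitivities Complex vector, one gain per receive channel.
#' @param noise_sd Standard deviation of the real and imaginary parts of the
#'   additive white noise, per channel per time sample.
#' @param breathing List with `phase_sd_rad`, `freq_sd_hz`, `lw_jitter_hz`:
#'   SDs of the independent zero-mean Gaussian per-shot draws.
#' @param residual_water_amp Amplitude of the residual (incompletely
#'   suppressed) water line included whenever `acq$water_suppressed` is TRUE;
#'   the retrospective gating stage tracks this resonance.
#' @param seed RNG seed making the simulation reproducible.
#' @param acq [acq_params()] for the virtual scan.
#' @return Object of class `sim_scenario`.
#' @export
sim_scenario <- function(amplitudes = c(Cr = 3.2e-4, TMA = 2.0e-4,
                                        TG09 = 1.0e-3, TG13 = 2.0e-3,
                                        TG16 = 6e-4, TG21 = 4e-4,
                                        TG23 = 5e-4, TG28 = 3e-4),
                         components = resonance_table(),
                         coil_sensitivities = c(1 + 0i, 0.8i, -0.6 + 0.3i,
                                                0.5 - 0.5i),
                         noise_sd = 3e-4,
                         breathing = list(phase_sd_rad = 0, freq_sd_hz = 0,
                                          lw_jitter_hz = 0),
                         residual_water_amp = 0.05,
                         seed = 1L,
                         acq = acq_params(n_channels = length(coil_sensitivities))) {
  stopifnot(is.numeric(amplitudes), !is.null(names(amplitudes)))
  if (any(amplitudes < 0)) stop("amplitudes must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  br <- utils::modifyList(list(phase_sd_rad = 0, freq_sd_hz = 0,
                               lw_jitter_hz = 0), as.list(breathing))
  if (any(unlist(br) < 0)) stop("breathing scales must be >= 0", call. = FALSE)
  if (all(Mod(coil_sensitivities) == 0))
    stop("coil_sensitivities must not be all zero", call. = FALSE)
  unknown <- setdiff(names(amplitudes), components$name)
  if (length(unknown))
    stop("unknown component(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (residual_water_amp < 0)
    stop("residual_water_amp must be >= 0", call. = FALSE)
  if (length(coil_sensitivities) != acq$n_channels)
    stop("coil_sensitivities length must equal acq$n_channels", call. = FALSE)
  structure(list(amplitudes = amplitudes, components = components,
                 coil_sensitivities = as.complex(coil_sensitivities),
                 noise_sd = noise_sd, breathing = br,
                 residual_water_amp = residual_water_amp,
                 seed = as.integer(seed), acq = acq),
            class = "sim_scenario")
}

#' Simulate one unit-amplitude component FID
#'
#' A Lorentzian component decays as `exp(-pi * LW * t)` and a Gaussian one as
#' `exp(-(pi * LW * t)^2 / (4 log 2))`, both giving a spectral full width at
#' half maximum of `LW` Hz; the resonance offset enters as
#' `exp(1i * 2 * pi * df * t)` with `df = (ppm - reference_ppm) * f0_mhz`.
#' Every component FID equals 1 + 0i at t = 0.
#'
#' @param name Component name present in `scenario$components`.
#' @param scenario A [sim_scenario()].
#' @param extra_lw_hz Additional Lorentzian damping in Hz (used for per-shot
#'   linewidth jitter).
#' @param extra_freq_hz Additional frequency offset in Hz.
#' @return Complex FID vector of length `acq$n_points`.
#' @export
simulate_component_fid <- function(name, scenario, extra_lw_hz = 0,
                                   extra_freq_hz = 0) {
  comp <- scenario$components[scenario$components$name == name, ]
  if (nrow(comp) != 1)
    stop("unknown component name: ", name, call. = FALSE)
  acq <- scenario$acq
  t <- time_axis(acq)
  df <- ppm_to_hz(comp$ppm - acq$reference_ppm, acq$f0_mhz) + extra_freq_hz
  env <- if (comp$lineshape == "gaussian") {
    # the Lorentzian jitter term stays Lorentzian even on Gaussian lines
    exp(-(pi * comp$lw_hz * t)^2 / (4 * log(2)) - pi * extra_lw_hz * t)
  } else {
    exp(-pi * (comp$lw_hz + extra_lw_hz) * t)
  }
  env * exp(1i * 2 * pi * df * t)
}

# components actually rendered for a scenario (adds residual water when the
# scan is water-suppressed, full water otherwise if listed)
active_components <- function(scenario) {
  amps <- scenario$amplitudes
  if (scenario$acq$water_suppressed && scenario$residual_water_amp > 0 &&
      !("water" %in% names(amps)))
    amps <- c(water = scenario$residual_water_amp, amps)
  amps
}

#' Simulate a multi-shot, multi-channel FID series with ground truth
#'
#' Each shot is the amplitude-weighted sum of the component FIDs, perturbed
#' by its own Gaussian phase / frequency-offset / linewidth-jitter draws
#' (breathing model), multiplied per channel by the complex coil
#' sensitivities, plus i.i.d. complex white noise. Fully reproducible from
#' the scenario seed.
#'
#' @param scenario A [sim_scenario()].
#' @return List with elements `series` ([fid_series()]) and `truth`, a list
#'   carrying `per_shot` (data.frame: shot, phase_rad, freq_hz, lw_jitter_hz)
#'   and `amplitudes` (the true component amplitudes actually rendered,
#'   including residual water).
#' @export
simulate_series <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  acq <- scenario$acq
  amps <- active_components(scenario)
  withr_seed <- scenario$seed
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(withr_seed)
  br <- scenario$breathing
  per_shot <- data.frame(
    shot = seq_len(acq$n_shots),
    phase_rad = stats::rnorm(acq$n_shots, 0, br$phase_sd_rad),
    freq_hz = stats::rnorm(acq$n_shots, 0, br$freq_sd_hz),
    lw_jitter_hz = stats::rnorm(acq$n_shots, 0, br$lw_jitter_hz))
  t <- time_axis(acq)
  data <- array(0i, c(acq$n_shots, acq$n_channels, acq$n_points))
  for (s in seq_len(acq$n_shots)) {
    clean <- rep(0i, acq$n_points)
    for (nm in names(amps)) {
      clean <- clean + amps[[nm]] *
        simulate_component_fid(nm, scenario,
                               extra_lw_hz = per_shot$lw_jitter_hz[s],
                               extra_freq_hz = per_shot$freq_hz[s])
    }
    clean <- clean * exp(1i * per_shot$phase_rad[s])
    for (ch in seq_len(acq$n_channels)) {
      noise <- complex(real = stats::rnorm(acq$n_points, 0, scenario$noise_sd),
                       imaginary = stats::rnorm(acq$n_points, 0, scenario$noise_sd))
      data[s, ch, ] <- scenario$coil_sensitivities[ch] * clean + noise
    }
  }
  list(series = fid_series(data, acq),
       truth = list(per_shot = per_shot, amplitudes = amps))
}

#' Preset simulation scenarios
#'
#' The standard study conditions used by the examples and the validation
#' suite:
#'
#' * `"bh"` — breath-hold: 8 water-suppressed averages with mild residual
#'   motion (phase SD 0.1 rad, frequency SD 1 Hz, linewidth jitter SD
#'   0.5 Hz);
#' * `"fb"` — free-breathing: 100 water-suppressed averages with
#'   breathing-scale corruption (phase SD 0.5 rad, frequency SD 3 Hz,
#'   linewidth jitter SD 3 Hz);
#' * `"water"` — the non-suppressed companion scan (2 averages, water
#'   amplitude 1);
#' * `"phantom"` — the fat-water phantom scan (non-suppressed, no motion).
#'
#' All presets use a 4-channel virtual coil and a noise level giving
#' in-vivo-like metabolite SNR after averaging.
#'
#' @param type Scenario preset.
#' @param seed RNG seed.
#' @param n_shots Override of the preset shot count.
#' @param sequence,te_s,tr_s,tm_s Sequence settings forwarded to
#'   [acq_params()].
#' @param ... Further overrides forwarded to [sim_scenario()].
#' @return A [sim_scenario()].
#' @export
preset_scenario <- function(type = c("bh", "fb", "water", "phantom"),
                            seed = 1, n_shots = NULL,
                            sequence = "PRESS", te_s = 0.02396, tr_s = 1.1,
                            tm_s = 0, ...) {
  type <- match.arg(type)
  n_shots <- if (!is.null(n_shots)) n_shots else
    switch(type, bh = 8L, fb = 100L, water = 2L, phantom = 8L)
  coil <- c(1 + 0i, 0.8i, -0.6 + 0.3i, 0.5 - 0.5i)
  acq <- acq_params(sequence = sequence, te_s = te_s, tr_s = tr_s,
                    tm_s = tm_s, n_channels = length(coil),
                    n_shots = n_shots,
                    water_suppressed = type %in% c("bh", "fb"))
  args <- switch(type,
    bh = list(breathing = list(phase_sd_rad = 0.1, freq_sd_hz = 1,
                               lw_jitter_hz = 0.5)),
    fb = list(breathing = list(phase_sd_rad = 0.5, freq_sd_hz = 3,
                               lw_jitter_hz = 3)),
    water = list(amplitudes = c(water = 1), residual_water_amp = 0),
    phantom = list(amplitudes = c(water = 1), residual_water_amp = 0,
                   noise_sd = 1e-4))
  do.call(sim_scenario,
          utils::modifyList(c(args, list(coil_sensitivities = coil,
                                         seed = seed, acq = acq)),
                            list(...)))
}

#' Geometry of the fat-water phantom
#'
#' A fat-filled cylindrical tube (inner radius `r_inner_mm`, outer tube
#' radius `r_outer_mm`) standing in water, enclosed by a voxel whose in-plane
#' cross-section is `cross_section_mm[1] x cross_section_mm[2]`.
#'
#' @param r_inner_mm Inner (fat) radius in mm.
#' @param r_outer_mm Outer tube radius in mm.
#' @param cross_section_mm Length-2 in-plane voxel extents in mm.
#' @return Object of class `phantom_geometry`.
#' @export
phantom_geometry <- function(r_inner_mm = 7.5, r_outer_mm = 8.5,
                             cross_section_mm = c(20, 20)) {
  if (r_inner_mm < 0 || r_outer_mm < r_inner_mm)
    stop("need 0 <= r_inner_mm <= r_outer_mm", call. = FALSE)
  if (length(cross_section_mm) != 2 || any(cross_section_mm <= 0))
    stop("cross_section_mm must be two positive extents", call. = FALSE)
  if (pi * r_outer_mm^2 >= prod(cross_section_mm))
    stop("tube does not fit inside the voxel cross-section", call. = FALSE)
  structure(list(r_inner_mm = r_inner_mm, r_outer_mm = r_outer_mm,
                 cross_section_mm = as.numeric(cross_section_mm)),
            class = "phantom_geometry")
}

#' Simulate the fat-water phantom acquisition
#'
#' Two-component series (water at 4.7 ppm, fatty-acid methylene at 1.3 ppm)
#' whose true amplitude ratio equals [phantom_expected_ratio()] for the given
#' geometry, optionally reduced by a chemical-shift-displacement overlap
#' factor. No breathing perturbation; water suppression off.
#'
#' @param geometry A [phantom_geometry()].
#' @param scenario A [sim_scenario()]; its amplitudes are ignored except for
#'   an optional `water` entry fixing the water amplitude (default 1).
#' @param overlap_factor Multiplies the fat amplitude, emulating partial
#'   voxel overlap of the displaced fat volume (1 = no displacement loss).
#' @return As [simulate_series()].
#' @export
simulate_phantom_series <- function(geometry, scenario, overlap_factor = 1) {
  stopifnot(inherits(geometry, "phantom_geometry"))
  water_amp <- if ("water" %in% names(scenario$amplitudes))
    scenario$amplitudes[["water"]] else 1
  ratio <- phantom_expected_ratio(geometry) / 100
  acq <- scenario$acq
  acq$water_suppressed <- FALSE
  sc <- sim_scenario(
    amplitudes = c(water = water_amp,
                   TG13 = water_amp * ratio * overlap_factor),
    components = scenario$components,
    coil_sensitivities = scenario$coil_sensitivities,
    noise_sd = scenario$noise_sd,
    breathing = list(phase_sd_rad = 0, freq_sd_hz = 0, lw_jitter_hz = 0),
    residual_water_amp = 0, seed = scenario$seed, acq = acq)
  simulate_series(sc)
}
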