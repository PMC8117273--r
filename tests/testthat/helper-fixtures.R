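# shared fixture builders for the suite (everything generated in code)

single_acq <- function(n_points = 1024, n_shots = 1, n_channels = 1, ...) {
  acq_params(n_points = n_points, n_shots = n_shots,
             n_channels = n_channels, ...)
}

# bare Lorentzian FID at a frequency offset from the carrier
lorentzian_fid <- function(acq, lw_hz = 10, offset_hz = 0, amp = 1,
                           phase = 0) {
  t <- time_axis_of(acq)
  amp * exp(-pi * lw_hz * t) * exp(1i * (2 * pi * offset_hz * t + phase))
}

# minimal single-component scenario on one channel
one_comp_scenario <- function(acq, name = "Cr", amp = 1, noise_sd = 0,
                              seed = 1, ...) {
  sim_scenario(amplitudes = stats::setNames(amp, name),
               coil_sensitivities = 1 + 0i, noise_sd = noise_sd,
               residual_water_amp = 0, seed = seed, acq = acq, ...)
}

# FB series where a labeled subset of shots carries heavy linewidth and
# phase corruption (the gating test scenario)
corrupted_series <- function(n_shots = 50, frac_corrupt = 0.2,
                             extra_lw_hz = 30, phase_mult = 5, seed = 4) {
  acq <- acq_params(n_channels = 1, n_shots = n_shots)
  sc <- sim_scenario(coil_sensitivities = 1 + 0i, acq = acq, seed = seed,
                     breathing = list(phase_sd_rad = 0.1, freq_sd_hz = 1,
                                      lw_jitter_hz = 0.5))
  sim <- simulate_series(sc)
  set.seed(seed + 1000)
  corrupt <- sample(n_shots, round(frac_corrupt * n_shots))
  t <- time_axis_of(acq)
  dat <- sim$series$data
  for (s in corrupt)
    dat[s, 1, ] <- dat[s, 1, ] * exp(-pi * extra_lw_hz * t) *
      exp(1i * stats::rnorm(1, 0, phase_mult * 0.1))
  list(series = fid_series(dat, acq), corrupt = sort(corrupt),
       clean = setdiff(seq_len(n_shots), corrupt), truth = sim$truth)
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(max(abs(object / expected - 1)), tol)
}
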