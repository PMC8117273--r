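test_that("autophase recovers imposed zeroth- and first-order phase", {
  acq <- single_acq(n_points = 2048)
  t <- time_axis_of(acq)
  fid <- lorentzian_fid(acq, 8, -300) + lorentzian_fid(acq, 8, 200)
  # zeroth order (single on-grid line, so no first-order term to confound)
  on_grid <- 40 / (acq$n_points * acq$dwell_s)
  ph <- autophase(lorentzian_fid(acq, 8, on_grid) * exp(1i * 0.7), acq)
  expect_equal(ph$phi0_rad, 0.7, tolerance = 1e-3)
  # fixed point: already-phased single Lorentzian
  ph0 <- autophase(lorentzian_fid(acq, 10), acq)
  expect_lt(abs(ph0$phi0_rad), 1e-6)
  expect_lt(abs(ph0$phi1_rad_per_hz), 1e-8)
  # one-dwell delay is a linear phase of 2*pi*dwell per Hz
  delayed <- c(0 + 0i, fid[-length(fid)])
  ph1 <- autophase(delayed, acq)
  expect_equal(abs(ph1$phi1_rad_per_hz), 2 * pi * acq$dwell_s,
               tolerance = 0.05)
  # idempotence: a second pass applies (~0, ~0)
  ph2 <- autophase(ph1$fid, acq)
  expect_lt(abs(ph2$phi0_rad), 1e-6)
  expect_lt(abs(ph2$phi1_rad_per_hz), 1e-3 * abs(ph1$phi1_rad_per_hz) + 1e-12)
  expect_error(autophase(rep(0i, 64), single_acq(n_points = 64)), "all-zero")
})

test_that("svd combination is identity-like for degenerate inputs", {
  acq <- single_acq(n_points = 256, n_shots = 2)
  sc <- one_comp_scenario(acq, noise_sd = 0.01, seed = 2)
  ser <- simulate_series(sc)$series
  comb <- svd_combine(ser)
  expect_equal(comb$acq$n_channels, 1L)
  # single channel: output proportional to input up to a global phase
  ratio <- comb$data[1, 1, ] / ser$data[1, 1, ]
  expect_lt(sd(Arg(ratio[Mod(ser$data[1, 1, ]) > 0.01])), 1e-6)

  # gains (1, 0): combined equals channel 1 up to phase
  acq2 <- single_acq(n_points = 256, n_shots = 1, n_channels = 2)
  sc2 <- sim_scenario(amplitudes = c(Cr = 1),
                      coil_sensitivities = c(1 + 0i, 0i), noise_sd = 0,
                      residual_water_amp = 0, acq = acq2)
  ser2 <- simulate_series(sc2)$series
  comb2 <- svd_combine(ser2)
  z <- comb2$data[1, 1, ]; x <- ser2$data[1, 1, ]
  phase <- Arg(sum(Conj(x) * z))
  expect_lt(max(Mod(z - exp(1i * phase) * x)), 1e-10 * max(Mod(x)))
})

test_that("svd combination gains sqrt(2) SNR for two equal channels", {
  snr_pair <- vapply(1:200, function(sd) {
    acq <- single_acq(n_points = 256, n_shots = 1, n_channels = 2)
    sc <- sim_scenario(amplitudes = c(Cr = 1),
                       coil_sensitivities = c(1 + 0i, 1 + 0i),
                       noise_sd = 0.04, residual_water_amp = 0,
                       seed = 5000 + sd, acq = acq)
    ser <- simulate_series(sc)$series
    single <- to_spectrum(ser$data[1, 1, ], acq)
    comb <- to_spectrum(svd_combine(ser)$data[1, 1, ], acq)
    c(as.numeric(snr(single, 3.027)), as.numeric(snr(comb, 3.027)))
  }, numeric(2))
  gain <- mean(snr_pair[2, ]) / mean(snr_pair[1, ])
  expect_equal(gain, sqrt(2), tolerance = 0.1)
})

test_that("svd combination is at least as good as the best single channel", {
  set.seed(77)
  for (rep in 1:20) {
    acq <- single_acq(n_points = 256, n_shots = 1, n_channels = 3)
    gains <- complex(real = rnorm(3), imaginary = rnorm(3))
    sc <- sim_scenario(amplitudes = c(Cr = 1), coil_sensitivities = gains,
                       noise_sd = 0.03, residual_water_amp = 0,
                       seed = 900 + rep, acq = acq)
    ser <- simulate_series(sc)$series
    best_single <- max(vapply(1:3, function(ch)
      as.numeric(snr(to_spectrum(autophase(ser$data[1, ch, ], acq)$fid, acq),
                     3.027)), numeric(1)))
    comb_snr <- as.numeric(snr(to_spectrum(svd_combine(ser)$data[1, 1, ], acq),
                               3.027))
    # one Monte-Carlo SD of slack on a per-draw basis
    expect_gt(comb_snr, 0.75 * best_single)
  }
})

test_that("zero-filling preserves the original frequency grid exactly", {
  set.seed(3)
  x <- complex(real = rnorm(512), imaginary = rnorm(512))
  expect_identical(zero_fill(x, 1), as.complex(x))
  zf <- zero_fill(x, 2)
  expect_length(zf, 1024)
  expect_lt(max(Mod(fft(zf)[seq(1, 1024, by = 2)] - fft(x))),
            1e-12 * max(Mod(fft(x))))
  expect_true(all(zero_fill(rep(0i, 16), 3) == 0i))
  expect_error(zero_fill(x, 0), "factor")
})

test_that("apodization adds its line broadening to a Lorentzian width", {
  acq <- single_acq(n_points = 2048)
  fid <- lorentzian_fid(acq, 10)
  expect_equal(apodize(fid, acq, 0), fid)
  expect_equal(apodize(fid, acq, 10)[1], fid[1])  # t = 0 sample unchanged
  sp <- to_spectrum(zero_fill(apodize(fid, acq, 10), 4), acq)
  expect_equal(fwhm(sp, acq$reference_ppm, 0.5), 20, tolerance = 2 * sp$df_hz)
  expect_error(apodize(fid, acq, -1), "lb_hz")
})

test_that("realignment recovers imposed shifts and tightens peak positions", {
  acq <- single_acq(n_points = 2048, n_shots = 3)
  t <- time_axis_of(acq)
  base <- lorentzian_fid(acq, 10) +
    0.5 * lorentzian_fid(acq, 10, ppm_to_hz(1.3 - 4.7, acq$f0_mhz))
  imposed <- c(4, -4, 0)
  set.seed(8)
  dat <- array(0i, c(3, 1, 2048))
  for (s in 1:3)
    dat[s, 1, ] <- base * exp(1i * 2 * pi * imposed[s] * t) +
      complex(real = rnorm(2048, 0, 1e-4), imaginary = rnorm(2048, 0, 1e-4))
  ra <- realign_shots(fid_series(dat, acq))
  expect_equal(ra$shifts_hz, imposed, tolerance = 0.05)  # within 0.2 Hz
  peaks_after <- vapply(1:3, function(s) {
    sp <- to_spectrum(zero_fill(ra$series$data[s, 1, ], 4), acq)
    sp$ppm_axis[which.max(Mod(sp$values))]
  }, numeric(1))
  expect_lt(diff(range(peaks_after)) * acq$f0_mhz, 4 * 1 / (4 * 2048 * acq$dwell_s))

  # identical shots: all shifts zero
  dat2 <- array(rep(base, each = 3), c(3, 1, 2048))
  for (s in 1:3) dat2[s, 1, ] <- base
  ra2 <- realign_shots(fid_series(dat2, acq))
  expect_lt(max(abs(ra2$shifts_hz)), 0.01)
  expect_false(any(ra2$low_confidence))

  # pure-noise shots flagged low confidence
  set.seed(9)
  dat3 <- array(complex(real = rnorm(3 * 2048), imaginary = rnorm(3 * 2048)),
                c(3, 1, 2048))
  ra3 <- realign_shots(fid_series(dat3, acq), confidence_floor = 0.9)
  expect_true(all(ra3$low_confidence))
})

test_that("realignment never widens the spread of water-peak positions", {
  sim <- simulate_series(preset_scenario("fb", seed = 13, n_shots = 20))
  comb <- svd_combine(sim$series)
  peak_pos <- function(series) vapply(seq_len(series$acq$n_shots), function(s) {
    sp <- to_spectrum(zero_fill(series$data[s, 1, ], 2), series$acq)
    idx <- which(sp$ppm_axis > 4.2 & sp$ppm_axis < 5.2)
    sp$ppm_axis[idx][which.max(Mod(sp$values[idx]))]
  }, numeric(1))
  before <- sd(peak_pos(comb))
  after <- sd(peak_pos(realign_shots(comb)$series))
  expect_lte(after, before + 1e-12)
})

test_that("fwhm matches closed forms for both lineshapes", {
  acq <- single_acq(n_points = 2048)
  t <- time_axis_of(acq)
  sp_l <- to_spectrum(zero_fill(exp(-pi * 15 * t) + 0i, 4), acq)
  expect_equal(fwhm(sp_l, 4.7, 0.5), 15, tolerance = 2 * sp_l$df_hz)
  # Gaussian envelope chosen for a 12 Hz FWHM
  lw <- 12
  sp_g <- to_spectrum(zero_fill(exp(-(pi * lw * t)^2 / (4 * log(2))) + 0i, 4),
                      acq)
  expect_equal(fwhm(sp_g, 4.7, 0.5), lw, tolerance = 2 * sp_g$df_hz)
  # flat spectrum has no half-maximum crossing
  flat <- to_spectrum(c(1, rep(0i, 255)), single_acq(n_points = 256))
  expect_error(fwhm(flat, 4.7, 0.5), "truncated|no positive peak")
})

test_that("snr divides peak height by the noise-window SD", {
  acq <- single_acq(n_points = 2048)
  sp <- to_spectrum(rep(0i, 2048), acq)
  # construct: peak of height 10 at 3 ppm, noise of SD 2 in -3..-1 ppm
  vals <- rep(0 + 0i, 2048)
  peak_idx <- which.min(abs(sp$ppm_axis - 3))
  vals[peak_idx] <- 10
  nidx <- which(sp$ppm_axis >= -3 & sp$ppm_axis <= -1)
  set.seed(11)
  noise <- rnorm(length(nidx))
  vals[nidx] <- noise / sd(noise) * 2
  sp$values <- vals
  expect_equal(as.numeric(snr(sp, 3)), 5, tolerance = 1e-10)
  # zero-noise guard
  sp$values[nidx] <- 0
  out <- snr(sp, 3)
  expect_true(is.infinite(out))
  expect_true(isTRUE(attr(out, "zero_noise")))
})

test_that("mean measured SNR agrees with the matched analytic value", {
  acq <- single_acq(n_points = 512)
  amp <- 1; sigma <- 0.03; lb <- 10
  t <- time_axis_of(acq)
  env <- exp(-pi * lb * t)
  clean <- amp * simulate_component_fid("Cr", one_comp_scenario(acq))
  peak_height <- max(Re(to_spectrum(apodize(clean, acq, lb), acq)$values))
  analytic <- peak_height / (sigma * sqrt(sum(env^2)))
  measured <- vapply(1:200, function(sd) {
    set.seed(3000 + sd)
    y <- clean + complex(real = rnorm(512, 0, sigma),
                         imaginary = rnorm(512, 0, sigma))
    as.numeric(snr(to_spectrum(apodize(y, acq, lb), acq), 3.027))
  }, numeric(1))
  expect_equal(mean(measured), analytic, tolerance = 0.1 * analytic)
})

test_that("quality-control exclusions use strict inequalities", {
  ok <- qc_filter(20, c(Cr = 12, FA = 43))
  expect_true(ok$qc_pass)
  bad_lw <- qc_filter(36, c(Cr = 12))
  expect_false(bad_lw$qc_pass)
  expect_match(bad_lw$qc_reasons, "linewidth")
  bad_snr <- qc_filter(20, c(Cr = 4.9))
  expect_false(bad_snr$qc_pass)
  expect_match(bad_snr$qc_reasons, "snr")
  # exactly at threshold passes (">" and "<" as printed)
  edge <- qc_filter(35, c(Cr = 5))
  expect_true(edge$qc_pass)
})
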