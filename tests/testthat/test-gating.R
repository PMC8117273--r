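test_that("shot characterization recovers the applied phase and frequency draws", {
  acq <- acq_params(n_channels = 1, n_shots = 40)
  sc <- sim_scenario(coil_sensitivities = 1 + 0i, acq = acq, seed = 6,
                     noise_sd = 1e-4,   # high SNR for the recovery check
                     breathing = list(phase_sd_rad = 0.4, freq_sd_hz = 3,
                                      lw_jitter_hz = 1))
  sim <- simulate_series(sc)
  qc <- characterize_shots(sim$series)
  expect_gt(cor(qc$water_phase_rad, sim$truth$per_shot$phase_rad), 0.99)
  expect_gt(cor(qc$water_shift_hz, sim$truth$per_shot$freq_hz), 0.99)
})

test_that("identical shots characterize identically; a broad shot stands out", {
  acq <- single_acq(n_points = 1024, n_shots = 5)
  base <- lorentzian_fid(acq, 12, 0, amp = 0.05) +
    lorentzian_fid(acq, 6, ppm_to_hz(3.027 - 4.7, acq$f0_mhz), amp = 0.01)
  dat <- array(0i, c(5, 1, 1024))
  for (s in 1:5) dat[s, 1, ] <- base
  t <- time_axis_of(acq)
  dat[3, 1, ] <- dat[3, 1, ] * exp(-pi * 24 * t)  # 3x water linewidth
  qc <- characterize_shots(fid_series(dat, acq))
  same <- c(1, 2, 4, 5)
  expect_equal(max(abs(diff(qc$water_lw_hz[same]))), 0)
  expect_equal(max(abs(diff(qc$water_phase_rad[same]))), 0)
  expect_equal(which.max(qc$water_lw_hz), 3L)
})

test_that("characterization refuses series without a water peak", {
  acq <- single_acq(n_points = 1024, n_shots = 6)
  set.seed(12)
  dat <- array(complex(real = rnorm(6 * 1024, 0, 1),
                       imaginary = rnorm(6 * 1024, 0, 1)), c(6, 1, 1024))
  expect_error(characterize_shots(fid_series(dat, acq)),
               "non-suppressed")
})

test_that("the linewidth threshold search admits all identical shots", {
  acq <- single_acq(n_points = 1024, n_shots = 8)
  base <- lorentzian_fid(acq, 12, 0, amp = 0.05) +
    lorentzian_fid(acq, 25, ppm_to_hz(1.3 - 4.7, acq$f0_mhz), amp = 0.02)
  set.seed(21)
  dat <- array(0i, c(8, 1, 1024))
  for (s in 1:8)
    dat[s, 1, ] <- base + complex(real = rnorm(1024, 0, 1e-4),
                                  imaginary = rnorm(1024, 0, 1e-4))
  ser <- fid_series(dat, acq)
  qc <- characterize_shots(ser)
  sel <- auto_lw_threshold(qc, ser)
  expect_gte(sel$threshold_hz, max(qc$water_lw_hz))
  # contract: trace covers every explored step; returned threshold maximizes
  # the SNR over accepted steps
  acc <- sel$trace[sel$trace$accepted, ]
  expect_equal(acc$fa_snr[acc$threshold_hz == sel$threshold_hz],
               max(acc$fa_snr))
  expect_error(auto_lw_threshold(qc[1:3, ], ser), "at least 4")
})

test_that("the threshold search rejects heavily corrupted shots, keeps clean ones", {
  cs <- corrupted_series(n_shots = 50, frac_corrupt = 0.2, seed = 4)
  qc <- characterize_shots(cs$series)
  sel <- auto_lw_threshold(qc, cs$series)
  excluded <- qc$water_lw_hz > sel$threshold_hz
  expect_gte(mean(excluded[cs$corrupt]), 0.8)
  expect_lte(mean(excluded[cs$clean]), 0.1)
})

test_that("phase gate implements the k x SD circular criterion", {
  mk_qc <- function(ph) {
    qc <- data.frame(shot = seq_along(ph), water_amp = 1, water_lw_hz = 12,
                     water_shift_hz = 0, water_phase_rad = ph,
                     accepted = TRUE, reject_reason = "none",
                     stringsAsFactors = FALSE)
    class(qc) <- c("shot_qc", class(qc))
    qc
  }
  # equal phases: no rejection (zero-variance guard)
  expect_true(all(phase_gate(mk_qc(rep(0.3, 10)))$accepted))
  # the single outlier is rejected, nothing else
  out <- phase_gate(mk_qc(c(0, 0, 0, 0, pi / 2)))
  expect_equal(which(!out$accepted), 5L)
  expect_equal(out$reject_reason[5], "phase")
  # k -> Inf rejects nothing, k = 0 rejects everything off the mean
  ph <- c(0.1, -0.2, 0.3, 0, 0.25)
  expect_true(all(phase_gate(mk_qc(ph), k = Inf)$accepted))
  expect_equal(sum(!phase_gate(mk_qc(ph), k = 0)$accepted), 5L)
})

test_that("Gaussian phases are rejected at the 2(1-Phi(k)) rate", {
  set.seed(14)
  ph <- rnorm(10000, 0, 0.5)
  qc <- data.frame(shot = seq_along(ph), water_amp = 1, water_lw_hz = 12,
                   water_shift_hz = 0, water_phase_rad = ph,
                   accepted = TRUE, reject_reason = "none",
                   stringsAsFactors = FALSE)
  class(qc) <- c("shot_qc", class(qc))
  frac <- mean(!phase_gate(qc, k = 0.6)$accepted)
  expect_equal(frac, 2 * (1 - pnorm(0.6)), tolerance = 0.02 / 0.549)
})

test_that("gating bookkeeping always sums to the shot count", {
  sim <- simulate_series(preset_scenario("fb", seed = 17, n_shots = 30))
  comb <- svd_combine(sim$series)
  g <- gate_and_average(comb)
  expect_equal(g$n_used + g$n_rejected_lw + g$n_rejected_phase, 30L)
  expect_gte(g$n_used, 1L)
  expect_equal(sum(g$qc$accepted), g$n_used)
  # reject_reason is "none" iff accepted
  expect_identical(g$qc$reject_reason == "none", g$qc$accepted)
})

test_that("breath-hold mode uses every shot without thresholds", {
  sim <- simulate_series(preset_scenario("bh", seed = 18))
  comb <- svd_combine(sim$series)
  g <- gate_and_average(comb, gate = FALSE)
  expect_equal(g$n_used, 8L)
  expect_true(is.na(g$lw_threshold_hz))
  expect_null(g$trace)
})

test_that("averaging the gated shots delivers the expected SNR growth", {
  sim <- simulate_series(preset_scenario("fb", seed = 19))
  comb <- svd_combine(sim$series)
  g <- gate_and_average(comb)
  acq <- comb$acq
  single_snrs <- vapply(which(g$qc$accepted)[1:5], function(s)
    as.numeric(snr(to_spectrum(apodize(comb$data[s, 1, ], acq, 10), acq), 1.3)),
    numeric(1))
  avg_snr <- as.numeric(snr(to_spectrum(apodize(g$averaged_fid, acq, 10), acq),
                            1.3))
  expect_gte(avg_snr, 0.8 * sqrt(g$n_used) * mean(single_snrs))
})

test_that("gating reduces the quantification bias of a corrupted series", {
  cs <- corrupted_series(n_shots = 50, frac_corrupt = 0.2, seed = 24)
  acq <- cs$series$acq
  basis <- build_basis(acq, include_water = TRUE)
  fit_amp <- function(fid) {
    noise <- max(as.numeric(estimate_noise_sd(fid)), 1e-12)
    fit_spectrum(apodize(fid, acq, 10), basis, noise_sd = noise)$amplitudes
  }
  qc <- characterize_shots(cs$series)
  gated <- gate_and_average(cs$series, qc = qc)
  ungated <- gate_and_average(cs$series, gate = FALSE, qc = qc)
  truth <- cs$truth$amplitudes[["TG13"]]
  bias_gated <- abs(fit_amp(gated$averaged_fid)[["TG13"]] - truth)
  bias_ungated <- abs(fit_amp(ungated$averaged_fid)[["TG13"]] - truth)
  expect_lte(bias_gated, bias_ungated + 0.02 * truth)
})

test_that("gating does not broaden the averaged water line", {
  cs <- corrupted_series(n_shots = 50, frac_corrupt = 0.2, seed = 31)
  acq <- cs$series$acq
  qc <- characterize_shots(cs$series)
  lw_of <- function(fid) {
    sp <- to_spectrum(zero_fill(fid, 2), acq)
    fwhm(sp, 4.7, 0.5)
  }
  gated <- gate_and_average(cs$series, qc = qc)
  ungated <- gate_and_average(cs$series, gate = FALSE, qc = qc)
  grid <- 1 / (2 * acq$n_points * acq$dwell_s)
  expect_lte(lw_of(gated$averaged_fid), lw_of(ungated$averaged_fid) + grid)
})
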