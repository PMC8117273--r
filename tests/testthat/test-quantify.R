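test_that("the chemical-shift displacement calculator matches the printed values", {
  df <- ppm_to_hz(4.7 - 1.3, 123.2)
  expect_equal(df, 418.88)
  expect_equal(round(100 * csde(df, 1150)), 36)
  expect_equal(round(100 * csde(df, 1700)), 25)
  expect_equal(round(100 * csde(df, 2200)), 19)
  expect_equal(csde(0, 1000), 0)
  # ppm front-end is equivalent to the Hz form
  expect_equal(csde_ppm(4.7, 1.3, 123.2, 1150), csde(df, 1150))
  expect_error(csde(100, 0), "bw_hz")
})

test_that("the phantom geometry formula gives the expected fat/water ratio", {
  expect_equal(round(phantom_expected_ratio(phantom_geometry(7.5, 8.5,
                                                             c(20, 20)))),
               102)
  expect_equal(phantom_expected_ratio(phantom_geometry(0, 8.5, c(20, 20))), 0)
  expect_equal(phantom_expected_ratio(phantom_geometry(10, 10, c(20, 20))),
               100 * (100 * pi) / (400 - 100 * pi))
  expect_error(phantom_geometry(9, 8.5), "r_inner")
  expect_error(phantom_geometry(10, 12, c(20, 20)), "fit")
})

test_that("relaxation correction reproduces the derived factors and limits", {
  # water and creatine factors at the standard cardiac TR/TE
  expect_equal(relaxation_correct(1, 1.20, 0.044, 1.1, 0.02396), 2.872,
               tolerance = 1e-3)
  expect_equal(relaxation_correct(1, 1.00, 0.135, 1.1, 0.02396), 1.790,
               tolerance = 1e-3)
  # TE = 0 and TR >> T1: factor -> 1
  expect_equal(relaxation_correct(1, 0.001, 0.001, 1000 * 0.001 * 1000, 0), 1,
               tolerance = 1e-4)
  expect_error(relaxation_correct(1, -1, 0.1, 1, 0.02), "t1")
  # simulate-then-correct is an exact round trip
  s0 <- 7.3
  t1 <- 0.35; t2 <- 0.089; tr <- 1.1; te <- 0.02396
  observed <- s0 * (1 - exp(-tr / t1)) * exp(-te / t2)
  expect_equal(relaxation_correct(observed, t1, t2, tr, te), s0)
})

test_that("the STEAM mixing-time factor is exp(TM/T1)", {
  expect_equal(steam_tm_correct(1, 0.0265, 1.0), exp(0.0265), tolerance = 1e-10)
  expect_equal(steam_tm_correct(1, 0.0265, 1.0), 1.0268, tolerance = 1e-4)
  expect_equal(steam_tm_correct(1, 0.0265, 0.35), 1.0787, tolerance = 1e-4)
  expect_equal(steam_tm_correct(3.2, 0, 1.0), 3.2)
  expect_error(steam_tm_correct(1, 0.02, 0), "t1")
})

test_that("the water reference constant follows the tissue-water formula", {
  expect_equal(water_reference(), 40348.5)
  expect_equal(water_reference(weight_fraction = 1), 55500)
  expect_equal(water_reference(weight_fraction = 0), 0)
})

test_that("concentration equations apply the proton ratios to corrected signals", {
  acq <- acq_params()  # PRESS, TE 23.96 ms, TR 1.1 s
  basis <- build_basis(acq)
  sc <- one_comp_scenario(acq)
  # construct a fit whose corrected Cr/W ratio is exactly 0.032%
  relax <- relaxation_table()
  corr_cr <- relaxation_correct(1, 1.00, 0.135, acq$tr_s, acq$te_s)
  corr_w <- relaxation_correct(1, 1.20, 0.044, acq$tr_s, acq$te_s)
  raw_cr <- 0.00032 * corr_w / corr_cr   # so S*_Cr / S*_W = 0.00032
  fid <- raw_cr * simulate_component_fid("Cr", sc)
  fit <- fit_spectrum(fid, basis, noise_sd = 1e-6)
  rep <- concentrations(fit, water_signal = 1, acq, relax)
  cr <- rep[rep$quantity == "Cr", ]
  expect_equal(cr$ratio_to_water_pct, 0.032, tolerance = 1e-3)
  expect_equal(cr$concentration_umol_g, 2 / 3 * 40348.5 * 0.00032,
               tolerance = 1e-3)
  expect_equal(round(cr$concentration_umol_g, 2), 8.61)

  # TG/W of 0.68% maps to 5.90 umol/g through the 2/93 proton factor
  corr_tg <- relaxation_correct(1, 0.35, 0.089, acq$tr_s, acq$te_s)
  raw_tg <- 0.0068 * corr_w / corr_tg
  fid_tg <- raw_tg * simulate_component_fid("TG13", sc)
  fit_tg <- fit_spectrum(fid_tg, basis, noise_sd = 1e-6)
  rep_tg <- concentrations(fit_tg, water_signal = 1, acq, relax)
  tg <- rep_tg[rep_tg$quantity == "TG", ]
  expect_equal(tg$concentration_umol_g, 2 / 93 * 40348.5 * 0.0068,
               tolerance = 1e-3)
  expect_equal(round(tg$concentration_umol_g, 2), 5.90)

  # zero metabolite amplitudes give zero concentrations
  fit0 <- fit_spectrum(0e0 * fid, basis, noise_sd = 1e-6)
  expect_warning(rep0 <- concentrations(fit0, 1, acq, relax), NA)
  expect_true(all(rep0$concentration_umol_g < 1e-8))

  # doubling the signal ratio doubles every concentration (linearity)
  fit2 <- fit_spectrum(2 * fid, basis, noise_sd = 1e-6)
  rep2 <- concentrations(fit2, water_signal = 1, acq, relax)
  expect_equal(rep2$concentration_umol_g, 2 * rep$concentration_umol_g,
               tolerance = 1e-6)
  # or equivalently halving the water signal
  rep_h <- concentrations(fit, water_signal = 0.5, acq, relax)
  expect_equal(rep_h$concentration_umol_g, 2 * rep$concentration_umol_g,
               tolerance = 1e-10)

  expect_error(concentrations(fit, water_signal = 0, acq, relax), "> 0")
})

test_that("STEAM quantification adds the TM factor to metabolite and water", {
  acq_st <- acq_params(sequence = "STEAM", te_s = 0.0054, tm_s = 0.0265)
  basis <- build_basis(acq_st)
  sc <- one_comp_scenario(acq_st)
  fid <- 0.001 * simulate_component_fid("Cr", sc)
  fit <- fit_spectrum(fid, basis, noise_sd = 1e-6)
  rep_st <- concentrations(fit, 1, acq_st, relaxation_table())
  # manual chain
  s_cr <- steam_tm_correct(relaxation_correct(0.001, 1.0, 0.135,
                                              acq_st$tr_s, acq_st$te_s),
                           0.0265, 1.0)
  s_w <- steam_tm_correct(relaxation_correct(1, 1.20, 0.044,
                                             acq_st$tr_s, acq_st$te_s),
                          0.0265, 1.20)
  expect_equal(rep_st[rep_st$quantity == "Cr", "concentration_umol_g"],
               2 / 3 * 40348.5 * s_cr / s_w, tolerance = 1e-3)
})

test_that("phantom mode corrects T2 only", {
  relax <- relaxation_table("phantom")
  expect_false(attr(relax, "t1_correct"))
  acq <- acq_params(water_suppressed = FALSE)
  s <- cmrs:::correct_species(1, "lipids", acq, relax)
  expect_equal(s, exp(acq$te_s / 0.05737))
})

test_that("T2 estimation recovers the decay constant from multi-TE amplitudes", {
  te <- c(23.96, 28.96, 33.96, 38.96, 43.96, 48.96, 53.96, 58.96, 63.96,
          68.96) / 1000
  fit <- estimate_t2(te, 100 * exp(-te / 0.05737))
  expect_equal(fit$t2_s, 0.05737, tolerance = 1e-3 * 0.05737)
  expect_false(fit$negative_rate)
  # two extra points of exact data reproduce the closed form
  fit2 <- estimate_t2(c(0.02, 0.04, 0.06), 5 * exp(-c(0.02, 0.04, 0.06) / 0.03))
  expect_equal(fit2$t2_s, 0.03, tolerance = 1e-6)
  closed <- (0.04 - 0.02) / log(fit2$fitted[1] / fit2$fitted[2])
  expect_equal(fit2$t2_s, closed, tolerance = 1e-6)
  # 5% multiplicative noise: small bias over repeated draws
  t2s <- vapply(1:200, function(seed) {
    set.seed(8000 + seed)
    estimate_t2(te, 100 * exp(-te / 0.05737) * exp(rnorm(10, 0, 0.05)))$t2_s
  }, numeric(1))
  expect_lt(abs(mean(t2s) / 0.05737 - 1), 0.02)
  # rising amplitudes flag a negative decay rate
  rising <- estimate_t2(te, 10 * exp(te / 0.1))
  expect_true(rising$negative_rate)
  expect_error(estimate_t2(te[1:2], c(1, 2)), "pairs")
})

test_that("true_concentrations mirrors the forward quantification chain", {
  acq <- acq_params()
  amps <- c(Cr = 3.2e-4, TG09 = 1e-3, TG13 = 2e-3, TG16 = 6e-4,
            TG21 = 4e-4, TG23 = 5e-4, TG28 = 3e-4)
  tc <- true_concentrations(amps, acq)
  basis <- build_basis(acq)
  sc <- one_comp_scenario(acq)
  fid <- Reduce(`+`, lapply(names(amps), function(nm)
    amps[[nm]] * simulate_component_fid(nm, sc)))
  fit <- fit_spectrum(fid, basis, noise_sd = 1e-8)
  rep <- concentrations(fit, 1, acq)
  expect_equal(rep$concentration_umol_g[match(c("Cr", "FA", "TG"),
                                              rep$quantity)],
               unname(tc), tolerance = 1e-3)
})
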