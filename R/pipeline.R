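#' Default pipeline configuration
#'
#' Flat key-value configuration with every pipeline constant overridable.
#' Defaults are the reference processing settings: 10 Hz exponential
#' apodization, zero-filling factor 2, stage-2 phase multiplier 0.6, water
#' linewidth exclusion above 35 Hz and SNR exclusion below 5.
#'
#' @param ... Overrides of the default entries.
#' @return Named list.
#' @export
default_config <- function(...) {
  cfg <- list(
    input = NULL,            # path to the water-suppressed container
    water_input = NULL,      # path to the non-suppressed companion container
    water_signal = NULL,     # alternative: water amplitude supplied directly
    mode = "bh",             # "bh" (no gating) or "fb" (two-stage gating)
    seed = 1L,
    output_dir = NULL,
    lb_hz = 10,
    zero_fill_factor = 2L,
    realign = TRUE,
    combine = "svd",         # "svd" or "sum"
    k_phase = 0.6,
    lw_step_hz = 1,
    disable_gate = "none",   # "none", "lw", "phase"
    lw_max_hz = 35,
    snr_min = 5,
    relaxation = "invivo",   # "invivo" or "phantom"
    tie_shifts = "group",
    verbose = FALSE)
  over <- list(...)
  if (length(over) == 1 && is.list(over[[1]]) && is.null(names(over)))
    over <- over[[1]]
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  utils::modifyList(cfg, over)
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file with flat key-value overrides of [default_config()].
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  default_config(jsonlite::fromJSON(path, simplifyVector = TRUE))
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE))
}

#' Preprocess a raw multi-channel series
#'
#' Applies the standard chain in order: per-channel phasing with SVD coil
#' combination, per-shot frequency realignment, and (optionally deferred)
#' zero-filling/apodization handled by later stages. Returns the combined,
#' realigned single-channel series plus per-shot spectral metrics.
#'
#' @param series Raw [fid_series()].
#' @param realign Logical: realign individual shots (skipped for a single
#'   shot).
#' @param combine `"svd"` (default) or `"sum"` (plain unweighted sum).
#' @return List with `series` (single-channel), `shifts_hz`,
#'   `low_confidence`.
#' @export
preprocess_series <- function(series, realign = TRUE,
                              combine = c("svd", "sum")) {
  combine <- match.arg(combine)
  acq <- series$acq
  combined <- if (combine == "svd") {
    svd_combine(series)
  } else {
    dat <- array(0i, c(acq$n_shots, 1, acq$n_points))
    for (s in seq_len(acq$n_shots))
      dat[s, 1, ] <- apply(series$data[s, , , drop = FALSE], 3, sum)
    a <- acq; a$n_channels <- 1L
    fid_series(dat, a, shot_index = series$shot_index)
  }
  shifts <- rep(0, acq$n_shots)
  lowconf <- rep(FALSE, acq$n_shots)
  if (realign && acq$n_shots >= 2) {
    ra <- realign_shots(combined)
    combined <- ra$series
    shifts <- ra$shifts_hz
    lowconf <- ra$low_confidence
  }
  list(series = combined, shifts_hz = shifts, low_confidence = lowconf)
}

#' Run the full processing pipeline
#'
#' Orchestrates preprocess -> (FB only) retrospective gating -> time-domain
#' model fit -> relaxation-corrected water-referenced quantification, and
#' (when `output_dir` is set) writes the tabular outputs: `shot_qc.csv` (one
#' row per shot, with every rejection decision), `fit.csv` (one row per
#' basis component) and `concentrations.csv`, plus `rejections.log`.
#' Deterministic given fixed inputs, config and seed; any stage error is
#' re-thrown tagged with the stage name.
#'
#' @param config Named list (see [default_config()]) or path to a JSON
#'   config file. Either `input` (container path) or `series` must be
#'   supplied.
#' @param series Optional in-memory [fid_series()] overriding
#'   `config$input`.
#' @param water_series Optional in-memory non-suppressed [fid_series()]
#'   overriding `config$water_input`.
#' @return List of class `pipeline_result`: `report`
#'   (`concentration_report`), `fit` (`fit_result`), `gating`
#'   (`gating_result`), `qc` (per-shot table), `metrics` (water linewidth /
#'   peak SNR / QC verdict of the final averaged spectrum), `config`.
#' @export
run_pipeline <- function(config = default_config(), series = NULL,
                         water_series = NULL) {
  if (is.character(config)) config <- read_config(config)
  cfg <- default_config(config)
  set.seed(cfg$seed)
  say <- function(...) if (isTRUE(cfg$verbose)) message(sprintf(...))

  series <- with_stage("input", {
    if (is.null(series)) {
      if (is.null(cfg$input)) stop("no input series or container path given")
      read_series(cfg$input)
    } else series
  })
  acq <- series$acq

  pp <- with_stage("preprocess",
                   preprocess_series(series, realign = isTRUE(cfg$realign) && acq$n_shots >= 2,
                                     combine = cfg$combine))
  say("preprocess: combined %d channel(s), %d shot(s)", acq$n_channels,
      acq$n_shots)

  gating <- with_stage("gate", {
    gate <- identical(tolower(cfg$mode), "fb")
    gate_and_average(pp$series, gate = gate, k_phase = cfg$k_phase,
                     step_hz = cfg$lw_step_hz, disable = cfg$disable_gate,
                     lb_hz = cfg$lb_hz)
  })
  say("gate: used %d / rejected %d (lw) + %d (phase)", gating$n_used,
      gating$n_rejected_lw, gating$n_rejected_phase)

  fit <- with_stage("fit", {
    noise_sd <- estimate_noise_sd(gating$averaged_fid)
    # a water component is always kept in the basis: water-suppressed scans
    # still carry a residual water line that must be modeled, not ignored
    basis <- build_basis(acq, include_water = TRUE)
    fid <- apodize(zero_fill(gating$averaged_fid, cfg$zero_fill_factor),
                   acq, cfg$lb_hz)
    basis_zf <- basis
    if (cfg$zero_fill_factor > 1) {
      basis_zf$fids <- apply(basis$fids, 2, zero_fill, factor = cfg$zero_fill_factor)
      basis_zf$acq$n_points <- as.integer(acq$n_points * cfg$zero_fill_factor)
    }
    fit_spectrum(fid, basis_zf, noise_sd = as.numeric(noise_sd),
                 tie_shifts = cfg$tie_shifts)
  })
  say("fit: converged=%s damping=%.2f Hz", fit$converged, fit$damping_hz)

  water_signal <- with_stage("quantify", {
    if (!is.null(cfg$water_signal)) {
      as.numeric(cfg$water_signal)
    } else {
      wser <- if (!is.null(water_series)) water_series
              else if (!is.null(cfg$water_input)) read_series(cfg$water_input)
              else stop("no water reference: set water_input, water_signal, ",
                        "or pass water_series")
      fit_water_amplitude(wser, lb_hz = cfg$lb_hz,
                          zero_fill_factor = cfg$zero_fill_factor,
                          combine = cfg$combine)
    }
  })

  relax <- relaxation_table(cfg$relaxation)
  report <- with_stage("quantify",
                       concentrations(fit, water_signal, acq, relax))

  metrics <- with_stage("metrics", {
    sp <- to_spectrum(apodize(zero_fill(gating$averaged_fid,
                                        cfg$zero_fill_factor), acq, cfg$lb_hz),
                      acq)
    water_lw <- tryCatch(fwhm(sp, acq$reference_ppm, 0.5),
                         error = function(e) NA_real_)
    peak_snr <- c(Cr = as.numeric(tryCatch(snr(sp, 3.027), error = function(e) NA)),
                  FA = as.numeric(tryCatch(snr(sp, 1.3), error = function(e) NA)))
    qc <- qc_filter(water_lw, peak_snr[is.finite(peak_snr)],
                    lw_max_hz = cfg$lw_max_hz, snr_min = cfg$snr_min)
    list(water_lw_hz = water_lw, peak_snr = peak_snr,
         qc_pass = qc$qc_pass, qc_reasons = qc$qc_reasons)
  })

  out <- list(report = report, fit = fit, gating = gating, qc = gating$qc,
              metrics = metrics, water_signal = water_signal, config = cfg)
  class(out) <- "pipeline_result"

  if (!is.null(cfg$output_dir)) with_stage("output", {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(gating$qc, file.path(cfg$output_dir, "shot_qc.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(fit), file.path(cfg$output_dir, "fit.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(report),
                     file.path(cfg$output_dir, "concentrations.csv"),
                     row.names = FALSE)
    rej <- gating$qc[!gating$qc$accepted, , drop = FALSE]
    lines <- sprintf(
      "shot %d rejected: criterion=%s water_lw=%.3f Hz water_phase=%.4f rad (lw threshold %.3f Hz, phase multiplier %.2f)",
      rej$shot, rej$reject_reason, rej$water_lw_hz, rej$water_phase_rad,
      gating$lw_threshold_hz, cfg$k_phase)
    writeLines(lines, file.path(cfg$output_dir, "rejections.log"))
  })
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$gating)
  print(x$report)
  invisible(x)
}

#' Water amplitude from a non-suppressed companion scan
#'
#' Preprocesses and averages the non-suppressed series, then fits it with a
#' water-only basis to get the reference amplitude on the same scale as the
#' metabolite fit.
#'
#' @param water_series Non-suppressed [fid_series()].
#' @param lb_hz,zero_fill_factor,combine As in the main pipeline.
#' @return Water amplitude (a.u.).
#' @export
fit_water_amplitude <- function(water_series, lb_hz = 10,
                                zero_fill_factor = 2L, combine = "svd") {
  acq <- water_series$acq
  pp <- preprocess_series(water_series, realign = acq$n_shots >= 2,
                          combine = combine)
  avg <- average_shots(pp$series)
  noise_sd <- as.numeric(estimate_noise_sd(avg))
  comp <- resonance_table()
  comp <- comp[comp$name == "water", ]
  basis <- build_basis(acq, components = comp)
  fid <- apodize(zero_fill(avg, zero_fill_factor), acq, lb_hz)
  if (zero_fill_factor > 1) {
    basis$fids <- apply(basis$fids, 2, zero_fill, factor = zero_fill_factor)
    basis$acq$n_points <- as.integer(acq$n_points * zero_fill_factor)
  }
  fit <- fit_spectrum(fid, basis, noise_sd = max(noise_sd, 1e-12))
  unname(fit$amplitudes["water"])
}
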