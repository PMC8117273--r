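#' Characterize every shot by its residual water peak
#'
#' For each shot the residual water resonance is located within 4.7 +/- 0.5
#' ppm of the magnitude spectrum; the shot's phase is the complex phase of
#' the peak bin before any per-shot phasing, its frequency offset the
#' (parabolic-refined) peak position relative to 4.7 ppm in Hz, its amplitude
#' the real-part peak height after zeroth-order phasing, and its linewidth
#' the water-peak FWHM of the phased real spectrum.
#'
#' @param series Single-channel (post-combination) [fid_series()] in which a
#'   residual or full water peak is present.
#' @param zero_fill_factor Zero-filling applied before peak picking, for
#'   sub-grid position precision.
#' @param detect_snr Number of magnitude-noise SDs above the noise mean that
#'   the water peak must reach to count as detected; if more than half the
#'   shots fail detection an error advises acquiring a non-suppressed
#'   reference.
#' @return data.frame of class `shot_qc`: `shot`, `water_amp`, `water_lw_hz`,
#'   `water_shift_hz`, `water_phase_rad`, `accepted`, `reject_reason`.
#' @export
characterize_shots <- function(series, zero_fill_factor = 2L,
                               detect_snr = 5) {
  acq <- series$acq
  if (acq$n_channels != 1)
    stop("characterize_shots expects a single-channel series", call. = FALSE)
  ref <- acq$reference_ppm
  n_shots <- acq$n_shots
  out <- data.frame(shot = seq_len(n_shots), water_amp = NA_real_,
                    water_lw_hz = NA_real_, water_shift_hz = NA_real_,
                    water_phase_rad = NA_real_, accepted = TRUE,
                    reject_reason = "none", stringsAsFactors = FALSE)
  undetected <- 0L
  for (s in seq_len(n_shots)) {
    fid <- zero_fill(get_fid(series, s), zero_fill_factor)
    sp <- to_spectrum(fid, acq)
    idx <- ppm_window_idx(sp, ref - 0.5, ref + 0.5)
    mag <- Mod(sp$values[idx])
    k <- which.max(mag)
    # detection check against the magnitude noise floor (mean + k * SD of
    # the Rayleigh-distributed noise magnitude)
    nidx <- ppm_window_idx(sp, -3, -1)
    floor_mag <- if (length(nidx) >= 8)
      mean(Mod(sp$values[nidx])) + detect_snr * stats::sd(Mod(sp$values[nidx]))
    else 0
    if (floor_mag > 0 && mag[k] < floor_mag) {
      undetected <- undetected + 1L
      next
    }
    # parabolic sub-bin peak position (magnitude); hz_axis is descending here
    hzw <- sp$hz_axis[idx]
    frac <- 0
    if (k > 1 && k < length(mag)) {
      denom <- mag[k - 1] - 2 * mag[k] + mag[k + 1]
      if (denom < 0) frac <- 0.5 * (mag[k - 1] - mag[k + 1]) / denom
    }
    step <- if (length(hzw) > 1) hzw[2] - hzw[1] else 0
    peak_hz <- hzw[k] + frac * step
    phase <- Arg(sp$values[idx][k])
    phased <- sp
    phased$values <- sp$values * exp(-1i * phase)
    amp <- Re(phased$values[idx][k])
    lw <- tryCatch(fwhm(phased, center_ppm = ref, window_ppm = 0.5),
                   error = function(e) NA_real_)
    out$water_amp[s] <- amp
    out$water_lw_hz[s] <- lw
    out$water_shift_hz[s] <- peak_hz   # offset from reference_ppm in Hz
    out$water_phase_rad[s] <- wrap_phase(phase)
  }
  if (undetected > n_shots / 2)
    stop("no detectable water peak in more than half of the shots; ",
         "acquire a non-suppressed water reference or increase ",
         "residual-water amplitude", call. = FALSE)
  class(out) <- c("shot_qc", class(out))
  out
}

# phase- and frequency-correct a shot using its ShotQC row, in time domain
correct_shot <- function(fid, acq, phase_rad, shift_hz) {
  t <- (seq_along(fid) - 1) * acq$dwell_s
  fid * exp(-1i * phase_rad) * exp(-1i * 2 * pi * shift_hz * t)
}

# average of accepted shots after per-shot frequency (and optionally phase)
# correction
corrected_average <- function(series, qc, shots, phase_correct = TRUE) {
  acq <- series$acq
  acc <- rep(0i, acq$n_points)
  for (s in shots)
    acc <- acc + correct_shot(get_fid(series, s), acq,
                              if (phase_correct) qc$water_phase_rad[s] else 0,
                              qc$water_shift_hz[s])
  acc / length(shots)
}

#' Adaptive linewidth threshold search (gating stage 1)
#'
#' Greedy search for the maximum acceptable per-shot water linewidth: start
#' at the threshold admitting the best quartile of shots, increase in
#' `step_hz` steps, and at each step average the admitted shots (after
#' phase/frequency correction and apodization) and evaluate the fatty-acid
#' SNR at 1.3 ppm. A step is accepted iff the SNR is maintained or increased;
#' among equal-SNR steps the one with the smaller resulting FA linewidth is
#' preferred. The search stops at the first rejected step.
#'
#' @param qc `shot_qc` table from [characterize_shots()].
#' @param series The same single-channel series.
#' @param step_hz Threshold increment (default 1 Hz).
#' @param start `"quartile"` (default: admit the best quartile of shots) or
#'   `"min"` (start just above the smallest linewidth).
#' @param fa_ppm Peak used to score the average (default 1.3).
#' @param lb_hz Apodization applied to the scored averages (default 10 Hz).
#' @return List with `threshold_hz` and `trace`, a data.frame of every
#'   explored step: `threshold_hz`, `n_admitted`, `fa_snr`, `fa_lw_hz`,
#'   `accepted`.
#' @export
auto_lw_threshold <- function(qc, series, step_hz = 1, start = c("quartile", "min"),
                              fa_ppm = 1.3, lb_hz = 10) {
  start <- match.arg(start)
  lw <- qc$water_lw_hz
  ok <- which(is.finite(lw))
  if (length(ok) < 4)
    stop("need at least 4 characterized shots for the threshold search",
         call. = FALSE)
  acq <- series$acq
  score <- function(threshold) {
    adm <- ok[lw[ok] <= threshold]
    if (!length(adm)) return(list(n = 0L, snr = -Inf, lw = Inf))
    # frequency realignment only: the threshold is chosen while shot-to-shot
    # phase corruption is still present (the phase stage has not run yet),
    # so phase-corrupted broad shots must be allowed to degrade the score
    avg <- corrected_average(series, qc, adm, phase_correct = FALSE)
    sp <- to_spectrum(apodize(avg, acq, lb_hz), acq)
    s <- tryCatch(as.numeric(snr(sp, fa_ppm)), error = function(e) NA_real_)
    w <- tryCatch(fwhm(sp, center_ppm = fa_ppm, window_ppm = 0.4),
                  error = function(e) NA_real_)
    list(n = length(adm), snr = if (is.finite(s)) s else -Inf,
         lw = if (is.finite(w)) w else Inf)
  }
  thr0 <- switch(start,
                 quartile = as.numeric(stats::quantile(lw[ok], 0.25, type = 1)),
                 min = min(lw[ok]))
  cur <- score(thr0)
  trace <- data.frame(threshold_hz = thr0, n_admitted = cur$n,
                      fa_snr = cur$snr, fa_lw_hz = cur$lw, accepted = TRUE)
  best_thr <- thr0
  thr <- thr0
  lw_max <- max(lw[ok])
  while (thr < lw_max) {
    thr <- thr + step_hz
    cand <- score(thr)
    accept <- cand$snr > cur$snr ||
      (cand$snr == cur$snr && cand$lw <= cur$lw)
    trace <- rbind(trace,
                   data.frame(threshold_hz = thr, n_admitted = cand$n,
                              fa_snr = cand$snr, fa_lw_hz = cand$lw,
                              accepted = accept))
    if (!accept) break
    cur <- cand
    best_thr <- thr
  }
  list(threshold_hz = best_thr, trace = trace)
}

#' Phase-deviation rejection (gating stage 2)
#'
#' Rejects any shot whose water-peak phase deviates from the circular mean
#' phase by more than `k` times the phase standard deviation. Following the
#' original criterion the SD is estimated over the whole scan (all
#' characterized shots), not only the stage-1 survivors; set
#' `sd_scope = "survivors"` for the alternative.
#'
#' @param qc `shot_qc` table; only currently-accepted shots are evaluated.
#' @param k Rejection multiplier (default 0.6).
#' @param sd_scope `"all"` (default) or `"survivors"`.
#' @return Updated `shot_qc` table with `accepted`/`reject_reason` set.
#' @export
phase_gate <- function(qc, k = 0.6, sd_scope = c("all", "survivors")) {
  sd_scope <- match.arg(sd_scope)
  pool <- switch(sd_scope,
                 all = which(is.finite(qc$water_phase_rad)),
                 survivors = which(qc$accepted & is.finite(qc$water_phase_rad)))
  if (!length(pool)) return(qc)
  mu <- Arg(sum(exp(1i * qc$water_phase_rad[pool])))
  dev_pool <- wrap_phase(qc$water_phase_rad[pool] - mu)
  sd_phase <- stats::sd(dev_pool)
  if (!is.finite(sd_phase) || sd_phase == 0) return(qc)  # zero-variance guard
  eval_idx <- which(qc$accepted & is.finite(qc$water_phase_rad))
  dev <- abs(wrap_phase(qc$water_phase_rad[eval_idx] - mu))
  rej <- eval_idx[dev > k * sd_phase]
  qc$accepted[rej] <- FALSE
  qc$reject_reason[rej] <- "phase"
  qc
}

#' Two-stage retrospective gating and averaging
#'
#' Free-breathing mode applies the adaptive linewidth threshold (stage 1)
#' then the phase-deviation criterion (stage 2); accepted shots are phase-
#' and frequency-corrected with their own ShotQC estimates and averaged.
#' Breath-hold mode (`gate = FALSE`) skips both stages and averages all
#' shots after correction. Counts always satisfy
#' `n_used + n_rejected_lw + n_rejected_phase = n_shots`.
#'
#' @param series Single-channel [fid_series()].
#' @param gate Logical: apply the two rejection stages (FALSE for BH mode).
#' @param k_phase Stage-2 multiplier (default 0.6).
#' @param step_hz Stage-1 threshold increment (default 1 Hz).
#' @param disable `"none"`, `"lw"` or `"phase"`: selectively disable a stage.
#' @param lb_hz Apodization used inside the stage-1 SNR scoring.
#' @param qc Optional precomputed [characterize_shots()] table.
#' @param sd_scope Passed to [phase_gate()].
#' @return List of class `gating_result`: `qc` (final `shot_qc` table),
#'   `lw_threshold_hz`, `n_used`, `n_rejected_lw`, `n_rejected_phase`,
#'   `averaged_fid`, `trace` (stage-1 search trace or NULL).
#' @export
gate_and_average <- function(series, gate = TRUE, k_phase = 0.6, step_hz = 1,
                             disable = c("none", "lw", "phase"), lb_hz = 10,
                             qc = NULL, sd_scope = "all") {
  disable <- match.arg(disable)
  acq <- series$acq
  if (is.null(qc)) qc <- characterize_shots(series)
  qc$accepted <- is.finite(qc$water_phase_rad)
  qc$reject_reason <- ifelse(qc$accepted, "none", "linewidth")
  threshold <- NA_real_
  trace <- NULL
  if (gate && disable != "lw" && acq$n_shots >= 4) {
    sel <- auto_lw_threshold(qc, series, step_hz = step_hz, lb_hz = lb_hz)
    threshold <- sel$threshold_hz
    trace <- sel$trace
    rej <- which(qc$accepted & (!is.finite(qc$water_lw_hz) |
                                  qc$water_lw_hz > threshold))
    qc$accepted[rej] <- FALSE
    qc$reject_reason[rej] <- "linewidth"
  }
  if (gate && disable != "phase") {
    qc <- phase_gate(qc, k = k_phase, sd_scope = sd_scope)
  }
  used <- which(qc$accepted)
  if (!length(used))
    stop("all shots rejected by retrospective gating", call. = FALSE)
  # shots that were never characterized fall back to zero correction
  qc2 <- qc
  qc2$water_phase_rad[!is.finite(qc2$water_phase_rad)] <- 0
  qc2$water_shift_hz[!is.finite(qc2$water_shift_hz)] <- 0
  avg <- corrected_average(series, qc2, used)
  res <- list(qc = qc, lw_threshold_hz = threshold,
              n_used = length(used),
              n_rejected_lw = sum(qc$reject_reason == "linewidth"),
              n_rejected_phase = sum(qc$reject_reason == "phase"),
              averaged_fid = avg, trace = trace)
  class(res) <- "gating_result"
  res
}

#' @export
print.gating_result <- function(x, ...) {
  cat(sprintf("<gating_result> used %d | rejected %d (linewidth) + %d (phase)%s\n",
              x$n_used, x$n_rejected_lw, x$n_rejected_phase,
              if (is.finite(x$lw_threshold_hz))
                sprintf(" | LW threshold %.1f Hz", x$lw_threshold_hz) else ""))
  invisible(x)
}
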