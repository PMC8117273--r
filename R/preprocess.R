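#' Automatic zeroth- and first-order phase correction
#'
#' The zeroth-order term is chosen so that the tallest magnitude peak becomes
#' real-positive; the first-order (frequency-linear) term is estimated by
#' magnitude-weighted least squares on the unwrapped spectral phase over the
#' points whose magnitude exceeds 20% of the maximum, with the pivot at the
#' tallest peak. Both corrections are applied and returned.
#'
#' @param fid Complex FID vector (non-zero).
#' @param acq [acq_params()].
#' @param first_order Logical: also estimate/apply the first-order term.
#' @return List with `fid` (corrected), `phi0_rad` (wrapped to (-pi, pi]),
#'   `phi1_rad_per_hz` and `pivot_hz`.
#' @export
autophase <- function(fid, acq, first_order = TRUE) {
  if (all(Mod(fid) == 0)) stop("cannot phase an all-zero FID", call. = FALSE)
  n <- length(fid)
  s <- fft_shift(stats::fft(as.complex(fid)))
  f <- freq_axis(n, acq$dwell_s)
  mag <- Mod(s)
  kmax <- which.max(mag)
  phi0 <- Arg(s[kmax])
  phi1 <- 0
  pivot <- f[kmax]
  if (first_order) {
    # Sample the phase at local magnitude maxima above 20% of the global
    # maximum: at a peak center the dispersive lineshape phase vanishes, so
    # the measured phase there is purely the (phi0 + phi1 * f) error. A
    # least-squares line through every masked point would be biased by the
    # antisymmetric phase swing across each line.
    mask <- mag > 0.2 * mag[kmax]
    peaks <- which(mask)
    peaks <- peaks[peaks > 1 & peaks < n]
    peaks <- peaks[mag[peaks] >= mag[peaks - 1] & mag[peaks] >= mag[peaks + 1]]
    if (length(peaks) >= 2) {
      # sub-bin refinement: parabolic peak position, phase interpolated to it
      df <- f[2] - f[1]
      fpk <- numeric(length(peaks))
      phk <- numeric(length(peaks))
      s0 <- s * exp(-1i * phi0)
      for (j in seq_along(peaks)) {
        p <- peaks[j]
        denom <- mag[p - 1] - 2 * mag[p] + mag[p + 1]
        frac <- if (denom < 0) 0.5 * (mag[p - 1] - mag[p + 1]) / denom else 0
        fpk[j] <- f[p] + frac * df
        nb <- p + sign(frac)
        dphi <- if (frac != 0) wrap_phase(Arg(s0[nb]) - Arg(s0[p])) else 0
        phk[j] <- Arg(s0[p]) + abs(frac) * dphi
      }
      ph <- unwrap_phase(phk)
      w <- mag[peaks]
      x <- fpk - pivot
      sw <- sum(w); mx <- sum(w * x) / sw; my <- sum(w * ph) / sw
      denom <- sum(w * (x - mx)^2)
      if (denom > 0) {
        phi1 <- sum(w * (x - mx) * (ph - my)) / denom
        phi0 <- wrap_phase(phi0 + (my - phi1 * mx))
      }
    }
  }
  corr <- exp(-1i * (phi0 + phi1 * (f - pivot)))
  out <- stats::fft(fft_unshift(s * corr), inverse = TRUE) / n
  list(fid = out, phi0_rad = wrap_phase(phi0), phi1_rad_per_hz = phi1,
       pivot_hz = pivot)
}

wrap_phase <- function(phi) {
  out <- (phi + pi) %% (2 * pi) - pi
  ifelse(out == -pi, pi, out)
}

unwrap_phase <- function(phi) {
  d <- diff(phi)
  jumps <- cumsum(c(0, round(d / (2 * pi))))
  phi - 2 * pi * jumps
}

#' SVD coil combination
#'
#' After per-channel phasing, the channel weights are the dominant left
#' singular vector of the channels-by-(shots x time) data matrix; each shot
#' is the conjugate-weighted sum over channels. A final global phase makes
#' the water peak of the mean spectrum real-positive. This is the
#' matched-filter combination: for equal-gain channels with independent
#' noise the SNR gain approaches sqrt(n_channels).
#'
#' @param series A [fid_series()] with `n_channels >= 1`.
#' @return Single-channel [fid_series()].
#' @export
svd_combine <- function(series) {
  acq <- series$acq
  x <- series$data
  if (all(Mod(x) == 0)) stop("cannot combine an all-zero series", call. = FALSE)
  nc <- acq$n_channels
  if (nc > 1) {
    # per-channel phasing estimated on the channel-mean FID
    for (ch in seq_len(nc)) {
      mean_fid <- apply(x[, ch, , drop = FALSE], 3, mean)
      if (all(Mod(mean_fid) == 0)) next
      ph <- autophase(mean_fid, acq)
      corr <- phase_correction_vector(length(mean_fid), acq, ph)
      for (s in seq_len(acq$n_shots))
        x[s, ch, ] <- apply_freq_phase(x[s, ch, ], corr)
    }
    m <- matrix(0i, nrow = nc, ncol = acq$n_shots * acq$n_points)
    for (ch in seq_len(nc)) m[ch, ] <- as.complex(aperm(x[, ch, , drop = FALSE], c(3, 1, 2)))
    sv <- svd(m, nu = 1, nv = 0)
    w <- sv$u[, 1]
  } else {
    w <- 1 + 0i
  }
  combined <- array(0i, c(acq$n_shots, 1, acq$n_points))
  for (s in seq_len(acq$n_shots)) {
    acc <- rep(0i, acq$n_points)
    for (ch in seq_len(nc)) acc <- acc + Conj(w[ch]) * x[s, ch, ]
    combined[s, 1, ] <- acc
  }
  # global phase: water peak (or tallest peak) of the mean spectrum real-positive
  mean_fid <- apply(combined[, 1, , drop = FALSE], 3, mean)
  sp <- to_spectrum(mean_fid, acq)
  idx <- ppm_window_idx(sp, acq$reference_ppm - 0.5, acq$reference_ppm + 0.5)
  if (!length(idx) || max(Mod(sp$values[idx])) < 0.2 * max(Mod(sp$values)))
    idx <- seq_along(sp$values)
  k <- idx[which.max(Mod(sp$values[idx]))]
  psi <- Arg(sp$values[k])
  combined <- combined * exp(-1i * psi)
  acq$n_channels <- 1L
  fid_series(combined, acq, shot_index = series$shot_index)
}

# frequency-domain multiplier for a stored autophase estimate
phase_correction_vector <- function(n, acq, ph) {
  f <- freq_axis(n, acq$dwell_s)
  exp(-1i * (ph$phi0_rad + ph$phi1_rad_per_hz * (f - ph$pivot_hz)))
}

apply_freq_phase <- function(fid, corr) {
  n <- length(fid)
  stats::fft(fft_unshift(fft_shift(stats::fft(as.complex(fid))) * corr),
             inverse = TRUE) / n
}

#' Zero-fill an FID
#'
#' Appends zeros so that the output has `factor` times the input length. The
#' DFT evaluated at the original frequency grid is unchanged; intermediate
#' bins interpolate the spectrum.
#'
#' @param fid Complex FID vector.
#' @param factor Integer >= 1.
#' @return Zero-padded complex vector.
#' @export
zero_fill <- function(fid, factor = 2L) {
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1) stop("factor must be >= 1", call. = FALSE)
  c(as.complex(fid), rep(0i, (factor - 1L) * length(fid)))
}

#' Exponential (line-broadening) apodization
#'
#' Multiplies the FID by `exp(-pi * lb_hz * t)`, adding `lb_hz` to the
#' full width at half maximum of a Lorentzian line.
#'
#' @param fid Complex FID vector.
#' @param acq [acq_params()] (supplies the dwell time).
#' @param lb_hz Line broadening in Hz (>= 0); 10 Hz by default.
#' @param shape `"exponential"` (default) or `"gaussian"`; the Gaussian
#'   alternative multiplies by `exp(-(pi * lb_hz * t)^2 / (4 log 2))`.
#' @return Apodized complex FID.
#' @export
apodize <- function(fid, acq, lb_hz = 10,
                    shape = c("exponential", "gaussian")) {
  shape <- match.arg(shape)
  if (lb_hz < 0) stop("lb_hz must be >= 0", call. = FALSE)
  t <- (seq_along(fid) - 1) * acq$dwell_s
  env <- if (shape == "gaussian")
    exp(-(pi * lb_hz * t)^2 / (4 * log(2))) else exp(-pi * lb_hz * t)
  as.complex(fid) * env
}

#' Per-shot frequency realignment
#'
#' Estimates each shot's frequency offset by cross-correlating its magnitude
#' spectrum with a reference (the pointwise median magnitude spectrum, or the
#' first shot) over the 0-6 ppm window, refines the offset by parabolic
#' interpolation of the correlation peak, and removes it by multiplying the
#' FID with `exp(-1i * 2 * pi * shift * t)`.
#'
#' @param series Single-channel [fid_series()] with at least 2 shots.
#' @param reference `"median_spectrum"` (default) or `"first_shot"`.
#' @param max_shift_hz Search half-range in Hz.
#' @param confidence_floor Normalized-correlation floor below which a shot's
#'   estimate is flagged low-confidence (returned, still applied).
#' @return List with `series` (realigned), `shifts_hz` and `low_confidence`
#'   (logical per shot).
#' @export
realign_shots <- function(series, reference = c("median_spectrum", "first_shot"),
                          max_shift_hz = 30, confidence_floor = 0.2) {
  reference <- match.arg(reference)
  acq <- series$acq
  if (acq$n_channels != 1)
    stop("realign_shots expects a single-channel (combined) series", call. = FALSE)
  if (acq$n_shots < 2) stop("need at least 2 shots to realign", call. = FALSE)
  n <- acq$n_points
  f <- freq_axis(n, acq$dwell_s)
  ppm <- acq$reference_ppm + f / acq$f0_mhz
  win <- which(ppm >= 0 & ppm <= 6)
  mags <- matrix(0, nrow = acq$n_shots, ncol = n)
  for (s in seq_len(acq$n_shots))
    mags[s, ] <- Mod(fft_shift(stats::fft(get_fid(series, s))))
  ref <- switch(reference,
                median_spectrum = apply(mags, 2, stats::median),
                first_shot = mags[1, ])
  df <- 1 / (n * acq$dwell_s)
  maxlag <- max(1L, min(ceiling(max_shift_hz / df), length(win) - 2L))
  t <- time_axis(acq)
  shifts <- numeric(acq$n_shots)
  lowconf <- logical(acq$n_shots)
  data <- series$data
  refw <- ref[win]
  for (s in seq_len(acq$n_shots)) {
    cc <- vapply(-maxlag:maxlag, function(lag) {
      idx <- win + lag
      ok <- idx >= 1 & idx <= n
      sum(refw[ok] * mags[s, idx[ok]])
    }, numeric(1))
    k <- which.max(cc)
    lag <- (-maxlag:maxlag)[k]
    # parabolic refinement on the three bins around the maximum
    frac <- 0
    if (k > 1 && k < length(cc)) {
      denom <- cc[k - 1] - 2 * cc[k] + cc[k + 1]
      if (denom < 0) frac <- 0.5 * (cc[k - 1] - cc[k + 1]) / denom
    }
    shifts[s] <- (lag + frac) * df
    # confidence: mean-centered (Pearson) correlation at the best lag --
    # plain normalized correlation of magnitude spectra is high even for
    # pure noise because magnitudes are positive
    idx <- win + lag
    ok <- idx >= 1 & idx <= n
    pear <- suppressWarnings(stats::cor(refw[ok], mags[s, idx[ok]]))
    lowconf[s] <- !is.finite(pear) || pear < confidence_floor
    data[s, 1, ] <- data[s, 1, ] * exp(-1i * 2 * pi * shifts[s] * t)
  }
  out <- series
  out$data <- data
  list(series = fid_series(data, acq, shot_index = series$shot_index),
       shifts_hz = shifts, low_confidence = lowconf)
}

#' Full width at half maximum of a spectral peak
#'
#' Measured on the real part of the (phased) spectrum: the tallest point
#' within `center_ppm +/- window_ppm` defines the peak; the width at half
#' that height is located by linear interpolation between the straddling grid
#' points and returned in Hz.
#'
#' @param spectrum An `mrs_spectrum`.
#' @param center_ppm Peak search center.
#' @param window_ppm Half-width of the search window in ppm.
#' @param mode `"real"` (default) or `"magnitude"`.
#' @return FWHM in Hz.
#' @export
fwhm <- function(spectrum, center_ppm = spectrum$reference_ppm,
                 window_ppm = 0.5, mode = c("real", "magnitude")) {
  mode <- match.arg(mode)
  idx <- ppm_window_idx(spectrum, center_ppm - window_ppm,
                        center_ppm + window_ppm)
  if (!length(idx)) stop("peak window outside the spectral axis", call. = FALSE)
  # work in ascending-Hz order
  hz <- spectrum$hz_axis[idx]
  y <- if (mode == "real") Re(spectrum$values[idx]) else Mod(spectrum$values[idx])
  o <- order(hz)
  hz <- hz[o]; y <- y[o]
  k <- which.max(y)
  ymax <- y[k]
  if (!is.finite(ymax) || ymax <= 0)
    stop("no positive peak inside the window", call. = FALSE)
  half <- ymax / 2
  left <- NA_real_; right <- NA_real_
  if (k >= 2) {
    for (i in k:2) {
      if (y[i - 1] <= half) {
        left <- hz[i - 1] + (hz[i] - hz[i - 1]) * (half - y[i - 1]) / (y[i] - y[i - 1])
        break
      }
    }
  }
  if (k <= length(y) - 1) {
    for (i in k:(length(y) - 1)) {
      if (y[i + 1] <= half) {
        right <- hz[i] + (hz[i + 1] - hz[i]) * (y[i] - half) / (y[i] - y[i + 1])
        break
      }
    }
  }
  if (!is.finite(left) || !is.finite(right))
    stop("no half-maximum crossing inside the window (peak truncated)",
         call. = FALSE)
  right - left
}

#' Spectral signal-to-noise ratio
#'
#' Peak height (real part) within +/- `search_ppm` of `peak_ppm`, divided by
#' the standard deviation of the real part in the signal-free noise window
#' (-3 to -1 ppm).
#'
#' @param spectrum An `mrs_spectrum` covering the noise window.
#' @param peak_ppm Peak position (e.g. 3.027 for creatine, 1.3 for the
#'   fatty-acid methylene peak).
#' @param search_ppm Half-width of the peak search window (default 0.15 ppm).
#' @param noise_window Length-2 ppm bounds of the noise region.
#' @return SNR (numeric). If the noise SD underflows, `Inf` is returned with
#'   attribute `zero_noise = TRUE`.
#' @export
snr <- function(spectrum, peak_ppm, search_ppm = 0.15,
                noise_window = c(-3, -1)) {
  nidx <- ppm_window_idx(spectrum, min(noise_window), max(noise_window))
  if (length(nidx) < 8)
    stop("noise window (-3..-1 ppm) outside the spectral axis", call. = FALSE)
  pidx <- ppm_window_idx(spectrum, peak_ppm - search_ppm, peak_ppm + search_ppm)
  if (!length(pidx)) stop("peak window outside the spectral axis", call. = FALSE)
  height <- max(Re(spectrum$values[pidx]))
  noise_sd <- stats::sd(Re(spectrum$values[nidx]))
  if (!is.finite(noise_sd) || noise_sd < .Machine$double.xmin ||
      noise_sd < 1e-14 * max(abs(height), 1e-300)) {
    out <- Inf
    attr(out, "zero_noise") <- TRUE
    return(out)
  }
  height / noise_sd
}

#' Quality-control exclusion filter
#'
#' Excludes spectra whose water linewidth exceeds `lw_max_hz` or whose
#' analyzed peaks fall below `snr_min`; both rules use strict inequalities,
#' so values exactly at the threshold pass.
#'
#' @param water_lw_hz Water FWHM in Hz.
#' @param peak_snr Named numeric vector of peak SNRs.
#' @param lw_max_hz Linewidth exclusion threshold (default 35 Hz).
#' @param snr_min SNR exclusion threshold (default 5).
#' @return List with `qc_pass` (logical) and `qc_reasons` (character).
#' @export
qc_filter <- function(water_lw_hz, peak_snr, lw_max_hz = 35, snr_min = 5) {
  reasons <- character(0)
  if (is.finite(water_lw_hz) && water_lw_hz > lw_max_hz)
    reasons <- c(reasons, sprintf("linewidth: water FWHM %.1f Hz > %.0f Hz",
                                  water_lw_hz, lw_max_hz))
  low <- peak_snr < snr_min
  if (any(low))
    reasons <- c(reasons,
                 sprintf("snr: %s = %.2f < %.0f",
                         names(peak_snr)[low], peak_snr[low], snr_min))
  list(qc_pass = length(reasons) == 0, qc_reasons = reasons)
}

#' Average the shots of a series
#'
#' @param series Single-channel [fid_series()].
#' @param shots Optional integer subset of shots to average.
#' @return Complex FID vector (the mean over shots).
#' @export
average_shots <- function(series, shots = NULL) {
  if (is.null(shots)) shots <- seq_len(series$acq$n_shots)
  if (!length(shots)) stop("no shots to average", call. = FALSE)
  acc <- rep(0i, series$acq$n_points)
  for (s in shots) acc <- acc + get_fid(series, s)
  acc / length(shots)
}
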