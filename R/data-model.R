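#' Acquisition parameters for a single-voxel MRS scan
#'
#' Bundles the sequence timing and sampling metadata that every processing
#' stage needs: localization sequence, echo/repetition/mixing times, carrier
#' frequency, dwell time, array geometry and the refocusing-pulse bandwidth
#' used by the chemical-shift-displacement calculator.
#'
#' @param sequence Localization sequence, one of `"PRESS"`, `"SLASER"`,
#'   `"STEAM"`.
#' @param te_s Echo time in seconds.
#' @param tr_s Repetition period in seconds (the effective period: when ECG
#'   triggering forces one acquisition every two heartbeats this is 2 RR).
#' @param tm_s Mixing time in seconds; must be 0 unless `sequence = "STEAM"`.
#' @param f0_mhz Transmitter (carrier) frequency in MHz, e.g. 123.2 at 3 T.
#' @param dwell_s Sampling interval of the FID in seconds.
#' @param n_points Complex samples per FID.
#' @param n_channels Receive channels.
#' @param n_shots Acquired averages (shots).
#' @param refocus_bw_hz Bandwidth in Hz of the slice-selective refocusing
#'   pulse (PRESS/sLASER) or the 90 degree pulse (STEAM).
#' @param voxel_mm Numeric length-3 vector of voxel extents in mm.
#' @param water_suppressed Logical; was water suppression played out.
#' @param reference_ppm Chemical shift assigned to the carrier; 4.7 ppm
#'   (water) by default.
#'
#' @return An object of class `acq_params` (a validated list).
#' @examples
#' acq <- acq_params(sequence = "PRESS", te_s = 0.02396, tr_s = 1.1)
#' acq$refocus_bw_hz
#' @export
acq_params <- function(sequence = c("PRESS", "SLASER", "STEAM"),
                       te_s = 0.02396,
                       tr_s = 1.1,
                       tm_s = 0,
                       f0_mhz = 123.2,
                       dwell_s = 4e-4,
                       n_points = 2048,
                       n_channels = 1,
                       n_shots = 1,
                       refocus_bw_hz = 1150,
                       voxel_mm = c(15, 25, 30),
                       water_suppressed = TRUE,
                       reference_ppm = 4.7) {
  sequence <- match.arg(toupper(sequence[1]), c("PRESS", "SLASER", "STEAM"))
  acq <- structure(
    list(sequence = sequence, te_s = as.numeric(te_s), tr_s = as.numeric(tr_s),
         tm_s = as.numeric(tm_s), f0_mhz = as.numeric(f0_mhz),
         dwell_s = as.numeric(dwell_s),
         n_points = as.integer(n_points), n_channels = as.integer(n_channels),
         n_shots = as.integer(n_shots),
         refocus_bw_hz = as.numeric(refocus_bw_hz),
         voxel_mm = as.numeric(voxel_mm),
         water_suppressed = isTRUE(water_suppressed),
         reference_ppm = as.numeric(reference_ppm)),
    class = "acq_params")
  validate_acq_params(acq)
  acq
}

validate_acq_params <- function(acq) {
  stopifnot(inherits(acq, "acq_params"))
  chk <- function(cond, msg) if (!isTRUE(cond)) stop("invalid acq_params: ", msg, call. = FALSE)
  chk(is.numeric(acq$te_s) && acq$te_s >= 0, "te_s must be >= 0")
  chk(is.numeric(acq$tr_s) && acq$tr_s > acq$te_s, "tr_s must be > te_s")
  chk(acq$tm_s == 0 || acq$sequence == "STEAM",
      "tm_s must be 0 unless sequence is STEAM")
  chk(acq$tm_s >= 0, "tm_s must be >= 0")
  chk(acq$f0_mhz > 0, "f0_mhz must be > 0")
  chk(acq$dwell_s > 0, "dwell_s must be > 0")
  chk(acq$n_points >= 2, "n_points must be >= 2")
  chk(acq$n_channels >= 1, "n_channels must be >= 1")
  chk(acq$n_shots >= 1, "n_shots must be >= 1")
  chk(acq$refocus_bw_hz > 0, "refocus_bw_hz must be > 0")
  chk(length(acq$voxel_mm) == 3 && all(acq$voxel_mm > 0),
      "voxel_mm must be three positive extents")
  invisible(acq)
}

#' Multi-shot, multi-channel FID series
#'
#' The raw input of every pipeline stage: a complex array indexed
#' (shot, channel, time) plus its acquisition metadata.
#'
#' @param data Complex array of dimension `(n_shots, n_channels, n_points)`.
#'   A plain complex vector is accepted for a single-shot, single-channel
#'   series.
#' @param acq An [acq_params()] object whose dimensions match `data`.
#' @param shot_index Optional integer heartbeat/average counter per shot;
#'   defaults to `1:n_shots`.
#'
#' @return An object of class `fid_series`.
#' @export
fid_series <- function(data, acq, shot_index = NULL) {
  if (is.null(dim(data))) dim(data) <- c(1L, 1L, length(data))
  if (length(dim(data)) != 3)
    stop("fid_series data must be a (shot, channel, time) array", call. = FALSE)
  validate_acq_params(acq)
  d <- dim(data)
  if (!identical(as.integer(d),
                 c(acq$n_shots, acq$n_channels, acq$n_points)))
    stop(sprintf(
      "fid_series shape mismatch: data is (%d, %d, %d) but acq says (%d, %d, %d)",
      d[1], d[2], d[3], acq$n_shots, acq$n_channels, acq$n_points),
      call. = FALSE)
  if (!all(is.finite(Re(data))) || !all(is.finite(Im(data))))
    stop("fid_series data must be finite", call. = FALSE)
  if (is.null(shot_index)) shot_index <- seq_len(acq$n_shots)
  if (length(shot_index) != acq$n_shots)
    stop("shot_index must have one entry per shot", call. = FALSE)
  structure(list(data = as.complex(data) |> array(d), acq = acq,
                 shot_index = as.integer(shot_index)),
            class = "fid_series")
}

#' @export
print.fid_series <- function(x, ...) {
  cat(sprintf("<fid_series> %d shot(s) x %d channel(s) x %d points | %s TE=%.4gs TR=%.4gs f0=%.4g MHz%s\n",
              x$acq$n_shots, x$acq$n_channels, x$acq$n_points, x$acq$sequence,
              x$acq$te_s, x$acq$tr_s, x$acq$f0_mhz,
              if (x$acq$water_suppressed) " [water-suppressed]" else ""))
  invisible(x)
}

#' @export
print.acq_params <- function(x, ...) {
  cat(sprintf("<acq_params> %s TE=%.4gs TR=%.4gs TM=%.4gs f0=%.4g MHz dwell=%.3gs n=%d\n",
              x$sequence, x$te_s, x$tr_s, x$tm_s, x$f0_mhz, x$dwell_s, x$n_points))
  invisible(x)
}

# time axis of one FID, seconds
time_axis <- function(acq) (seq_len(acq$n_points) - 1) * acq$dwell_s

# signed DFT frequency axis in ascending Hz (fftshift ordering)
freq_axis <- function(n, dwell_s) (seq_len(n) - 1 - floor(n / 2)) / (n * dwell_s)

fft_shift <- function(x) {
  n <- length(x)
  k <- n - floor(n / 2)
  c(x[(k + 1):n], x[1:k])
}

fft_unshift <- function(x) {
  n <- length(x)
  k <- floor(n / 2)
  c(x[(k + 1):n], x[1:k])
}

# extract a single shot/channel FID as a complex vector
get_fid <- function(series, shot = 1, channel = 1) {
  as.complex(series$data[shot, channel, ])
}

#' Convert a ppm difference to Hz
#'
#' @param ppm Chemical shift difference (or absolute shift relative to the
#'   carrier) in ppm.
#' @param f0_mhz Carrier frequency in MHz.
#' @return Frequency in Hz (`ppm * f0_mhz`).
#' @export
ppm_to_hz <- function(ppm, f0_mhz) ppm * f0_mhz

#' Frequency-domain view of an FID
#'
#' Discrete Fourier transform with the NMR ppm axis convention: DFT bin at
#' signed frequency f (Hz) maps to `reference_ppm + f / f0_mhz`, and the axis
#' is reported in descending ppm (left-to-right as a spectrum is drawn).
#'
#' @param fid Complex FID vector.
#' @param acq [acq_params()] supplying dwell time, carrier frequency and
#'   reference ppm. `n_points` may differ from `length(fid)` (e.g. after
#'   zero-filling); the axis adapts to the FID length.
#' @return An object of class `mrs_spectrum` with elements `values`
#'   (complex), `ppm_axis` (descending), `hz_axis`, `f0_mhz`,
#'   `reference_ppm`, `df_hz` (grid step) and `dwell_s`.
#' @examples
#' acq <- acq_params()
#' sp <- to_spectrum(exp(-pi * 10 * time_axis_of(acq)), acq)
#' @export
to_spectrum <- function(fid, acq) {
  n <- length(fid)
  s <- fft_shift(stats::fft(as.complex(fid)))
  f <- freq_axis(n, acq$dwell_s)
  ppm <- acq$reference_ppm + f / acq$f0_mhz
  ord <- rev(seq_len(n))   # descending ppm
  structure(list(values = s[ord], ppm_axis = ppm[ord], hz_axis = f[ord],
                 f0_mhz = acq$f0_mhz, reference_ppm = acq$reference_ppm,
                 df_hz = 1 / (n * acq$dwell_s), dwell_s = acq$dwell_s),
            class = "mrs_spectrum")
}

#' Invert a spectrum back to its FID
#'
#' Exact inverse of [to_spectrum()] (before any apodization), up to DFT
#' round-off.
#'
#' @param spectrum An `mrs_spectrum`.
#' @return Complex FID vector.
#' @export
from_spectrum <- function(spectrum) {
  n <- length(spectrum$values)
  s <- spectrum$values[rev(seq_len(n))]      # back to ascending frequency
  stats::fft(fft_unshift(s), inverse = TRUE) / n
}

#' Public helper: time axis of an acquisition
#' @param acq An [acq_params()] object.
#' @return Numeric vector of sample times in seconds.
#' @export
time_axis_of <- function(acq) time_axis(acq)

#' @export
print.mrs_spectrum <- function(x, ...) {
  cat(sprintf("<mrs_spectrum> %d points | %.2f..%.2f ppm | df=%.3g Hz\n",
              length(x$values), max(x$ppm_axis), min(x$ppm_axis), x$df_hz))
  invisible(x)
}

# indices of a spectrum inside [lo, hi] ppm
ppm_window_idx <- function(spectrum, lo_ppm, hi_ppm) {
  which(spectrum$ppm_axis >= lo_ppm & spectrum$ppm_axis <= hi_ppm)
}
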