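#' Write an FID series to the cmrs binary container
#'
#' Single-file, self-describing layout designed to be portable and trivially
#' inspectable:
#'
#' * bytes 1-8: magic string `"CMRSFID1"`;
#' * a little-endian 32-bit integer giving the byte length of the JSON
#'   header;
#' * the JSON header (UTF-8): every [acq_params()] field, the `shot_index`
#'   vector, the array dimensions and the payload storage note;
#' * the real part of the complex cube as little-endian float64, in R array
#'   (column-major) order;
#' * the imaginary part, same layout.
#'
#' Complex data are stored as paired float arrays to avoid complex-dialect
#' issues across languages; `read_series(write_series(s))` reproduces `s`
#' bit-exactly.
#'
#' @param series A validated [fid_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_series()], [nifti_mrs_metadata()]
#' @export
write_series <- function(series, path) {
  if (!inherits(series, "fid_series"))
    stop("series must be a fid_series", call. = FALSE)
  validate_acq_params(series$acq)
  header <- c(series$acq[setdiff(names(series$acq), NULL)],
              list(shot_index = series$shot_index,
                   dims = dim(series$data),
                   storage = "float64le real then imag, column-major"))
  hjson <- jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA)
  hraw <- charToRaw(as.character(hjson))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("CMRSFID1"), con)
  writeBin(length(hraw), con, size = 4L, endian = "little")
  writeBin(hraw, con)
  writeBin(as.numeric(Re(series$data)), con, size = 8L, endian = "little")
  writeBin(as.numeric(Im(series$data)), con, size = 8L, endian = "little")
  invisible(path)
}

required_acq_fields <- c("sequence", "te_s", "tr_s", "tm_s", "f0_mhz",
                         "dwell_s", "n_points", "n_channels", "n_shots",
                         "refocus_bw_hz", "voxel_mm", "water_suppressed",
                         "reference_ppm")

#' Read an FID series from the cmrs binary container
#'
#' @param path File written by [write_series()] (or conforming to the layout
#'   documented there).
#' @return A validated [fid_series()].
#' @export
read_series <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 8L))
  if (!identical(magic, "CMRSFID1"))
    stop("not a cmrs FID container (bad magic): ", path, call. = FALSE)
  hlen <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  header <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", hlen)))
  missing <- setdiff(required_acq_fields, names(header))
  if (length(missing))
    stop("container header missing metadata field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  dims <- as.integer(header$dims)
  if (length(dims) != 3)
    stop("container header dims must have length 3", call. = FALSE)
  if (!identical(dims,
                 as.integer(c(header$n_shots, header$n_channels, header$n_points))))
    stop(sprintf(
      "container shape error: payload dims (%s) disagree with metadata (n_shots=%d, n_channels=%d, n_points=%d)",
      paste(dims, collapse = ", "),
      header$n_shots, header$n_channels, header$n_points), call. = FALSE)
  n <- prod(dims)
  re <- readBin(con, "numeric", n, size = 8L, endian = "little")
  im <- readBin(con, "numeric", n, size = 8L, endian = "little")
  if (length(re) < n || length(im) < n)
    stop("container shape error: truncated payload", call. = FALSE)
  acq <- acq_params(sequence = header$sequence, te_s = header$te_s,
                    tr_s = header$tr_s, tm_s = header$tm_s,
                    f0_mhz = header$f0_mhz, dwell_s = header$dwell_s,
                    n_points = header$n_points, n_channels = header$n_channels,
                    n_shots = header$n_shots,
                    refocus_bw_hz = header$refocus_bw_hz,
                    voxel_mm = header$voxel_mm,
                    water_suppressed = header$water_suppressed,
                    reference_ppm = header$reference_ppm)
  fid_series(array(complex(real = re, imaginary = im), dims), acq,
             shot_index = header$shot_index)
}

#' NIfTI-MRS-style metadata mapping (interoperability stub)
#'
#' Translates [acq_params()] fields to/from the metadata naming used by the
#' NIfTI-MRS convention (SpectrometerFrequency in MHz, EchoTime and
#' RepetitionTime in seconds, dwell time, ...). Only the name mapping is
#' provided; full NIfTI-MRS file I/O is out of scope.
#'
#' @param acq An [acq_params()] object.
#' @return Named list with NIfTI-MRS-style keys.
#' @export
nifti_mrs_metadata <- function(acq) {
  validate_acq_params(acq)
  list(SpectrometerFrequency = acq$f0_mhz,
       ResonantNucleus = "1H",
       EchoTime = acq$te_s,
       RepetitionTime = acq$tr_s,
       MixingTime = acq$tm_s,
       DwellTime = acq$dwell_s,
       NumberOfSpectralPoints = acq$n_points,
       ReceiveCoilActiveElements = acq$n_channels,
       NumberOfTransients = acq$n_shots,
       PulseSequenceType = acq$sequence,
       WaterSuppressed = acq$water_suppressed,
       VoxelExtents_mm = acq$voxel_mm,
       ChemicalShiftReference_ppm = acq$reference_ppm)
}

#' @rdname nifti_mrs_metadata
#' @param meta Named list as produced by [nifti_mrs_metadata()].
#' @export
from_nifti_mrs_metadata <- function(meta) {
  acq_params(sequence = meta$PulseSequenceType,
             te_s = meta$EchoTime, tr_s = meta$RepetitionTime,
             tm_s = if (is.null(meta$MixingTime)) 0 else meta$MixingTime,
             f0_mhz = meta$SpectrometerFrequency,
             dwell_s = meta$DwellTime,
             n_points = meta$NumberOfSpectralPoints,
             n_channels = meta$ReceiveCoilActiveElements,
             n_shots = meta$NumberOfTransients,
             voxel_mm = meta$VoxelExtents_mm,
             water_suppressed = meta$WaterSuppressed,
             reference_ppm = meta$ChemicalShiftReference_ppm)
}
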