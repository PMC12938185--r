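# Broadband conditioning, QC segment selection, narrowband decomposition.

#' Shipped narrowband definitions
#'
#' The four canonical frequency bands: delta (1-4 Hz), theta (4-8 Hz),
#' alpha (8-13 Hz), beta (13-30 Hz).
#'
#' @param names optional subset, e.g. `c("delta", "alpha")`.
#' @return named list of `c(low, high)` pairs in Hz.
#' @export
band_specs <- function(names = NULL) {
  bands <- list(delta = c(1, 4), theta = c(4, 8),
                alpha = c(8, 13), beta = c(13, 30))
  if (is.null(names)) return(bands)
  miss <- setdiff(names, names(bands))
  if (length(miss)) stop("unknown band(s): ", paste(miss, collapse = ", "))
  bands[names]
}

band_prefix <- function(band_name) {
  paste0(toupper(substring(band_name, 1, 1)), substring(band_name, 2))
}

#' Broadband conditioning of a raw recording
#'
#' Zero-phase (forward-backward) FIR band-pass between `low` and `high` Hz,
#' Fourier resampling to `target_rate` (the band-pass provides anti-alias
#' protection), and average re-referencing. One filter length at each end
#' (rescaled to the output rate) is flagged as edge-contaminated.
#'
#' @param recording an `eeg_recording`.
#' @param low,high band edges in Hz (defaults 1 and 40).
#' @param target_rate output sampling rate in Hz (default 256); the output
#'   has `round(n_in * target_rate / rate_in)` samples.
#' @return the conditioned `eeg_recording`.
#' @export
broadband_condition <- function(recording, low = 1, high = 40,
                                target_rate = 256) {
  fs <- recording$sampling_rate
  if (high >= fs / 2) stop("upper band edge must be below the input Nyquist")
  b <- design_bandpass_fir(low, high, fs)
  filt <- zero_phase_filter_mat(b, recording$data)
  n_out <- round(ncol(filt) * target_rate / fs)
  out <- t(apply(filt, 1L, fft_resample, n_out = n_out))
  out <- average_reference(out)
  eeg_recording(out, target_rate, recording$montage,
                recording$subject_id, recording$group,
                edge = ceiling(length(b) * target_rate / fs))
}

#' Select the first artifact-free segment of fixed length
#'
#' Scans sample-by-sample from the start and returns the earliest window of
#' `window` seconds in which every channel stays within `+-threshold`
#' microvolts. Exclusion (no clean window) is a documented outcome, not an
#' error: `NULL` is returned.
#'
#' @param recording an `eeg_recording` of at least `window` seconds.
#' @param window window length in seconds (default 10).
#' @param threshold absolute amplitude bound in microvolts (default 100).
#' @return the cropped `eeg_recording` with attribute `qc_start` (1-based
#'   first sample of the window), or `NULL` if the trial is excluded.
#' @export
select_qc_segment <- function(recording, window = 10, threshold = 100) {
  n <- ncol(recording$data)
  win <- round(window * recording$sampling_rate)
  if (n < win) stop("recording shorter than the QC window")
  ok <- colSums(abs(recording$data) > threshold) == 0L
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values & r$lengths >= win)
  if (!length(cand)) return(NULL)
  s <- starts[cand[1L]]
  out <- recording
  out$data <- recording$data[, s:(s + win - 1L), drop = FALSE]
  attr(out, "qc_start") <- s
  out
}

#' Narrowband zero-phase filtering
#'
#' Zero-phase FIR band-pass into one of the canonical bands (or any custom
#' band), followed by average re-referencing. One kernel length at each end
#' is flagged as edge-contaminated and excluded from GFP peak picking.
#'
#' @param recording an `eeg_recording`.
#' @param band a band name (see [band_specs()]) or numeric `c(low, high)`.
#' @return the filtered `eeg_recording` with `band` attached.
#' @export
narrowband_filter <- function(recording, band) {
  if (is.character(band)) {
    band_name <- band
    band <- band_specs(band)[[1]]
  } else band_name <- sprintf("%g-%gHz", band[1], band[2])
  fs <- recording$sampling_rate
  if (band[2] >= fs / 2) stop("band must lie below the Nyquist frequency")
  b <- design_bandpass_fir(band[1], band[2], fs)
  out <- zero_phase_filter_mat(b, recording$data)
  out <- average_reference(out)
  rec <- eeg_recording(out, fs, recording$montage, recording$subject_id,
                       recording$group, edge = length(b))
  rec$band <- band_name
  rec
}
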