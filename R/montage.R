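#' Construct a quasi-uniform scalp montage on the unit sphere
#'
#' Places `n_channels` electrodes on a spherical cap (upper head surface)
#' using a Fibonacci spiral, giving an approximately uniform high-density
#' layout. Coordinates follow the convention +x right, +y anterior, +z up.
#'
#' @param n_channels number of electrodes (>= 8); default 52, a typical
#'   retained-channel count for a 64-channel net after discarding poor
#'   peripheral sites.
#' @param cap_angle polar angle (degrees from vertex) covered by the cap.
#' @return object of class `montage`: data.frame with columns
#'   `channel`, `x`, `y`, `z` (unit-norm positions).
#' @export
make_montage <- function(n_channels = 52, cap_angle = 110) {
  if (n_channels < 8) stop("montage too small: need at least 8 channels")
  i <- seq_len(n_channels)
  golden <- pi * (3 - sqrt(5))
  zmin <- cos(cap_angle * pi / 180)
  z <- 1 - (i - 0.5) / n_channels * (1 - zmin)
  r <- sqrt(pmax(0, 1 - z^2))
  th <- golden * i
  m <- data.frame(channel = sprintf("E%02d", i),
                  x = r * cos(th), y = r * sin(th), z = z,
                  stringsAsFactors = FALSE)
  class(m) <- c("montage", "data.frame")
  validate_montage(m)
  m
}

#' @keywords internal
validate_montage <- function(m, min_channels = 2) {
  stopifnot(is.data.frame(m), all(c("channel", "x", "y", "z") %in% names(m)))
  if (anyDuplicated(m$channel)) stop("montage channel ids must be unique")
  if (nrow(m) < min_channels)
    stop("montage too small: need at least ", min_channels, " channels")
  nrm <- sqrt(m$x^2 + m$y^2 + m$z^2)
  if (any(abs(nrm - 1) > 1e-9)) stop("montage positions must lie on the unit sphere")
  invisible(m)
}

montage_positions <- function(m) as.matrix(m[, c("x", "y", "z")])

#' Read / write channel-location tables
#'
#' Plain CSV with columns `channel,x,y,z` (unit-sphere coordinates).
#' @param path file path.
#' @export
read_montage_csv <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(m) <- c("montage", "data.frame")
  validate_montage(m)
  m
}

#' @rdname read_montage_csv
#' @param montage a `montage` object.
#' @export
write_montage_csv <- function(montage, path) {
  utils::write.csv(as.data.frame(montage), path, row.names = FALSE)
  invisible(path)
}

#' Create an EEG recording container
#'
#' @param data numeric channel x sample matrix (microvolts).
#' @param sampling_rate sampling rate in Hz.
#' @param montage a `montage` matching `nrow(data)`.
#' @param subject_id subject identifier.
#' @param group group label (`"HC"`, `"MD"`, `"SV"` or `"synthetic"`).
#' @param edge number of samples at each end contaminated by filter
#'   transients (excluded from GFP peak picking).
#' @return object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, sampling_rate, montage,
                          subject_id = "S01", group = "synthetic",
                          edge = 0L) {
  data <- as.matrix(data)
  if (!all(is.finite(data))) stop("recording contains non-finite values")
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  validate_montage(montage)
  if (nrow(data) != nrow(montage))
    stop("channel count does not match montage")
  structure(list(data = data, sampling_rate = sampling_rate,
                 montage = montage, subject_id = subject_id,
                 group = group, edge = as.integer(edge)),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s [%s]: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$group, nrow(x$data), ncol(x$data),
              x$sampling_rate, ncol(x$data) / x$sampling_rate))
  invisible(x)
}

#' Read / write a recording as a plain CSV matrix
#'
#' Rows are channels (first column holds the channel id), columns samples.
#' @param path file path.
#' @param montage montage to attach (channel ids must match).
#' @param sampling_rate sampling rate in Hz of the stored data.
#' @inheritParams eeg_recording
#' @export
read_recording_csv <- function(path, montage, sampling_rate,
                               subject_id = "S01", group = "synthetic") {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- tab[[1]]
  dat <- as.matrix(tab[, -1, drop = FALSE])
  if (!identical(ids, montage$channel))
    stop("channel ids in file do not match montage")
  eeg_recording(dat, sampling_rate, montage, subject_id, group)
}

#' @rdname read_recording_csv
#' @param recording an `eeg_recording`.
#' @export
write_recording_csv <- function(recording, path) {
  tab <- data.frame(channel = recording$montage$channel,
                    recording$data, check.names = FALSE)
  names(tab) <- c("channel", paste0("t", seq_len(ncol(recording$data))))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
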