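# Global field power and GFP-peak topography extraction.

#' Global field power
#'
#' The spatial standard deviation (population form) of the
#' average-referenced scalp map at each sample:
#' GFP(t) = sqrt(mean_c (v_c(t) - vbar(t))^2).
#'
#' @param recording an `eeg_recording` with at least two channels.
#' @return object of class `gfp_series`: list with `values` (nonnegative,
#'   one per sample) and `sampling_rate`.
#' @export
gfp <- function(recording) {
  x <- recording$data
  if (nrow(x) < 2) stop("GFP needs at least two channels")
  centered <- average_reference(x)
  structure(list(values = sqrt(colMeans(centered^2)),
                 sampling_rate = recording$sampling_rate),
            class = "gfp_series")
}

# Strict local maxima; plateaus contribute their leftmost sample.
find_local_maxima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  s <- sign(diff(v))
  nzidx <- which(s != 0)
  if (length(nzidx) < 2) return(integer(0))
  sv <- s[nzidx]
  # a rise whose next nonzero step is a fall; the sample after the rise is
  # the peak (= leftmost sample of a plateau)
  j <- which(sv[-length(sv)] == 1 & sv[-1] == -1)
  nzidx[j] + 1L
}

#' Extract GFP-peak topographies
#'
#' Finds all strict local maxima of the GFP series (plateaus: leftmost
#' sample), greedily enforces a minimum peak distance (higher peaks win),
#' drops peaks inside the filter edge-taper zones, then uniformly samples
#' `n_select` peaks without replacement. If fewer peaks are available, all
#' are returned with a warning.
#'
#' @param recording an `eeg_recording` (its `edge` field defines the
#'   excluded taper zones).
#' @param gfp_series optional precomputed [gfp()] result.
#' @param min_distance minimum index gap between retained peaks (samples).
#' @param n_select number of peak maps to sample per recording.
#' @param seed integer seed for the subsampling.
#' @return object of class `peak_maps`: `maps` (n_peaks x n_channels,
#'   average-referenced), `peak_indices` (strictly increasing),
#'   `subject_id`, `band`.
#' @export
pick_peaks <- function(recording, gfp_series = NULL, min_distance = 10,
                       n_select = 1000, seed = NULL) {
  if (is.null(gfp_series)) gfp_series <- gfp(recording)
  v <- gfp_series$values
  if (!length(v)) stop("empty GFP series")
  peaks <- find_local_maxima(v)
  edge <- recording$edge %||% 0L
  if (edge > 0L)
    peaks <- peaks[peaks > edge & peaks <= length(v) - edge]
  if (length(peaks)) {
    # greedy: taller peaks claim a +-(min_distance - 1) exclusion zone
    ord <- order(-v[peaks], peaks)
    blocked <- rep(FALSE, length(v))
    keep <- logical(length(peaks))
    for (j in ord) {
      p <- peaks[j]
      if (!blocked[p]) {
        keep[j] <- TRUE
        lo <- max(1L, p - min_distance + 1L)
        hi <- min(length(v), p + min_distance - 1L)
        blocked[lo:hi] <- TRUE
      }
    }
    peaks <- sort(peaks[keep])
  }
  if (length(peaks) > n_select) {
    peaks <- with_seed(seed, sort(sample(peaks, n_select)))
  } else if (length(peaks) < n_select) {
    warning(sprintf("only %d GFP peaks available (requested %d); using all",
                    length(peaks), n_select))
  }
  maps <- t(average_reference(recording$data)[, peaks, drop = FALSE])
  structure(list(maps = maps, peak_indices = peaks,
                 subject_id = recording$subject_id,
                 band = recording$band %||% NULL),
            class = "peak_maps")
}

#' Pool peak maps across subjects
#'
#' Row-binds per-subject `peak_maps` (each already capped at its
#' `n_select`) for group-level clustering.
#'
#' @param peak_list list of `peak_maps`.
#' @return a `peak_maps` object with a `subject` vector marking provenance.
#' @export
pool_peak_maps <- function(peak_list) {
  maps <- do.call(rbind, lapply(peak_list, `[[`, "maps"))
  subj <- rep(vapply(peak_list, `[[`, character(1), "subject_id"),
              vapply(peak_list, function(p) nrow(p$maps), integer(1)))
  structure(list(maps = maps, peak_indices = NULL, subject_id = NULL,
                 subject = subj, band = peak_list[[1]]$band),
            class = "peak_maps")
}
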