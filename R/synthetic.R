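# Semi-Markov synthetic EEG with planted microstate structure.

#' Synthetic recording configuration
#'
#' Bundles the generative parameters of one synthetic resting-state
#' recording: a semi-Markov state sequence (gamma dwell times, row-stochastic
#' jump matrix with zero diagonal), a band-limited amplitude envelope, and
#' spatially smooth sensor noise.
#'
#' @param n_channels electrodes (default 52).
#' @param sampling_rate Hz (default 256, the working rate after broadband
#'   conditioning).
#' @param duration seconds.
#' @param n_states number of planted microstate classes.
#' @param transition_matrix n_states x n_states row-stochastic matrix with
#'   zero diagonal; default cycles-free uniform off-diagonal.
#' @param dwell_mean mean dwell time in ms (default 80, the center of the
#'   canonical 60-120 ms quasi-stability range).
#' @param dwell_shape gamma shape of the dwell-time law (default 4,
#'   right-skewed).
#' @param band numeric length-2 envelope band in Hz (default alpha, 8-13,
#'   which gives densely spaced GFP peaks).
#' @param snr ratio of state-signal RMS to noise RMS; `Inf` for noiseless.
#' @param seed integer seed.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_channels = 52, sampling_rate = 256,
                             duration = 60, n_states = 4,
                             transition_matrix = NULL,
                             dwell_mean = 80, dwell_shape = 4,
                             band = c(8, 13), snr = 5, seed = NULL) {
  if (is.null(transition_matrix)) {
    transition_matrix <- matrix(1 / (n_states - 1), n_states, n_states)
    diag(transition_matrix) <- 0
  }
  cfg <- structure(list(n_channels = n_channels, sampling_rate = sampling_rate,
                        duration = duration, n_states = n_states,
                        transition_matrix = transition_matrix,
                        dwell_mean = dwell_mean, dwell_shape = dwell_shape,
                        band = band, snr = snr, seed = seed),
                   class = "synthetic_config")
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  tm <- cfg$transition_matrix
  if (!is.matrix(tm) || nrow(tm) != cfg$n_states || ncol(tm) != cfg$n_states)
    stop("transition_matrix must be n_states x n_states")
  if (any(abs(diag(tm)) > 1e-9)) stop("transition_matrix diagonal must be zero")
  if (any(tm < 0) || any(abs(rowSums(tm) - 1) > 1e-9))
    stop("transition_matrix rows must be nonnegative and sum to 1")
  if (cfg$dwell_mean <= 0) stop("dwell_mean must be positive")
  if (cfg$snr <= 0) stop("snr must be positive")
  if (!(cfg$band[1] > 0 && cfg$band[1] < cfg$band[2] &&
        cfg$band[2] < cfg$sampling_rate / 2))
    stop("band must satisfy 0 < low < high < Nyquist")
  invisible(cfg)
}

#' Sample a semi-Markov microstate sequence
#'
#' Segments alternate state (consecutive segments always differ): each
#' segment's state is drawn from the transition row of its predecessor, and
#' its dwell time is gamma(shape, mean) in ms, floored at one sample.
#'
#' @param config a `synthetic_config`.
#' @param seed overrides `config$seed` when given.
#' @return list with `states` (per-sample state index, length
#'   `duration * sampling_rate`), `segment_states`, `segment_lengths`
#'   (in samples).
#' @export
sample_state_sequence <- function(config, seed = config$seed) {
  validate_synthetic_config(config)
  n_total <- round(config$duration * config$sampling_rate)
  rate <- config$sampling_rate
  with_seed(seed, {
    seg_states <- integer(0); seg_lens <- integer(0)
    s <- sample.int(config$n_states, 1L)
    filled <- 0L
    while (filled < n_total) {
      dwell_ms <- stats::rgamma(1L, shape = config$dwell_shape,
                                scale = config$dwell_mean / config$dwell_shape)
      len <- max(1L, round(dwell_ms / 1000 * rate))
      seg_states <- c(seg_states, s)
      seg_lens <- c(seg_lens, len)
      filled <- filled + len
      s <- sample.int(config$n_states, 1L, prob = config$transition_matrix[s, ])
    }
    seg_lens[length(seg_lens)] <- seg_lens[length(seg_lens)] - (filled - n_total)
    states <- rep.int(seg_states, seg_lens)
    list(states = states, segment_states = seg_states,
         segment_lengths = seg_lens)
  })
}

# Band-limited unit-variance process, rectified: the amplitude envelope.
band_envelope <- function(n, band, rate) {
  b <- design_bandpass_fir(band[1], band[2], rate)
  x <- stats::rnorm(n + 6L * length(b))
  y <- fft_fir(b, x)[(3L * length(b) + 1L):(3L * length(b) + n)]
  abs(y / stats::sd(y))
}

# Spatially smooth sensor noise: white channel noise mixed through a
# Gaussian spatial kernel over electrode distances.
smooth_noise <- function(montage, n, spatial_scale = 0.5) {
  pos <- montage_positions(montage)
  D2 <- as.matrix(stats::dist(pos))^2
  Kmix <- exp(-D2 / (2 * spatial_scale^2))
  Kmix %*% matrix(stats::rnorm(nrow(pos) * n), nrow(pos), n)
}

#' Synthesize a multichannel EEG recording from planted microstates
#'
#' signal(t) = envelope(t) * template\[state(t)\] + noise(t), where the
#' envelope is the rectified magnitude of a band-limited unit-variance
#' process and the noise is spatially smooth Gaussian scaled so that
#' state-signal RMS / noise RMS equals `config$snr`. The output is
#' average-referenced.
#'
#' @param config a `synthetic_config`.
#' @param montage montage with `config$n_channels` rows (default generated).
#' @param templates n_states x n_channels matrix (default
#'   [make_templates()] on the montage).
#' @param sequence optional precomputed [sample_state_sequence()] result.
#' @param subject_id,group passed to the recording.
#' @param keep_components store the noiseless signal and the noise as
#'   attributes (for SNR diagnostics).
#' @param seed overrides `config$seed`.
#' @return an `eeg_recording`; the planted truth is attached as attribute
#'   `truth` (list: templates, state_sequence, segment list,
#'   transition_matrix, envelope).
#' @export
synthesize_eeg <- function(config, montage = NULL, templates = NULL,
                           sequence = NULL, subject_id = "S01",
                           group = "synthetic", keep_components = FALSE,
                           seed = config$seed) {
  validate_synthetic_config(config)
  if (is.null(montage)) montage <- make_montage(config$n_channels)
  seeds <- split_seed(seed, 4L)
  if (is.null(templates))
    templates <- make_templates(montage, config$n_states, seed = seeds[[1]])
  templates <- normalize_maps(as.matrix(templates))
  if (ncol(templates) != nrow(montage)) stop("template/montage dimension mismatch")
  if (is.null(sequence)) sequence <- sample_state_sequence(config, seed = seeds[[2]])
  n <- length(sequence$states)
  env <- with_seed(seeds[[3]], band_envelope(n, config$band, config$sampling_rate))
  sig <- t(templates[sequence$states, , drop = FALSE]) * rep(env, each = nrow(montage))
  if (is.finite(config$snr)) {
    noise <- with_seed(seeds[[4]], smooth_noise(montage, n))
    noise <- noise * (sqrt(mean(sig^2)) / sqrt(mean(noise^2)) / config$snr)
  } else {
    noise <- 0
  }
  dat <- average_reference(sig + noise)
  rec <- eeg_recording(dat, config$sampling_rate, montage, subject_id, group)
  attr(rec, "truth") <- list(templates = templates,
                             state_sequence = sequence$states,
                             segment_states = sequence$segment_states,
                             segment_lengths = sequence$segment_lengths,
                             transition_matrix = config$transition_matrix,
                             envelope = env)
  if (keep_components) {
    attr(rec, "signal") <- sig
    attr(rec, "noise") <- noise
  }
  rec
}

# Dirichlet row sample with given mean row (zero diagonal) and concentration.
rdirichlet_row <- function(mean_row, concentration) {
  alpha <- mean_row * concentration
  g <- vapply(alpha, function(a) if (a <= 0) 0 else stats::rgamma(1L, a), numeric(1))
  if (sum(g) <= 0) return(mean_row)
  g / sum(g)
}

# Concentration that yields the target SD for an entry with mean m:
# Var = m (1 - m) / (conc + 1).
dirichlet_concentration <- function(m, sd) m * (1 - m) / sd^2 - 1

#' Default group specification for the planted severity contrast
#'
#' The planted effect lives in the C->B transition entry: moderate (MD)
#' subjects center at 0.383 (SD 0.104), severe (SV) at 0.162 (SD 0.040);
#' remaining off-diagonal mass in the C row is split evenly, other rows are
#' uniform. Clinical couplings: VAS decreases with the C->B entry
#' (target Spearman magnitude 0.66), ABC increases with it (target 0.69).
#'
#' @return named list of per-group specs usable by [make_cohort()].
#' @export
default_group_specs <- function() {
  base_row <- function(cb) {
    m <- matrix(1 / 3, 4, 4); diag(m) <- 0
    m[3, ] <- c((1 - cb) / 2, cb, 0, (1 - cb) / 2)
    m
  }
  list(
    HC = list(transition_mean = {m <- matrix(1 / 3, 4, 4); diag(m) <- 0; m},
              row_concentration = rep(50, 4)),
    MD = list(transition_mean = base_row(0.383),
              row_concentration = c(50, 50, dirichlet_concentration(0.383, 0.104), 50)),
    SV = list(transition_mean = base_row(0.162),
              row_concentration = c(50, 50, dirichlet_concentration(0.162, 0.040), 50))
  )
}

#' Simulate a patient cohort with planted group differences
#'
#' Per subject: draws a transition matrix (off-diagonal rows Dirichlet-
#' perturbed around the group mean rows), synthesizes EEG, and emits
#' clinical scores as monotone functions of the planted C->B transition
#' entry plus Gaussian noise calibrated to a requested Spearman magnitude.
#'
#' @param n_per_group named integer vector, e.g. `c(MD = 31, SV = 19)`.
#' @param group_specs per-group list (see [default_group_specs()]); each
#'   element needs `transition_mean` (row-stochastic, zero diagonal) and
#'   `row_concentration` (length n_states).
#' @param config base `synthetic_config` (transition matrix is overridden
#'   per subject).
#' @param vas_rho,abc_rho target Spearman correlations between the planted
#'   C->B entry and the VAS / ABC scores (sign included; magnitude 1 with
#'   `coupling_noise = 0`).
#' @param coupling_noise multiplier on the calibrated score noise; 0 gives
#'   exact monotone coupling.
#' @param seed master seed; all per-subject randomness derives from it.
#' @return list with `recordings` (list of `eeg_recording`), `clinical`
#'   (data.frame subject_id, group, DHI, VAS, ABC), `truth` (list:
#'   templates, per-subject transition matrices, state sequences).
#' @export
make_cohort <- function(n_per_group = c(MD = 31, SV = 19),
                        group_specs = default_group_specs(),
                        config = synthetic_config(),
                        vas_rho = -0.66, abc_rho = 0.69,
                        coupling_noise = 1, seed = NULL) {
  groups <- names(n_per_group)
  if (is.null(groups) || !all(groups %in% names(group_specs)))
    stop("n_per_group must be named with groups present in group_specs")
  for (g in groups) {
    sp <- group_specs[[g]]
    tm <- sp$transition_mean
    if (any(abs(rowSums(tm) - 1) > 1e-9) || any(tm < 0) || any(diag(tm) != 0))
      stop(sprintf("degenerate group spec for %s: rows must be stochastic with zero diagonal", g))
  }
  n_total <- sum(n_per_group)
  seeds <- split_seed(seed, n_total + 2L)
  montage <- make_montage(config$n_channels)
  templates <- make_templates(montage, config$n_states, seed = seeds[[n_total + 1L]])

  recordings <- vector("list", n_total)
  tms <- vector("list", n_total)
  seqs <- vector("list", n_total)
  grp <- character(n_total); sid <- character(n_total)
  i <- 0L
  for (g in groups) {
    sp <- group_specs[[g]]
    for (j in seq_len(n_per_group[[g]])) {
      i <- i + 1L
      sid[i] <- sprintf("%s%02d", g, j); grp[i] <- g
      subj_seeds <- split_seed(seeds[[i]], 2L)
      tm <- with_seed(subj_seeds[[1]], {
        t(vapply(seq_len(config$n_states), function(r)
          rdirichlet_row(sp$transition_mean[r, ], sp$row_concentration[r]),
          numeric(config$n_states)))
      })
      cfg_i <- config; cfg_i$transition_matrix <- tm; cfg_i$seed <- NULL
      rec <- synthesize_eeg(cfg_i, montage = montage, templates = templates,
                            subject_id = sid[i], group = g,
                            seed = subj_seeds[[2]])
      recordings[[i]] <- rec
      tms[[i]] <- tm
      seqs[[i]] <- attr(rec, "truth")$state_sequence
    }
  }

  cb <- vapply(tms, function(m) m[3, 2], numeric(1))   # planted C->B entry
  z <- (cb - mean(cb)) / stats::sd(cb)
  # Pearson(z, z + e) = 1/sqrt(1 + var(e)); Spearman tracks it closely here.
  noise_sd <- function(rho) coupling_noise * sqrt(1 / rho^2 - 1)
  clinical <- with_seed(seeds[[n_total + 2L]], {
    vas_lin <- sign(vas_rho) * z + stats::rnorm(n_total, 0, noise_sd(vas_rho))
    abc_lin <- sign(abc_rho) * z + stats::rnorm(n_total, 0, noise_sd(abc_rho))
    dhi <- numeric(n_total)
    for (g in groups) {
      idx <- grp == g
      dhi[idx] <- switch(g,
                         HC = stats::runif(sum(idx), 0, 14),
                         MD = stats::runif(sum(idx), 20, 60),
                         SV = stats::runif(sum(idx), 61, 100),
                         stats::runif(sum(idx), 0, 100))
    }
    data.frame(subject_id = sid, group = grp,
               DHI = round(dhi, 1),
               VAS = 5 + 2 * vas_lin,
               ABC = 60 + 15 * abc_lin,
               stringsAsFactors = FALSE)
  })
  list(recordings = recordings, clinical = clinical,
       truth = list(templates = templates, transition_matrices = tms,
                    state_sequences = seqs, planted_entry = cb))
}
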