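# Shared fixtures, built in code at test time.

fixture_montage <- function(n = 16) make_montage(n)

# A recording whose channels share one waveform through random spatial
# gains (survives average referencing).
waveform_recording <- function(wave, rate, n_channels = 8, seed = 1,
                               montage = NULL) {
  montage <- montage %||% make_montage(n_channels)
  gains <- with_seed_test(seed, stats::rnorm(nrow(montage)))
  eeg_recording(outer(gains, wave), rate, montage)
}

# local seed isolation for helpers (mirror of the package-internal helper)
with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Peak maps drawn exactly from templates with white channel noise:
# v = +-a * T[k] + noise, noise scaled to the requested map-level SNR.
planted_peak_maps <- function(templates, n = 1000, snr = 5, seed = 1) {
  with_seed_test(seed, {
    C <- ncol(templates)
    k <- sample(nrow(templates), n, replace = TRUE)
    a <- abs(stats::rnorm(n)) + 0.2
    maps <- templates[k, ] * a * sample(c(-1, 1), n, replace = TRUE)
    if (is.finite(snr))
      maps <- maps + matrix(stats::rnorm(n * C), n, C) * (sqrt(mean(a^2) / C) / snr)
    list(maps = maps, states = k, amplitudes = a)
  })
}

# Segmentation object built directly from a label sequence (correlations
# default to one-hot so smoothing decisions are deterministic).
manual_segmentation <- function(labels, rate = 256, K = 4, corr = NULL) {
  if (is.null(corr)) {
    corr <- matrix(0.1, length(labels), K)
    corr[cbind(seq_along(labels), labels)] <- 0.9
  }
  structure(list(labels = labels,
                 fit = corr[cbind(seq_along(labels), labels)],
                 corr = corr, sampling_rate = rate, band = NULL,
                 class_names = LETTERS[seq_len(K)], flagged = integer(0)),
            class = "segmentation")
}

# Synthetic per-subject feature vectors over all four bands (values
# arbitrary but named by the full grammar), for feature-table tests.
fake_feature_vector <- function(seed = 1, tp_matrices = NULL) {
  bands <- c("Delta", "Theta", "Alpha", "Beta")
  with_seed_test(seed, {
    out <- c()
    for (b in bands) {
      for (code in c("MD", "COV", "MO", "GEV"))
        for (s in LETTERS[1:4])
          out[paste0(b, "_", code, "_", s)] <- stats::runif(1)
      tp <- if (!is.null(tp_matrices)) tp_matrices[[tolower(b)]] else
        matrix(stats::runif(16), 4, 4)
      for (i in 1:4) for (j in 1:4) if (i != j)
        out[paste0(b, "_TP_", LETTERS[i], "-", LETTERS[j])] <- tp[i, j]
    }
    out
  })
}
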