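# Broadband conditioning, QC segment selection, narrowband filtering.

rms <- function(x) sqrt(mean(x^2))

# exclude edge-flagged samples when judging filter response
valid_cols <- function(rec) {
  n <- ncol(rec$data)
  (rec$edge + 1L):(n - rec$edge)
}

test_that("shipped band definitions match the canonical delta-beta split", {
  b <- band_specs()
  expect_equal(b$delta, c(1, 4))
  expect_equal(b$theta, c(4, 8))
  expect_equal(b$alpha, c(8, 13))
  expect_equal(b$beta, c(13, 30))
  expect_error(band_specs("gamma"), "unknown band")
})

test_that("broadband conditioning stops 50 Hz, passes 10 Hz with zero phase, resamples to 256 Hz", {
  fs <- 1000; t <- seq_len(10 * fs) / fs
  rec50 <- waveform_recording(sin(2 * pi * 50 * t), fs, seed = 1)
  out50 <- broadband_condition(rec50)
  expect_equal(out50$sampling_rate, 256)
  expect_equal(ncol(out50$data), round(10 * fs * 256 / 1000))
  v <- valid_cols(out50)
  in_rms <- rms(rec50$data - colMeans(rec50$data)[col(rec50$data)])
  expect_lt(rms(out50$data[, v]) / in_rms, 0.01)

  rec10 <- waveform_recording(sin(2 * pi * 10 * t), fs, seed = 1)
  out10 <- broadband_condition(rec10)
  v <- valid_cols(out10)
  in_rms <- rms(rec10$data - colMeans(rec10$data)[col(rec10$data)])
  expect_lt(abs(rms(out10$data[, v]) / in_rms - 1), 0.05)
  # zero phase: mid-recording output aligns with the ideally resampled input
  ideal <- sin(2 * pi * 10 * ((seq_len(ncol(out10$data)) - 1) / 256 + 1 / fs))
  mid <- v[v > 800 & v < 1500]
  cc <- cor(out10$data[1, mid], ideal[mid])
  expect_gt(abs(cc), 0.9999)
})

test_that("conditioned output is average-referenced", {
  fs <- 1000; t <- seq_len(15 * fs) / fs
  rec <- waveform_recording(sin(2 * pi * 7 * t), fs, seed = 3)
  out <- broadband_condition(rec)
  expect_lt(max(abs(colSums(out$data))), 1e-6)
})

test_that("too-short recordings are rejected with an explicit message", {
  rec <- waveform_recording(rnorm(500), 1000, seed = 2)
  expect_error(broadband_condition(rec), "too short")
})

# brute-force QC oracle: earliest window where every sample is in bounds
qc_oracle <- function(data, win, thr) {
  ok <- colSums(abs(data) > thr) == 0
  n <- length(ok)
  for (s in seq_len(n - win + 1)) {
    if (all(ok[s:(s + win - 1)])) return(s)
  }
  NULL
}

test_that("QC selection returns the earliest clean window", {
  mont <- make_montage(8)
  rate <- 100
  zero <- eeg_recording(matrix(0, 8, 20 * rate), rate, mont)
  out <- select_qc_segment(zero, window = 10, threshold = 100)
  expect_equal(attr(out, "qc_start"), 1L)
  expect_equal(ncol(out$data), 10 * rate)

  # +150 uV spike at t = 2 s only
  spiky <- matrix(0, 8, 20 * rate)
  spiky[3, 2 * rate] <- 150
  rec <- eeg_recording(spiky, rate, mont)
  out <- select_qc_segment(rec, 10, 100)
  expect_equal(attr(out, "qc_start"), 2L * rate + 1L)
  expect_identical(attr(out, "qc_start"), qc_oracle(spiky, 10 * rate, 100))

  # a spike every 5 s: no clean 10 s window can exist
  bad <- matrix(0, 8, 20 * rate)
  bad[1, seq(1, 20 * rate, by = 5 * rate)] <- 200
  expect_null(select_qc_segment(eeg_recording(bad, rate, mont), 10, 100))
  expect_error(select_qc_segment(zero, window = 30), "shorter")
})

test_that("QC selection equals the brute-force scan on random instances", {
  mont <- make_montage(8)
  rate <- 50
  set.seed(404)
  for (case in 1:20) {
    n <- sample(500:1500, 1)
    dat <- matrix(rnorm(8 * n, sd = 40), 8, n)
    # sprinkle occasional large excursions
    hits <- sample(n, sample(0:8, 1))
    dat[cbind(sample(8, length(hits), replace = TRUE), hits)] <- 180
    rec <- eeg_recording(dat, rate, mont)
    oracle <- qc_oracle(dat, 5 * rate, 100)
    got <- select_qc_segment(rec, window = 5, threshold = 100)
    if (is.null(oracle)) expect_null(got)
    else expect_identical(attr(got, "qc_start"), oracle)
  }
})

test_that("narrowband filtering isolates the requested band and removes DC", {
  fs <- 256; t <- seq_len(60 * fs) / fs
  mont <- make_montage(8)
  gains2 <- rnorm(8); gains20 <- rnorm(8)
  dat <- outer(gains2, sin(2 * pi * 2 * t)) + outer(gains20, sin(2 * pi * 20 * t))
  rec <- eeg_recording(dat, fs, mont)
  out <- narrowband_filter(rec, "delta")
  v <- valid_cols(out)
  # the 20 Hz component must be attenuated by >= 40 dB
  spec_amp <- function(x, f) {
    n <- length(x); Mod(fft(x))[round(f * n / fs) + 1] / n
  }
  for (ch in 1:3) {
    a_in <- spec_amp(dat[ch, ], 20)
    a_out <- spec_amp(out$data[ch, v], 20)
    expect_lt(a_out / a_in, 0.01)
  }
  expect_lt(max(abs(rowMeans(out$data[, v]))) / rms(out$data[, v]), 1e-4)
})

test_that("narrowband filtering is idempotent up to transition-band effects", {
  fs <- 256
  set.seed(7)
  mont <- make_montage(8)
  # spectrum confined to the pass-band interior (9-12 Hz), where the
  # idempotence claim is meaningful
  t <- seq_len(30 * fs) / fs
  wave <- sin(2 * pi * 10.5 * t) + 0.4 * sin(2 * pi * 10 * t + 1)
  rec <- eeg_recording(outer(rnorm(8), wave), fs, mont)
  once <- narrowband_filter(rec, "alpha")
  twice <- narrowband_filter(once, "alpha")
  v <- (2 * once$edge):(ncol(once$data) - 2 * once$edge)
  expect_lt(max(abs(twice$data[, v] - once$data[, v])) / rms(once$data[, v]), 0.02)
})

test_that("a pass-band sinusoid suffers no lag (cross-correlation peaks at zero)", {
  fs <- 256; t <- seq_len(30 * fs) / fs
  rec <- waveform_recording(sin(2 * pi * 10 * t), fs, seed = 5)
  out <- narrowband_filter(rec, "alpha")
  v <- valid_cols(out)
  lags <- -5:5
  cc <- vapply(lags, function(l) {
    idx <- v[v + l >= 1 & v + l <= ncol(out$data)]
    cor(rec$data[1, idx] - colMeans(rec$data)[idx], out$data[1, idx + l])
  }, numeric(1))
  expect_equal(lags[which.max(abs(cc))], 0)
})
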