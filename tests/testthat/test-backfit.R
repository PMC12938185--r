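# Back-fitting, minimum-duration smoothing, temporal metrics, GEV,
# transition probabilities.

test_that("back-fitting labels constant-template data perfectly", {
  mont <- make_montage(16)
  tm <- make_templates(mont, 4, seed = 1)
  ts <- template_set(tm, labels = LETTERS[1:4])
  rec <- eeg_recording(matrix(tm[2, ], 16, 100) * 3, 256, mont)
  seg <- backfit(rec, ts)
  expect_true(all(seg$labels == 2))
  expect_equal(seg$fit, rep(1, 100), tolerance = 1e-9)
})

test_that("per-sample winner equals the brute-force argmax over correlations", {
  mont <- make_montage(12)
  tm <- make_templates(mont, 4, seed = 2)
  ts <- template_set(tm, labels = LETTERS[1:4])
  set.seed(51)
  dat <- matrix(rnorm(12 * 300), 12, 300)
  seg <- backfit(eeg_recording(dat, 256, mont), ts)
  for (i in sample(300, 40)) {
    cors <- apply(tm, 1, function(m) spatial_correlation(m, dat[, i]))
    expect_equal(seg$labels[i], unname(which.max(cors)))
    expect_equal(seg$fit[i], unname(max(cors)), tolerance = 1e-9)
  }
})

test_that("zero-variance samples inherit the previous label and are flagged", {
  mont <- make_montage(12)
  tm <- make_templates(mont, 4, seed = 2)
  ts <- template_set(tm, labels = LETTERS[1:4])
  dat <- matrix(tm[3, ], 12, 10) * 2
  dat[, 4] <- 0
  seg <- backfit(eeg_recording(dat, 256, mont), ts)
  expect_equal(seg$labels[4], 3L)
  expect_equal(seg$flagged, 4L)
  dat[, 1] <- 0
  seg2 <- backfit(eeg_recording(dat, 256, mont), ts)
  expect_equal(seg2$labels[1], 1L)
})

test_that("a short interior run is dissolved into its flanks", {
  seg <- manual_segmentation(rep(c(1L, 2L, 1L), c(40, 2, 40)), rate = 256)
  out <- smooth_min_duration(seg, min_ms = 30)   # min run = 8 samples
  r <- rle(out$labels)
  expect_equal(r$values, 1L)
  expect_equal(r$lengths, 82L)
})

test_that("dissolved samples go to the better-correlated flank", {
  lab <- rep(c(1L, 2L, 3L), c(40, 4, 40))
  corr <- matrix(0.1, 84, 4)
  corr[cbind(seq_along(lab), lab)] <- 0.9
  corr[41:42, 1] <- 0.8; corr[41:42, 3] <- 0.2   # first two lean to flank 1
  corr[43:44, 3] <- 0.8; corr[43:44, 1] <- 0.2   # last two lean to flank 3
  seg <- manual_segmentation(lab, rate = 256, corr = corr)
  out <- smooth_min_duration(seg, min_ms = 30)
  r <- rle(out$labels)
  expect_equal(r$values, c(1L, 3L))
  expect_equal(r$lengths, c(42L, 42L))
})

test_that("compliant segmentations are fixed points of smoothing", {
  seg <- manual_segmentation(rep(c(1L, 2L, 3L, 4L), each = 10), rate = 256)
  out <- smooth_min_duration(seg, min_ms = 30)
  expect_identical(out$labels, seg$labels)
  # first/last runs are exempt even when short
  seg2 <- manual_segmentation(rep(c(1L, 2L, 1L), c(2, 30, 3)), rate = 256)
  out2 <- smooth_min_duration(seg2, min_ms = 30)
  expect_identical(out2$labels, seg2$labels)
})

test_that("smoothing terminates and leaves no violating interior runs", {
  # exhaustive small alternating cases; min run is 8 samples at 256 Hz
  for (T in c(8, 16, 32)) {
    for (K in c(2, 4)) {
      lab <- rep_len(seq_len(K), T)
      set.seed(T + K)
      corr <- matrix(runif(T * 4), T, 4)
      seg <- manual_segmentation(as.integer(lab), rate = 256, corr = corr)
      out <- smooth_min_duration(seg, min_ms = 30)
      r <- rle(out$labels)
      if (K == 2) expect_lte(length(r$values), 2)
      expect_lt(length(r$values), T)   # strictly fewer runs than the input
      if (length(r$values) > 2)        # any surviving interior run is long enough
        expect_true(all(r$lengths[2:(length(r$values) - 1)] >= 8))
    }
  }
  # random label noise at scale: result obeys the constraint everywhere
  set.seed(61)
  lab <- rep(sample(1:4, 300, TRUE), pmax(1, rpois(300, 6)))
  corr <- matrix(runif(length(lab) * 4), length(lab), 4)
  seg <- manual_segmentation(as.integer(lab), rate = 256, corr = corr)
  out <- smooth_min_duration(seg, min_ms = 30)
  r <- rle(out$labels)
  if (length(r$values) > 2)
    expect_true(all(r$lengths[2:(length(r$values) - 1)] >= 8))
})

test_that("temporal metrics match hand-computed values and partition coverage", {
  seg <- manual_segmentation(rep(c(1L, 2L, 1L), c(10, 5, 10)), rate = 256)
  tm <- temporal_metrics(seg)
  expect_equal(tm$mean_duration[1], 10 * 1000 / 256)   # 39.0625 ms
  expect_equal(tm$coverage[1], 0.8)
  expect_equal(tm$occurrence[1], 2 / (25 / 256))       # 20.48 / s
  expect_equal(tm$mean_duration[2], 5 * 1000 / 256)
  expect_true(is.na(tm$mean_duration[3]))
  expect_equal(tm$coverage[3], 0)
  expect_equal(tm$occurrence[4], 0)
  expect_equal(sum(tm$coverage), 1)
  # single class throughout
  seg1 <- manual_segmentation(rep(2L, 128), rate = 256)
  tm1 <- temporal_metrics(seg1)
  expect_equal(tm1$coverage[2], 1)
  expect_equal(tm1$occurrence[2], 1 / 0.5)
  expect_equal(tm1$mean_duration[2], 500)
})

test_that("per-class GEV sums to one on noiseless data and matches the direct formula", {
  mont <- make_montage(16)
  tm <- make_templates(mont, 4, seed = 3)
  ts <- template_set(tm, labels = LETTERS[1:4])
  cfg <- synthetic_config(n_channels = 16, duration = 6, snr = Inf, seed = 7)
  rec <- synthesize_eeg(cfg, montage = mont, templates = tm)
  seg <- backfit(rec, ts)
  gev <- gev_per_class(rec, seg, ts)
  expect_equal(sum(gev), 1, tolerance = 1e-6)
  # direct summation oracle on a short random instance
  set.seed(52)
  dat <- matrix(rnorm(16 * 40), 16, 40)
  rec2 <- eeg_recording(dat, 256, mont)
  seg2 <- backfit(rec2, ts)
  gev2 <- gev_per_class(rec2, seg2, ts)
  g <- apply(dat, 2, function(v) sqrt(mean((v - mean(v))^2)))
  num <- numeric(4)
  for (t in 1:40) {
    k <- seg2$labels[t]
    r <- spatial_correlation(dat[, t], tm[k, ])
    num[k] <- num[k] + (g[t] * r)^2
  }
  expect_equal(unname(gev2), num / sum(g^2), tolerance = 1e-12)
})

test_that("transition probabilities count distinct consecutive runs", {
  seg <- manual_segmentation(rep(c(1L, 2L, 1L, 3L), each = 10), rate = 256)
  tp <- transition_probabilities(seg)
  expect_equal(unname(tp["A", c("B", "C")]), c(0.5, 0.5))
  expect_equal(unname(tp["B", "A"]), 1)
  expect_true(all(is.na(tp["C", ])))
  # class D never occurs, so its row is undefined as well
  expect_setequal(attr(tp, "undefined_rows"), c("C", "D"))
  # cyclic sequence: point masses on the successor
  seg2 <- manual_segmentation(rep(rep(1:4, 5), each = 10), rate = 256)
  tp2 <- transition_probabilities(seg2)
  for (i in 1:4) {
    j <- if (i == 4) 1 else i + 1
    expect_equal(unname(tp2[i, j]), 1)
  }
  rs <- rowSums(tp2, na.rm = TRUE)
  expect_equal(unname(rs), rep(1, 4), tolerance = 1e-12)
  expect_true(all(diag(tp2) == 0))
  # single run: everything undefined
  tp3 <- transition_probabilities(manual_segmentation(rep(1L, 50)))
  expect_true(all(is.na(tp3)))
  # sample-wise convention: diagonal-dominant, rows still stochastic
  tps <- transition_probabilities(seg2, mode = "samples")
  expect_true(all(diag(tps) > 0.8))
  expect_equal(unname(rowSums(tps)), rep(1, 4), tolerance = 1e-12)
})

test_that("coverage approximately equals occurrence x mean duration", {
  cfg <- synthetic_config(n_channels = 16, duration = 30, snr = 4, seed = 33)
  mont <- make_montage(16)
  tm <- make_templates(mont, 4, seed = 4)
  rec <- synthesize_eeg(cfg, montage = mont, templates = tm)
  seg <- smooth_min_duration(backfit(rec, template_set(tm, labels = LETTERS[1:4])))
  m <- temporal_metrics(seg)
  for (k in 1:4) {
    if (m$n_runs[k] == 0) next
    expect_equal(m$coverage[k],
                 m$occurrence[k] * m$mean_duration[k] / 1000,
                 tolerance = 1e-9)
  }
})
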