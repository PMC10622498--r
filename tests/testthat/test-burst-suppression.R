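test_that("band-pass filter attenuates out-of-band and passes in-band tones", {
  fs <- 2500; t <- seq(0, 20, by = 1 / fs)[-1]
  slow <- signal_recording(matrix(100 * sin(2 * pi * 0.1 * t)), fs = fs)
  mid <- signal_recording(matrix(100 * sin(2 * pi * 50 * t)), fs = fs)
  f_slow <- bandpass(slow, c(1, 1000))
  f_mid <- bandpass(mid, c(1, 1000))
  # steady-state amplitude away from filter edge transients
  core <- round(length(t) * 0.25):round(length(t) * 0.75)
  amp <- function(x) (max(x[core]) - min(x[core])) / 2
  expect_lt(amp(f_slow$samples[, 1]) / 100, 10^(-20 / 20))  # > 20 dB down
  expect_gt(amp(f_mid$samples[, 1]) / 100, 0.95)            # within 5%
  expect_error(bandpass(mid, c(1000, 1)), "low < high")
  expect_error(bandpass(mid, c(1, 2000)), "Nyquist")
})

test_that("rectified bins average |signal| and drop the partial tail", {
  fs <- 1000
  const <- signal_recording(matrix(rep(5, 2.9 * fs)), fs = fs)
  b <- rectified_bins(const, 0.7)
  expect_equal(length(b$values), 4L)        # 2.9 s -> 4 full 700-ms bins
  expect_true(all(abs(b$values - 5) < 1e-12))
  sq <- signal_recording(matrix(rep(c(10, -10), 1.4 * fs / 2)), fs = fs)
  expect_true(all(abs(rectified_bins(sq, 0.7)$values - 10) < 1e-12))
  short <- signal_recording(matrix(rnorm(300)), fs = fs)
  expect_error(rectified_bins(short, 0.7), "too short")
})

test_that("bimodal threshold sits in the valley and scales with gain", {
  set.seed(1)
  v <- c(rnorm(500, 2, 0.1), rnorm(500, 10, 0.1))
  thr <- bimodal_threshold(v)
  expect_gt(thr, 3); expect_lt(thr, 9)
  expect_equal(bimodal_threshold(7 * v), 7 * thr, tolerance = 1e-9)
  expect_error(bimodal_threshold(rep(4, 100)), "no-bimodality")
  uni <- qnorm(ppoints(500), 5, 1)    # smooth unimodal sample
  expect_error(bimodal_threshold(uni), "no-bimodality")
  expect_equal(bimodal_threshold(uni, fallback_quantile = 0.5),
               unname(quantile(uni, 0.5)))
})

test_that("classification merges across short gaps then applies the duration rule", {
  # candidate bursts [0,1.4) and [2.1,4.2): 0.7-s gap < 2 s -> one burst [0,4.2)
  bins <- structure(list(starts = seq(0, by = 0.7, length.out = 20),
                         values = c(9, 9, 1, 9, 9, 9, rep(1, 14)),
                         bin_width_s = 0.7), class = "bin_series")
  seg <- classify_segments(bins, threshold = 5)
  b <- seg$intervals[seg$intervals$label == "burst", ]
  expect_equal(nrow(b), 1L)
  expect_equal(b$start, 0); expect_equal(b$end, 4.2)

  # an isolated 1.4-s candidate is rejected (not > 2 s): all suppression
  bins2 <- structure(list(starts = seq(0, by = 0.7, length.out = 20),
                          values = c(rep(1, 8), 9, 9, rep(1, 10)),
                          bin_width_s = 0.7), class = "bin_series")
  seg2 <- classify_segments(bins2, threshold = 5)
  expect_equal(unique(seg2$intervals$label), "suppression")
})

test_that("alternating 5 s bursts and suppressions give BSR one half", {
  bins <- structure(list(starts = 0:119, values = rep(rep(c(9, 1), each = 5), 12),
                         bin_width_s = 1), class = "bin_series")
  seg <- classify_segments(bins, threshold = 5)
  expect_equal(seg$bsr$bsr, c(0.5, 0.5))
  st <- sum(seg$intervals$end[seg$intervals$label == "suppression"] -
              seg$intervals$start[seg$intervals$label == "suppression"])
  expect_equal(st, sum(seg$bsr$bsr * 60))   # BSR x bin width sums to supp time
})

test_that("merge-then-accept is idempotent on its own output", {
  sim <- simulate_bs_lfp(bs_model(), 120, fs = 2500, seed = 17)
  seg <- segment_bs(sim$recording)
  # rebuild a bin series from the predicted labels and reclassify
  n_bins <- round(max(seg$intervals$end) / 0.7)
  mids <- (seq_len(n_bins) - 0.5) * 0.7
  lab <- ieskit:::label_at(seg$intervals, mids, 0.7)
  bins2 <- structure(list(starts = mids - 0.35,
                          values = ifelse(lab == "burst", 1, 0),
                          bin_width_s = 0.7), class = "bin_series")
  seg2 <- classify_segments(bins2, threshold = 0.5, seg$params)
  expect_equal(seg2$intervals, seg$intervals, tolerance = 1e-9)
})

test_that("segmentation labels are invariant to uniform gain", {
  sim <- simulate_bs_lfp(bs_model(), 120, fs = 2500, seed = 19)
  seg1 <- segment_bs(sim$recording)
  rec3 <- sim$recording
  rec3$samples <- rec3$samples * 3
  seg3 <- segment_bs(rec3)
  expect_equal(seg3$intervals, seg1$intervals, tolerance = 1e-9)
  expect_equal(seg3$threshold, 3 * seg1$threshold, tolerance = 1e-6)
})

test_that("segmentation scoring: identity is 1, complement is 0", {
  iv <- data.frame(label = c("burst", "suppression", "burst"),
                   start = c(0, 10, 25), end = c(10, 25, 42),
                   stringsAsFactors = FALSE)
  flip <- iv
  flip$label <- ifelse(iv$label == "burst", "suppression", "burst")
  expect_equal(score_segmentation(iv, iv), 1.0)
  expect_equal(score_segmentation(flip, iv), 0.0)
  short <- data.frame(label = "burst", start = 0, end = 10)
  expect_error(score_segmentation(short, iv), "different spans")
})

test_that("synthetic recordings produce bimodal rectified-amplitude bins", {
  sim <- simulate_bs_lfp(bs_model(), 120, fs = 2500, seed = 23)
  bins <- rectified_bins(bandpass(sim$recording, c(1, 1000)), 0.7)
  thr <- bimodal_threshold(bins)        # a valley exists
  lo <- mean(bins$values < thr)
  expect_gt(lo, 0.1); expect_lt(lo, 0.9)  # both modes populated
})
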