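test_that("suppression z-scoring centres on the suppression baseline", {
  fs <- 1000
  iv <- data.frame(label = c("suppression", "burst"), start = c(0, 10),
                   end = c(10, 20), stringsAsFactors = FALSE)
  set.seed(3)
  supp <- rnorm(10 * fs, 2, 1)
  x <- c(supp, rep(mean(supp), 10 * fs))  # burst half equals suppression mean
  rec <- signal_recording(matrix(x), fs = fs)
  z <- suppression_zscore(rec, iv)
  expect_equal(max(abs(z[(10 * fs + 1):(20 * fs)])), 0, tolerance = 1e-9)
})

test_that("z-scores are invariant to positive gain", {
  fs <- 1000
  iv <- data.frame(label = c("suppression", "burst"), start = c(0, 8),
                   end = c(8, 12), stringsAsFactors = FALSE)
  set.seed(4)
  rec <- signal_recording(matrix(rnorm(12 * fs, 0, 2)), fs = fs)
  rec3 <- rec; rec3$samples <- 3 * rec$samples
  expect_equal(suppression_zscore(rec, iv), suppression_zscore(rec3, iv),
               tolerance = 1e-12)
})

test_that("a 40 uV transient over a 2 uV suppression baseline scores ~20 z", {
  fs <- 1000
  iv <- data.frame(label = "suppression", start = 0, end = 20,
                   stringsAsFactors = FALSE)
  set.seed(5)
  x <- rnorm(20 * fs, 0, 2)
  x[10 * fs] <- x[10 * fs] + 40
  rec <- signal_recording(matrix(x), fs = fs)
  z <- suppression_zscore(rec, iv)
  expect_equal(z[10 * fs], 20, tolerance = 2.5)
})

test_that("baseline errors are named and the robust fallback works", {
  fs <- 1000
  rec <- signal_recording(matrix(rnorm(6 * fs)), fs = fs, state = "awake")
  short_iv <- data.frame(label = c("suppression", "burst"), start = c(0, 2),
                         end = c(2, 6), stringsAsFactors = FALSE)
  expect_error(suppression_zscore(rec, short_iv), "insufficient suppression")
  z <- suppression_zscore(rec, params = detection_params(
    baseline_source = "robust_whole_trace"))
  expect_lt(abs(median(z)), 0.05)
  expect_equal(mad(z), 1, tolerance = 0.05)
})

test_that("detector finds injected transients, not noise, and respects dead-time", {
  fs <- 2500
  set.seed(6)
  z <- rnorm(40 * fs)
  z <- z / max(abs(z)) * 4                # max |z| = 4: below threshold
  expect_equal(nrow(detect_ies(z, fs)), 0L)

  tpl <- ies_template(fs)
  w15 <- tpl$waveform * 15 / max(abs(tpl$waveform))   # 15-z peak
  zi <- rnorm(40 * fs, 0, 0.3)            # low background for the timing check
  for (tt in c(10, 20, 30)) {
    i0 <- round(tt * fs) - tpl$peak_offset + 1
    zi[i0:(i0 + length(w15) - 1)] <- zi[i0:(i0 + length(w15) - 1)] + w15
  }
  ev <- detect_ies(zi, fs)
  expect_equal(nrow(ev), 3L)
  expect_true(all(abs(ev$time - c(10, 20, 30)) <= 0.002))
  expect_true(all(ev$ptp_z > 10))

  # two transients 30 ms apart: the dead-time keeps only the first
  z2 <- rnorm(10 * fs) * 0.5
  for (tt in c(5, 5.03)) {
    i0 <- round(tt * fs) - tpl$peak_offset + 1
    z2[i0:(i0 + length(w15) - 1)] <- z2[i0:(i0 + length(w15) - 1)] + w15
  }
  ev2 <- detect_ies(z2, fs)
  expect_equal(nrow(ev2), 1L)
  expect_lt(abs(ev2$time - 5), 0.002)
})

test_that("accepted events are never closer than the dead-time", {
  fs <- 2500
  set.seed(7)
  z <- rnorm(60 * fs) * 3
  tpl <- ies_template(fs)
  for (tt in seq(2, 58, by = 0.4)) {      # dense spikes
    i0 <- round(tt * fs) - tpl$peak_offset + 1
    z[i0:(i0 + length(tpl$waveform) - 1)] <-
      z[i0:(i0 + length(tpl$waveform) - 1)] + tpl$waveform * 15
  }
  ev <- detect_ies(z, fs)
  expect_gt(nrow(ev), 50)
  expect_true(all(diff(ev$time) >= 0.05 - 1e-9))
})

test_that("lowering the z threshold never decreases the event count", {
  sim <- simulate_bs_lfp(detection_model(), 120, fs = 2500, seed = 31)
  sim <- inject_ies(sim, rate_per_min = 6, amplitude_z = 13, seed = 32)
  seg <- segment_bs(sim$recording)
  z <- suppression_zscore(sim$recording, seg)
  counts <- vapply(c(12, 10, 8), function(thr)
    nrow(detect_ies(z, 2500, detection_params(z_threshold = thr))), 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("detection pipeline output is invariant to recording gain", {
  sim <- simulate_bs_lfp(detection_model(), 120, fs = 2500, seed = 33)
  sim <- inject_ies(sim, rate_per_min = 3, amplitude_z = 15, seed = 34)
  ev1 <- detect_ies_pipeline(sim$recording)
  rec5 <- sim$recording; rec5$samples <- rec5$samples * 5
  ev5 <- detect_ies_pipeline(rec5)
  expect_equal(ev5$time, ev1$time, tolerance = 1e-9)
  expect_equal(ev5$peak_z, ev1$peak_z, tolerance = 1e-6)
})

test_that("rate summaries divide counts by duration", {
  expect_equal(ies_rate(data.frame(channel = character(0), time = numeric(0)),
                        10)$rate_per_min, numeric(0))
  ev <- data.frame(channel = "CA1", time = sort(runif(193, 0, 3600)))
  rs <- ies_rate(ev, 60)
  expect_equal(rs$rate_per_min, 193 / 60, tolerance = 1e-12)
  expect_error(ies_rate(ev, 0), "duration_min")
})

test_that("detection scoring matches greedily one-to-one", {
  truth <- c(1, 2, 3)
  s <- detection_score(truth, truth)
  expect_equal(s$precision, 1); expect_equal(s$recall, 1)
  s2 <- detection_score(numeric(0), truth)
  expect_equal(s2$recall, 0)
  # one prediction near two truths can only match one
  s3 <- detection_score(c(1.0), c(0.99, 1.01), tolerance_ms = 25)
  expect_equal(s3$n_matched, 1L)
  expect_equal(s3$recall, 0.5)
})
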