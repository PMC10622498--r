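test_that("deterministic burst/suppression alternation has exact symmetry", {
  model <- bs_model(burst_median = 5, burst_sigma = 0, supp_median = 5,
                    supp_sigma = 0)
  sim <- simulate_bs_lfp(model, 60, fs = 500, seed = 1)
  iv <- sim$truth$intervals
  expect_equal(sum(iv$label == "burst"), 6L)
  expect_equal(sum(iv$label == "suppression"), 6L)
  expect_equal(sum(iv$end[iv$label == "suppression"] -
                     iv$start[iv$label == "suppression"]), 30)
  expect_equal(max(iv$end), 60)
})

test_that("generator is seed-deterministic and seed-sensitive", {
  a <- simulate_bs_lfp(bs_model(), 30, fs = 500, seed = 7)
  b <- simulate_bs_lfp(bs_model(), 30, fs = 500, seed = 7)
  c <- simulate_bs_lfp(bs_model(), 30, fs = 500, seed = 8)
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$truth$intervals, b$truth$intervals)
  expect_false(identical(a$recording$samples, c$recording$samples))
})

test_that("empirical suppression fraction matches the alternating-renewal mean", {
  model <- bs_model()
  # analytic mean fraction E[S] / (E[B] + E[S]); log-normal mean =
  # median * exp(sigma^2 / 2)
  eb <- model$burst_median * exp(model$burst_sigma^2 / 2)
  es <- model$supp_median * exp(model$supp_sigma^2 / 2)
  expected <- es / (eb + es)
  fr <- vapply(1:10, function(s) {
    iv <- simulate_bs_lfp(model, 900, fs = 250, seed = s)$truth$intervals
    interval_time <- function(lab) sum(iv$end[iv$label == lab] -
                                         iv$start[iv$label == lab])
    interval_time("suppression") / 900
  }, 0)
  se <- stats::sd(fr) / sqrt(length(fr))
  # small allowance beyond 3 SE for the start-with-burst edge bias
  expect_lt(abs(mean(fr) - expected), 3 * se + 0.01)
})

test_that("explicit-time injection places scaled transients at those times", {
  sim <- simulate_bs_lfp(detection_model(), 40, fs = 2500, seed = 3)
  before <- sim$recording$samples[, 1]
  out <- inject_ies(sim, times = c(10, 20, 30), amplitude_z = 15)
  expect_equal(out$truth$ies_times$CA1, c(10, 20, 30))
  added <- out$recording$samples[, 1] - before
  expect_equal(sum(abs(added) > 0) > 0, TRUE)
  # additions confined to near the requested times
  t_nz <- (which(abs(added) > 1e-9) - 1) / 2500
  expect_true(all(vapply(t_nz, function(t)
    min(abs(t - c(10, 20, 30))) < 0.1, NA)))
  # realized peak-to-peak in suppression-SD z units within 10% of target
  ssd <- sd(before[ieskit:::interval_mask(sim$truth$intervals, "suppression",
                                          length(before), 2500)])
  for (tt in c(10, 20, 30)) {
    idx <- round((tt - 0.05) * 2500):round((tt + 0.1) * 2500)
    ptp <- diff(range(added[idx])) / ssd
    expect_gt(ptp, 13.5); expect_lt(ptp, 16.5)
  }
})

test_that("Poisson injection realizes the requested rate and spacing", {
  sim <- simulate_bs_lfp(bs_model(), 3600, fs = 250, seed = 5)
  out <- inject_ies(sim, rate_per_min = 3, amplitude_z = 15, seed = 6)
  n <- length(out$truth$ies_times$CA1)
  expect_lt(abs(n - 180), 3 * sqrt(180))
  expect_true(all(diff(out$truth$ies_times$CA1) >= 0.05))
  expect_error(inject_ies(sim, rate_per_min = -1), "non-negative")
})

test_that("coupled-train generator respects coupling probability and lags", {
  tr <- simulate_coupled_trains(3, 3, coupling_prob = 1, lag_jitter_sd_ms = 5,
                                duration_s = 600, seed = 11)
  expect_true(all(vapply(tr$target, function(t)
    min(abs(tr$ref - t)) <= 0.020, NA)))
  expect_true(all(tr$truth$coupled_flags))

  tr0 <- simulate_coupled_trains(3, 3, coupling_prob = 0, duration_s = 600,
                                 seed = 12)
  expect_false(any(tr0$truth$coupled_flags))
  expect_error(simulate_coupled_trains(3, 3, 0.5, 5, duration_s = 0),
               "duration_s")
  expect_error(simulate_coupled_trains(3, 3, 1.5, 5, duration_s = 10),
               "coupling_prob")
  a <- simulate_coupled_trains(3, 3, 0.5, 5, 300, seed = 9)
  b <- simulate_coupled_trains(3, 3, 0.5, 5, 300, seed = 9)
  expect_identical(a, b)
})

test_that("calcium generator pairs states through the seed and recovers rates", {
  model <- ca_model(n_cells = 100, state_modulation = 0.5, frac_fail_roi = 0)
  aw <- simulate_ca_matrix(model, 600, seed = 21, state = "awake")
  ga <- simulate_ca_matrix(model, 600, seed = 21, state = "GA")
  expect_identical(aw$rois, ga$rois)
  expect_equal(ga$truth$rates, 0.5 * aw$truth$rates)
  r_aw <- rowSums(aw$activity) / 600
  r_ga <- rowSums(ga$activity) / 600
  expect_lt(abs(median(r_ga) / median(r_aw) - 0.5), 0.1)
  # measured per-cell rates recover generative rates within Poisson error
  err_z <- (rowSums(aw$activity) - aw$truth$rates * 600) /
    sqrt(pmax(aw$truth$rates * 600, 1))
  expect_lt(mean(abs(err_z) > 4), 0.02)
  expect_identical(simulate_ca_matrix(model, 60, seed = 3)$activity,
                   simulate_ca_matrix(model, 60, seed = 3)$activity)
  expect_error(ca_model(n_cells = 0), "n_cells")
})

test_that("paired-pulse generator encodes the requested facilitation ratio", {
  sw <- simulate_paired_pulse(ppr = 1.0, noise_sd_uv = 0)
  res <- paired_pulse_ratio(sw)
  expect_equal(res$ratio, 1.0, tolerance = 0.01)
  expect_error(simulate_paired_pulse(ppr = 0), "ppr")
  expect_error(simulate_paired_pulse(ppr = 1, isi_ms = -4), "isi_ms")
})
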