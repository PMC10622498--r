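test_that("window synchrony arithmetic on disjoint and merged windows", {
  ref <- as.numeric(1:10)
  expect_equal(window_synchrony(ref, ref, 10, 20), 10 / (10 * 0.02))
  expect_equal(window_synchrony(ref, numeric(0), 10, 20), 0)
  expect_error(window_synchrony(numeric(0), ref, 10, 20), "empty reference")
  # random trains vs loop-based interval oracle, including window overlap
  set.seed(8)
  for (k in 1:5) {
    r <- sort(runif(40, 0, 60)); tg <- sort(runif(50, 0, 60))
    expect_equal(window_synchrony(r, tg, 500, 60),
                 brute_window_synchrony(r, tg, 500, 60), tolerance = 1e-12)
  }
})

test_that("synchrony of an independent Poisson target estimates its rate", {
  set.seed(9)
  vals <- replicate(60, {
    r <- sort(runif(rpois(1, 30), 0, 600))
    tg <- sort(runif(rpois(1, 60), 0, 600))   # 0.1 events/s
    window_synchrony(r, tg, 100, 600)
  })
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - 0.1), 3 * se + 0.005)
})

test_that("jitter surrogates conserve counts and stay within the span", {
  target <- sort(runif(80, 0, 600))
  surr <- jitter_surrogates(target, 10, 600, n_surrogates = 50, seed = 10)
  expect_equal(dim(surr), c(80L, 50L))
  expect_true(all(surr >= 0 & surr < 600))
  # every surrogate spike within 2 x half-width of some original spike
  expect_true(all(apply(surr, 2L, function(s)
    max(vapply(s, function(t) min(abs(target - t)), 0)) <= 0.020 + 1e-12)))
  expect_identical(surr, jitter_surrogates(target, 10, 600,
                                           n_surrogates = 50, seed = 10))
})

test_that("boundary reflection keeps spikes in range without deleting them", {
  target <- c(0.001, 599.999)
  surr <- jitter_surrogates(target, 1000, 600, n_surrogates = 200, seed = 11)
  expect_true(all(surr >= 0 & surr < 600))
  expect_equal(nrow(surr), 2L)
})

test_that("strongly coupled trains are significant with the minimal p", {
  tr <- simulate_coupled_trains(3, 3, coupling_prob = 1, lag_jitter_sd_ms = 5,
                                duration_s = 1800, seed = 13)
  jt <- jitter_test(tr$ref, tr$target, 1800,
                    jitter_params(half_widths_ms = c(50, 100)), seed = 14)
  expect_true(all(jt$significant))
  expect_equal(jt$p_value, rep(1 / 1001, 2), tolerance = 1e-12)
})

test_that("attained p-values are bounded below and match the surrogate count", {
  tr <- simulate_coupled_trains(3, 3, 0, duration_s = 1800, seed = 15)
  p1 <- jitter_test(tr$ref, tr$target, 1800,
                    jitter_params(half_widths_ms = 100, n_surrogates = 1),
                    seed = 16)
  expect_true(p1$p_value %in% c(0.5, 1))
  p <- jitter_test(tr$ref, tr$target, 1800,
                   jitter_params(half_widths_ms = 100, n_surrogates = 200),
                   seed = 17)
  expect_gt(p$p_value, 0)
  expect_lte(p$p_value, 1)
  expect_identical(p$significant, p$observed > p$surrogate_max)
})

test_that("peri-event histogram concentrates mass at the generative lag", {
  ref <- as.numeric(1:50)
  h0 <- peri_event_histogram(ref, ref, 100, 5)
  expect_equal(sum(h0$count), 50L)
  expect_equal(h0$lag_ms[which.max(h0$count)], 2.5)  # 0-lag bin

  set.seed(18)
  lagged <- ref + 0.007
  h5 <- peri_event_histogram(ref, lagged, 100, 5)
  expect_equal(h5$count[h5$lag_ms == 7.5], 50L)      # bin [5,10) holds +7 ms

  # uniform independent trains: flat within chi-square tolerance
  r <- sort(runif(300, 10, 590)); tg <- sort(runif(3000, 0, 600))
  h <- peri_event_histogram(r, tg, 100, 25)
  cs <- chisq.test(h$count)
  expect_gt(cs$p.value, 1e-4)
  expect_error(peri_event_histogram(ref, ref, 100, 300), "exceed")
  expect_error(peri_event_histogram(ref, ref, 100, 7), "divide")
})

test_that("fraction-within matches brute-force enumeration", {
  expect_equal(fraction_within(1:10, 1:10, 100), 1.0)
  expect_equal(fraction_within(1:10, numeric(0), 100), 0)
  expect_error(fraction_within(numeric(0), 1:3, 100), "empty")
  set.seed(19)
  for (k in 1:5) {
    r <- sort(runif(30, 0, 300)); tg <- sort(runif(20, 0, 300))
    expect_equal(fraction_within(r, tg, 100),
                 brute_fraction_within(r, tg, 100), tolerance = 1e-12)
  }
  tr <- simulate_coupled_trains(2, 2, coupling_prob = 0.3,
                                lag_jitter_sd_ms = 5, duration_s = 1200,
                                seed = 20)
  expect_equal(fraction_within(tr$ref, tr$target, 100),
               brute_fraction_within(tr$ref, tr$target, 100),
               tolerance = 1e-12)
})

test_that("per-reference-event synchrony variant is available and sane", {
  set.seed(21)
  r <- sort(runif(30, 0, 300)); tg <- sort(runif(40, 0, 300))
  merged <- window_synchrony(r, tg, 500, 300, merge = TRUE)
  per_ref <- window_synchrony(r, tg, 500, 300, merge = FALSE)
  expect_gt(per_ref, 0)
  expect_equal(merged, per_ref, tolerance = 0.5)  # same scale, not identical
})
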