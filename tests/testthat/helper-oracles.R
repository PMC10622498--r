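# Independent brute-force oracles used to check package computations.
# These deliberately use naive loop-based algorithms, not the package's
# vectorized implementations.

# All permutations of 1..n in lexicographic order (iterative
# next-permutation), independent of the package's recursive generator.
perms_lex <- function(n) {
  p <- seq_len(n)
  out <- list(p)
  repeat {
    k <- 0L
    for (i in seq_len(n - 1L)) if (p[i] < p[i + 1L]) k <- i
    if (k == 0L) break
    l <- k
    for (i in (k + 1L):n) if (p[k] < p[i]) l <- i
    tmp <- p[k]; p[k] <- p[l]; p[l] <- tmp
    p[(k + 1L):n] <- rev(p[(k + 1L):n])
    out[[length(out) + 1L]] <- p
  }
  do.call(rbind, out)
}

# Exact two-sided Spearman permutation p by full enumeration.
brute_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  obs <- stats::cor(rx, ry)
  pm <- perms_lex(length(x))
  rhos <- numeric(nrow(pm))
  for (i in seq_len(nrow(pm))) rhos[i] <- stats::cor(rx, ry[pm[i, ]])
  list(rho = obs, p = mean(abs(rhos) >= abs(obs) - 1e-12))
}

# Merged-window synchrony by direct interval arithmetic (loops).
brute_window_synchrony <- function(ref, target, half_width_ms, duration_s) {
  hw <- half_width_ms / 1000
  s <- pmax(sort(ref) - hw, 0); e <- pmin(sort(ref) + hw, duration_s)
  ms <- s[1]; me <- e[1]; wins <- NULL
  for (i in seq_along(s)[-1]) {
    if (s[i] > me) { wins <- rbind(wins, c(ms, me)); ms <- s[i]; me <- e[i] }
    else me <- max(me, e[i])
  }
  wins <- rbind(wins, c(ms, me))
  count <- 0L
  for (t in target)
    for (r in seq_len(nrow(wins)))
      if (t >= wins[r, 1] && t < wins[r, 2]) { count <- count + 1L; break }
  count / sum(wins[, 2] - wins[, 1])
}

# Fraction of ref events with a target within +/- window, by loops.
brute_fraction_within <- function(ref, target, window_ms) {
  w <- window_ms / 1000
  hits <- 0L
  for (r in ref) if (any(abs(target - r) <= w)) hits <- hits + 1L
  hits / length(ref)
}

# Generator model used for detection-oriented simulations: burst background
# kept at 2x suppression SD so that it stays below a 10-z threshold over a
# 10-min recording while the amplitude histogram remains clearly bimodal.
detection_model <- function() {
  bs_model(burst_amplitude_sd = 10, suppression_amplitude_sd = 5)
}

# Two-channel GA session with coupled spike trains injected into each
# channel; returns recording plus full ground truth.
make_dual_session <- function(seed, duration_s = 300, rate_per_min = 3,
                              coupling_prob = 0.9, fs = 2500) {
  s1 <- simulate_bs_lfp(detection_model(), duration_s, fs = fs, seed = seed,
                        channel_name = "CA1")
  s2 <- simulate_bs_lfp(detection_model(), duration_s, fs = fs,
                        seed = seed + 5000L, channel_name = "mPFC")
  s2$truth$intervals <- s1$truth$intervals   # shared anesthesia state
  tr <- simulate_coupled_trains(rate_per_min, rate_per_min, coupling_prob,
                                lag_jitter_sd_ms = 5, duration_s,
                                seed = seed + 9000L)
  s1 <- inject_ies(s1, times = tr$ref, amplitude_z = 15)
  s2 <- inject_ies(s2, times = tr$target, amplitude_z = 15)
  rec <- signal_recording(cbind(s1$recording$samples, s2$recording$samples),
                          fs = fs, channel_names = c("CA1", "mPFC"),
                          state = "GA")
  list(recording = rec,
       truth = list(intervals = s1$truth$intervals,
                    ies_times = list(CA1 = s1$truth$ies_times$CA1,
                                     mPFC = s2$truth$ies_times$mPFC)))
}
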