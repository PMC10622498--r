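#' Evoked response amplitude
#'
#' Baseline-subtracted extremum magnitude within a response window after a
#' stimulus.  The baseline is the mean over the sweep's pre-stimulus
#' window; the first 2 ms after the stimulus are blanked to exclude the
#' stimulus artifact.
#'
#' @param sweep an \code{evoked_sweep} (see
#'   \code{\link{simulate_paired_pulse}}), or a compatible list with
#'   \code{trace}, \code{fs}, \code{stim_times}, \code{baseline_window_s}.
#' @param stim_index which stimulus (1-based).
#' @param response_window_ms search window after the stimulus, ms.
#' @param blank_ms post-stimulus blanking, ms.
#' @return amplitude in uV (magnitude of the baseline-subtracted extremum).
#' @export
fepsp_amplitude <- function(sweep, stim_index = 1L, response_window_ms = 30,
                            blank_ms = 2) {
  tr <- sweep$trace; fs <- sweep$fs
  stim <- sweep$stim_times[stim_index]
  w_end <- stim + response_window_ms / 1000
  if (stim_index < length(sweep$stim_times) &&
      w_end > sweep$stim_times[stim_index + 1L])
    stop("response window collides with the next stimulus")
  if (w_end > length(tr) / fs) stop("response window extends past the sweep")
  bl <- baseline_level(sweep)
  i0 <- round((stim + blank_ms / 1000) * fs) + 1L
  i1 <- round(w_end * fs)
  seg <- tr[i0:i1] - bl
  max(abs(seg))
}

baseline_level <- function(sweep) {
  b <- sweep$baseline_window_s
  idx <- (round(b[1L] * sweep$fs) + 1L):max(1L, round(b[2L] * sweep$fs))
  mean(sweep$trace[idx])
}

#' Paired-pulse ratio
#'
#' Ratio of the second to the first evoked response amplitude.  At short
#' inter-stimulus intervals the first response's decaying tail contaminates
#' the second; by default a single exponential is fitted to the tail of the
#' first response (between its peak and the second stimulus) and its
#' extrapolation is subtracted before measuring the second amplitude.
#'
#' @param sweep an \code{evoked_sweep} with >= 2 stimuli.
#' @param correct_overlap logical; subtract the extrapolated first-response
#'   tail (default \code{TRUE}).  \code{FALSE} measures the raw second
#'   amplitude.
#' @param response_window_ms per-stimulus response window (ms).
#' @return list of class \code{ppr_result}: \code{amp1_uv},
#'   \code{amp2_uv}, \code{ratio}, \code{tail_tau_ms} (NA when
#'   uncorrected).
#' @examples
#' sw <- simulate_paired_pulse(ppr = 1.93, noise_sd_uv = 0)
#' paired_pulse_ratio(sw)$ratio
#' @export
paired_pulse_ratio <- function(sweep, correct_overlap = TRUE,
                               response_window_ms = 30) {
  if (length(sweep$stim_times) < 2L) stop("need at least 2 stimuli")
  fs <- sweep$fs
  a1 <- fepsp_amplitude(sweep, 1L, response_window_ms = min(
    response_window_ms, 1000 * diff(sweep$stim_times[1:2]) - 1))
  if (a1 < 1e-9) stop("first response amplitude ~ 0: ratio undefined")
  bl <- baseline_level(sweep)
  tau_ms <- NA_real_
  sweep2 <- sweep
  if (correct_overlap) {
    fit <- fit_response_tail(sweep, bl)
    tau_ms <- fit$tau_ms
    t <- (seq_along(sweep$trace) - 1L) / fs
    pred <- ifelse(t >= fit$t0, fit$a * exp(-(t - fit$t0) / (fit$tau_ms / 1000)), 0)
    sweep2$trace <- sweep$trace - pred
  }
  a2 <- fepsp_amplitude(sweep2, 2L, response_window_ms = response_window_ms)
  structure(list(amp1_uv = a1, amp2_uv = a2, ratio = a2 / a1,
                 tail_tau_ms = tau_ms),
            class = "ppr_result")
}

#' @export
print.ppr_result <- function(x, ...) {
  cat(sprintf("<ppr_result> A1 = %.1f uV, A2 = %.1f uV, PPR = %.3f\n",
              x$amp1_uv, x$amp2_uv, x$ratio))
  invisible(x)
}

# Exponential fit to the decaying tail of response 1 on [peak + 2 ms,
# stim2 - 1 ms], by log-linear regression on the baseline-subtracted
# magnitude.  Returns the signed amplitude at t0 so subtraction preserves
# response polarity.
fit_response_tail <- function(sweep, bl) {
  fs <- sweep$fs
  stim1 <- sweep$stim_times[1L]; stim2 <- sweep$stim_times[2L]
  i0 <- round((stim1 + 0.002) * fs) + 1L
  i1 <- round(stim2 * fs)
  seg <- sweep$trace[i0:i1] - bl
  pk <- which.max(abs(seg))
  sgn <- sign(seg[pk])
  j0 <- pk + round(0.002 * fs)
  j1 <- length(seg) - round(0.001 * fs)
  if (j1 - j0 < 5L) stop("tail window too short for an exponential fit")
  y <- sgn * seg[j0:j1]
  tt <- (seq.int(j0, j1) - j0) / fs
  pos <- y > max(y) * 1e-3
  if (sum(pos) < 5L) stop("tail amplitude too small for an exponential fit")
  co <- stats::coef(stats::lm(log(y[pos]) ~ tt[pos]))
  tau <- -1 / co[[2L]]
  if (!is.finite(tau) || tau <= 0) stop("tail fit did not yield a decay")
  list(a = sgn * exp(co[[1L]]), tau_ms = tau * 1000,
       t0 = (i0 + j0 - 2L) / fs)
}

#' Normalize a daily series to its baseline day
#'
#' @param values numeric vector of daily measurements.
#' @param baseline_index index of the baseline day (default 1).
#' @return values divided by the baseline value.
#' @export
normalize_dynamics <- function(values, baseline_index = 1L) {
  b <- values[baseline_index]
  if (!is.finite(b) || b == 0) stop("baseline value is zero or missing")
  values / b
}
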