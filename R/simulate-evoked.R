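#' Simulate a paired-pulse evoked field-potential sweep
#'
#' Builds a sweep with two stimulus-evoked negative-going fEPSPs at the
#' given inter-stimulus interval (default 40 ms, i.e. 25-Hz paired
#' stimulation).  The second response amplitude equals \code{ppr} times the
#' first before noise is added, so the generator's facilitation ratio is
#' exactly recoverable in the noiseless case.
#'
#' @param ppr paired-pulse ratio (> 0); e.g. 1.93 for intact facilitation,
#'   1.24 for the post-anesthesia impaired regime.
#' @param isi_ms inter-stimulus interval in ms (> 0, default 40).
#' @param amp1_uv first-response amplitude in uV (default 500).
#' @param noise_sd_uv additive Gaussian noise SD in uV.
#' @param fs sampling rate in Hz (default 10000).
#' @param rise_ms,decay_ms fEPSP kernel time constants (ms).
#' @param seed integer seed for the noise.
#' @return an \code{evoked_sweep}: list with \code{trace} (uV),
#'   \code{fs}, \code{stim_times} (s), \code{baseline_window_s} (pre-stimulus
#'   window used for baseline), and \code{truth} (\code{ppr}, \code{amp1_uv},
#'   kernel constants).
#' @export
simulate_paired_pulse <- function(ppr, isi_ms = 40, amp1_uv = 500,
                                  noise_sd_uv = 0, fs = 10000,
                                  rise_ms = 1.5, decay_ms = 10, seed = NULL) {
  stop_if_not_positive(ppr, "ppr")
  stop_if_not_positive(isi_ms, "isi_ms")
  stop_if_not_positive(amp1_uv, "amp1_uv")
  if (noise_sd_uv < 0) stop("'noise_sd_uv' must be non-negative")
  stim1 <- 0.05
  stim_times <- c(stim1, stim1 + isi_ms / 1000)
  total_s <- stim_times[2L] + 0.12
  n <- round(total_s * fs)
  t <- (seq_len(n) - 1L) / fs
  kernel <- function(t0) {
    u <- t - t0
    k <- ifelse(u > 0, (1 - exp(-u / (rise_ms / 1000))) * exp(-u / (decay_ms / 1000)), 0)
    k / max(k)
  }
  trace <- -amp1_uv * kernel(stim_times[1L]) - ppr * amp1_uv * kernel(stim_times[2L])
  if (noise_sd_uv > 0)
    trace <- trace + with_seed(seed, stats::rnorm(n, 0, noise_sd_uv))
  structure(list(trace = trace, fs = fs, stim_times = stim_times,
                 baseline_window_s = c(0, stim1 - 0.005),
                 truth = list(ppr = ppr, amp1_uv = amp1_uv,
                              rise_ms = rise_ms, decay_ms = decay_ms)),
            class = "evoked_sweep")
}

#' @export
print.evoked_sweep <- function(x, ...) {
  cat(sprintf("<evoked_sweep> %d samples at %g Hz, stimuli at %s s\n",
              length(x$trace), x$fs,
              paste(format(x$stim_times), collapse = ", ")))
  invisible(x)
}
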