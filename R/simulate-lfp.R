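#' Burst-suppression generator model
#'
#' Parameters of the synthetic anesthetized LFP: alternating burst and
#' suppression epochs with log-normal durations, pink (1/f) Gaussian
#' background noise whose standard deviation switches between epochs.
#' Bimodality of the rectified-amplitude histogram requires
#' \code{burst_amplitude_sd > suppression_amplitude_sd}.
#'
#' Defaults give a mean suppression-time fraction of
#' \eqn{E[S] / (E[B] + E[S]) = 1/3} (log-normal means
#' \eqn{median \cdot exp(\sigma^2/2)}), inside the 0.2-0.5 BSR regime
#' maintained during the recordings this emulates.
#'
#' @param burst_median,burst_sigma median (s) and log-scale sigma of burst
#'   durations.  \code{sigma = 0} gives fixed durations.
#' @param supp_median,supp_sigma same for suppression durations.
#' @param burst_amplitude_sd,suppression_amplitude_sd background noise SD in
#'   uV during bursts / suppressions.
#' @param spectral_exponent slope alpha of the 1/f^alpha background power
#'   spectrum.
#' @return an object of class \code{bs_model}.
#' @export
bs_model <- function(burst_median = 8, burst_sigma = 0.4,
                     supp_median = 4, supp_sigma = 0.4,
                     burst_amplitude_sd = 25, suppression_amplitude_sd = 5,
                     spectral_exponent = 1) {
  for (nm in c("burst_median", "supp_median", "burst_amplitude_sd",
               "suppression_amplitude_sd"))
    stop_if_not_positive(get(nm), nm)
  if (burst_sigma < 0 || supp_sigma < 0)
    stop("duration sigmas must be non-negative")
  if (burst_amplitude_sd <= suppression_amplitude_sd)
    stop("burst amplitude SD must exceed suppression amplitude SD (bimodality)")
  structure(list(burst_median = burst_median, burst_sigma = burst_sigma,
                 supp_median = supp_median, supp_sigma = supp_sigma,
                 burst_amplitude_sd = burst_amplitude_sd,
                 suppression_amplitude_sd = suppression_amplitude_sd,
                 spectral_exponent = spectral_exponent),
            class = "bs_model")
}

# Gaussian 1/f^alpha noise with unit variance, via spectral shaping.
pink_noise <- function(n, alpha = 1) {
  if (n < 2L) return(stats::rnorm(n))
  w <- stats::rnorm(n)
  shape <- pmin(seq_len(n), n - seq_len(n) + 2L) - 1L  # two-sided frequency index
  shape[1L] <- 1
  gain <- shape^(-alpha / 2)
  gain[1L] <- 0                              # drop DC
  x <- Re(stats::fft(stats::fft(w) * gain, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Simulate a burst-suppression LFP recording with ground truth
#'
#' Draws alternating burst/suppression epochs from the model's duration
#' distributions (starting with a burst), fills each with pink Gaussian
#' noise at the epoch's amplitude SD, and returns the recording together
#' with the exact generative interval labels.
#'
#' @param model a \code{\link{bs_model}}.
#' @param duration_s total duration in seconds (>= 10).
#' @param fs sampling rate in Hz.  The default 2500 Hz keeps the standard
#'   1-1000 Hz analysis band below Nyquist.
#' @param seed integer seed; identical seeds give identical recordings.
#' @param channel_name label for the single generated channel.
#' @return list with elements \code{recording} (a
#'   \code{\link{signal_recording}}) and \code{truth} (list with
#'   \code{intervals} data frame \code{label,start,end}, and empty
#'   \code{ies_times}).
#' @examples
#' sim <- simulate_bs_lfp(bs_model(), duration_s = 60, fs = 500, seed = 1)
#' head(sim$truth$intervals)
#' @export
simulate_bs_lfp <- function(model, duration_s, fs = 2500, seed = NULL,
                            channel_name = "CA1") {
  stopifnot(inherits(model, "bs_model"))
  stop_if_not_positive(duration_s, "duration_s")
  stop_if_not_positive(fs, "fs")
  if (duration_s < 10) stop("'duration_s' must be at least 10 s")
  with_seed(seed, {
    labels <- character(0); durs <- numeric(0); total <- 0; burst <- TRUE
    while (total < duration_s) {
      d <- if (burst) {
        if (model$burst_sigma == 0) model$burst_median
        else stats::rlnorm(1L, log(model$burst_median), model$burst_sigma)
      } else {
        if (model$supp_sigma == 0) model$supp_median
        else stats::rlnorm(1L, log(model$supp_median), model$supp_sigma)
      }
      labels <- c(labels, if (burst) "burst" else "suppression")
      durs <- c(durs, d); total <- total + d; burst <- !burst
    }
    durs[length(durs)] <- durs[length(durs)] - (total - duration_s)
    ends <- cumsum(durs); starts <- c(0, ends[-length(ends)])
    keep <- ends > starts
    intervals <- data.frame(label = labels[keep], start = starts[keep],
                            end = ends[keep], stringsAsFactors = FALSE)

    n <- round(duration_s * fs)
    noise <- pink_noise(n, model$spectral_exponent)
    scale <- rep(model$suppression_amplitude_sd, n)
    bmask <- interval_mask(intervals, "burst", n, fs)
    scale[bmask] <- model$burst_amplitude_sd
    rec <- signal_recording(matrix(noise * scale, ncol = 1L), fs = fs,
                            channel_names = channel_name, state = "GA")
    list(recording = rec,
         truth = list(intervals = intervals,
                      ies_times = stats::setNames(list(numeric(0)), channel_name)))
  })
}

#' Interictal-spike waveform template
#'
#' A biphasic sharp transient built from exponential rise/decay lobes, with
#' its peak-to-peak amplitude normalized to 1 (scaled at injection time).
#' The default 8-ms rise / 20-ms decay keeps the two extrema within 30 ms,
#' so injected events satisfy the standard peak-to-peak detection rule.
#'
#' @param fs sampling rate in Hz.
#' @param rise_ms,decay_ms rise and decay time constants of each lobe (ms).
#' @param lobe_lag_ms delay of the (inverted, smaller) second lobe (ms).
#' @param total_ms template support (ms).
#' @return list with \code{waveform} (unit peak-to-peak), \code{peak_offset}
#'   (samples from template start to the absolute-amplitude peak) and
#'   \code{fs}.
#' @export
ies_template <- function(fs, rise_ms = 8, decay_ms = 20, lobe_lag_ms = 10,
                         total_ms = 80) {
  t <- seq(0, total_ms / 1000, by = 1 / fs)
  lobe <- function(t0) {
    u <- t - t0
    ifelse(u > 0, (1 - exp(-u / (rise_ms / 1000))) * exp(-u / (decay_ms / 1000)), 0)
  }
  w <- lobe(0) - 0.7 * lobe(lobe_lag_ms / 1000)
  w <- w / (max(w) - min(w))
  list(waveform = w, peak_offset = which.max(abs(w)) - 1L, fs = fs)
}

#' Inject interictal spikes into a recording
#'
#' Adds template-shaped transients to one channel, either at explicit times
#' or as a homogeneous Poisson process.  Amplitude is specified in z-units
#' of the recording's suppression-epoch SD (from the ground-truth
#' intervals), making downstream z-based detection gain-invariant.  Events
#' are kept at a pairwise spacing of at least \code{min_spacing_s}
#' (matching the detector dead-time) by dropping violators.
#'
#' @param sim list with \code{recording} and \code{truth}, as returned by
#'   \code{\link{simulate_bs_lfp}}.
#' @param times explicit event times in seconds (the waveform's absolute
#'   peak lands on each time), or \code{NULL} to draw from a Poisson process.
#' @param rate_per_min Poisson rate, events per minute (used when
#'   \code{times} is \code{NULL}).
#' @param amplitude_z target peak-to-peak amplitude in suppression-SD
#'   z-units (default 15).
#' @param channel channel label or index to inject into.
#' @param template an \code{\link{ies_template}}; built at the recording's
#'   fs when \code{NULL}.
#' @param min_spacing_s minimum pairwise spacing (s); set 0 to disable.
#' @param seed integer seed for the Poisson draw.
#' @return an updated \code{list(recording, truth)} with
#'   \code{truth$ies_times[[channel]]} extended by the injected times.
#' @export
inject_ies <- function(sim, times = NULL, rate_per_min = NULL,
                       amplitude_z = 15, channel = 1L, template = NULL,
                       min_spacing_s = 0.05, seed = NULL) {
  rec <- sim$recording; truth <- sim$truth
  stopifnot(inherits(rec, "signal_recording"))
  if (is.null(times) && is.null(rate_per_min))
    stop("give either explicit 'times' or a 'rate_per_min'")
  if (!is.null(rate_per_min) && rate_per_min < 0)
    stop("'rate_per_min' must be non-negative")
  fs <- rec$fs; dur <- duration(rec)
  if (is.character(channel)) channel <- match(channel, rec$channel_names)
  ch_name <- rec$channel_names[channel]
  if (is.null(template)) template <- ies_template(fs)

  if (is.null(times)) {
    times <- with_seed(seed, {
      n_ev <- stats::rpois(1L, rate_per_min * dur / 60)
      sort(stats::runif(n_ev, 0, dur))
    })
  } else times <- sort(times)
  if (min_spacing_s > 0 && length(times) > 1L) {
    keep <- c(TRUE, diff(times) >= min_spacing_s)
    # re-scan because dropping an event can re-expose a violation
    while (any(!keep)) {
      times <- times[keep]
      keep <- if (length(times) > 1L) c(TRUE, diff(times) >= min_spacing_s) else TRUE
    }
  }
  times <- times[times > 0.1 & times < dur - 0.1]

  supp_sd <- suppression_sd(rec, truth$intervals, channel)
  w <- template$waveform * amplitude_z * supp_sd
  x <- rec$samples[, channel]
  for (tt in times) {
    i0 <- round(tt * fs) - template$peak_offset + 1L
    idx <- i0:(i0 + length(w) - 1L)
    ok <- idx >= 1L & idx <= length(x)
    x[idx[ok]] <- x[idx[ok]] + w[ok]
  }
  rec$samples[, channel] <- x
  old <- truth$ies_times[[ch_name]]
  truth$ies_times[[ch_name]] <- sort(c(if (is.null(old)) numeric(0) else old, times))
  list(recording = rec, truth = truth)
}

# SD of one channel over the ground-truth suppression intervals.
suppression_sd <- function(rec, intervals, channel = 1L) {
  mask <- interval_mask(intervals, "suppression", nrow(rec$samples), rec$fs)
  if (sum(mask) < 2L) stop("no suppression samples to reference amplitude against")
  stats::sd(rec$samples[mask, channel])
}
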