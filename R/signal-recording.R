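#' Continuous multi-channel recording
#'
#' A \code{signal_recording} holds one or more continuous voltage channels
#' sampled at a common fixed rate, together with a brain-state label.  Samples
#' are in microvolts (uV) and time is 0-based seconds from recording start;
#' all intervals used by the package are half-open \code{[start, end)}.
#'
#' @param samples numeric matrix, one column per channel (uV).  A plain
#'   vector is accepted for a single channel.
#' @param fs sampling rate in Hz (> 0).
#' @param channel_names character vector of unique channel labels; defaults
#'   to \code{"ch1"}, \code{"ch2"}, ...
#' @param state brain state, \code{"awake"} or \code{"GA"} (general
#'   anesthesia).
#'
#' @return An object of class \code{signal_recording}: a list with elements
#'   \code{samples} (matrix), \code{fs}, \code{channel_names}, \code{state}
#'   and \code{start_time} (fixed at 0).
#' @examples
#' rec <- signal_recording(cbind(rnorm(1000), rnorm(1000)), fs = 500,
#'                         channel_names = c("CA1", "mPFC"), state = "GA")
#' duration(rec)
#' @export
signal_recording <- function(samples, fs, channel_names = NULL,
                             state = c("GA", "awake")) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1L)
  if (!is.matrix(samples) || !is.numeric(samples))
    stop("'samples' must be a numeric matrix (samples x channels)")
  if (anyNA(samples))
    stop("recording contains NA/NaN samples")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("'fs' must be a single positive number (Hz)")
  state <- match.arg(state)
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(ncol(samples)))
  if (length(channel_names) != ncol(samples))
    stop("length of 'channel_names' must match the number of channels")
  if (anyDuplicated(channel_names))
    stop("channel names must be unique")
  colnames(samples) <- channel_names
  structure(list(samples = samples, fs = fs,
                 channel_names = channel_names, state = state,
                 start_time = 0),
            class = "signal_recording")
}

#' @export
print.signal_recording <- function(x, ...) {
  cat(sprintf("<signal_recording> %d channel(s) [%s], fs = %g Hz, %.3f s, state = %s\n",
              ncol(x$samples), paste(x$channel_names, collapse = ", "),
              x$fs, nrow(x$samples) / x$fs, x$state))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec a \code{signal_recording}.
#' @return duration in seconds (n samples / fs).
#' @export
duration <- function(rec) {
  stopifnot(inherits(rec, "signal_recording"))
  nrow(rec$samples) / rec$fs
}

#' Extract one channel as a numeric vector
#' @param rec a \code{signal_recording}.
#' @param channel channel label or index.
#' @return numeric vector of uV samples.
#' @export
channel <- function(rec, channel = 1L) {
  stopifnot(inherits(rec, "signal_recording"))
  if (is.character(channel)) {
    if (!channel %in% rec$channel_names)
      stop(sprintf("channel '%s' not found", channel))
    channel <- match(channel, rec$channel_names)
  }
  rec$samples[, channel]
}

# Interpolate short NaN gaps (<= max_gap_s) linearly; error on longer gaps.
# Amplitude-threshold detectors are sensitive to dropouts, hence the default
# policy elsewhere is to refuse NaN input outright.
fill_na_gaps <- function(x, fs, max_gap_s = 0.010) {
  if (!anyNA(x)) return(x)
  r <- rle(is.na(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  bad <- which(r$values)
  if (any(r$lengths[bad] / fs > max_gap_s))
    stop(sprintf("NaN gap longer than %g ms; refusing to interpolate",
                 max_gap_s * 1000))
  if (is.na(x[1L]) || is.na(x[length(x)]))
    stop("NaN gap at recording edge cannot be interpolated")
  idx <- which(!is.na(x))
  stats::approx(idx, x[idx], xout = seq_along(x))$y
}
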