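#' Detection parameters
#'
#' Defaults implement the suppression-referenced spike rule: bipolar
#' threshold at 10 z-scores of the suppression-epoch baseline, acceptance
#' only if the peak-to-peak excursion within a 30-ms window exceeds the
#' same threshold, and a 50-ms dead-time so one spike is never counted
#' twice.
#'
#' @param z_threshold threshold in z-units (default 10).
#' @param ptp_window_ms peak-to-peak acceptance window in ms (default 30).
#' @param dead_time_ms minimum spacing between accepted events in ms
#'   (default 50).
#' @param baseline_source \code{"suppression_epochs"} (mean/SD over
#'   suppression intervals; requires a segmentation) or
#'   \code{"robust_whole_trace"} (median / 1.4826 MAD of the whole trace,
#'   for awake recordings with no suppression state).
#' @return an object of class \code{detection_params}.
#' @export
detection_params <- function(z_threshold = 10, ptp_window_ms = 30,
                             dead_time_ms = 50,
                             baseline_source = c("suppression_epochs",
                                                 "robust_whole_trace")) {
  for (nm in c("z_threshold", "ptp_window_ms", "dead_time_ms"))
    stop_if_not_positive(get(nm), nm)
  structure(list(z_threshold = z_threshold, ptp_window_ms = ptp_window_ms,
                 dead_time_ms = dead_time_ms,
                 baseline_source = match.arg(baseline_source)),
            class = "detection_params")
}

#' Suppression-referenced z-scoring
#'
#' Standardizes a channel as \code{(x - mean) / sd} with mean and SD taken
#' over the suppression epochs of the segmentation (both statistics from
#' the same reference, keeping the score gain-invariant).  With
#' \code{baseline_source = "robust_whole_trace"} the baseline is the trace
#' median and 1.4826 times the median absolute deviation, for recordings
#' with no suppression state (awake).
#'
#' @param rec a \code{\link{signal_recording}}.
#' @param segmentation a \code{segmentation} (or interval data frame);
#'   required for the suppression baseline, ignored otherwise.
#' @param params a \code{\link{detection_params}}.
#' @param channel channel label or index.
#' @return numeric vector of z-scores, same length as the channel.
#' @export
suppression_zscore <- function(rec, segmentation = NULL,
                               params = detection_params(), channel = 1L) {
  stopifnot(inherits(rec, "signal_recording"))
  x <- channel(rec, channel)
  if (params$baseline_source == "robust_whole_trace") {
    med <- stats::median(x)
    s <- 1.4826 * stats::median(abs(x - med))
    if (s == 0) stop("zero MAD: cannot z-score a constant trace")
    return((x - med) / s)
  }
  if (is.null(segmentation))
    stop("suppression baseline requires a segmentation (or use baseline_source = 'robust_whole_trace')")
  iv <- if (inherits(segmentation, "segmentation")) segmentation$intervals
        else segmentation
  if (interval_time(iv, "suppression") < 5)
    stop("insufficient suppression time (< 5 s); use baseline_source = 'robust_whole_trace'")
  mask <- interval_mask(iv, "suppression", length(x), rec$fs)
  mu <- mean(x[mask]); s <- stats::sd(x[mask])
  if (s == 0) stop("zero suppression SD: cannot z-score")
  (x - mu) / s
}

#' Detect interictal epileptiform spikes on a z-scored signal
#'
#' Candidate events are local extrema of \code{|z|} within contiguous
#' supra-threshold runs (\code{|z| >= z_threshold}, both polarities).  A
#' candidate is accepted if any \code{ptp_window_ms} window containing its
#' peak has \code{max(z) - min(z) > z_threshold}.  Accepted candidates are
#' scanned in time order and any candidate within \code{dead_time_ms} of
#' the last accepted event is suppressed.  Event times are stamped at the
#' absolute-value peak.
#'
#' @param z numeric z-scored signal.
#' @param fs sampling rate in Hz.
#' @param params a \code{\link{detection_params}}.
#' @param channel channel label attached to the output rows.
#' @return data frame of class \code{ies_events} with columns
#'   \code{channel}, \code{time} (s), \code{peak_z}, \code{ptp_z},
#'   \code{polarity} (+1/-1); zero rows when nothing crosses threshold.
#' @export
detect_ies <- function(z, fs, params = detection_params(), channel = "ch1") {
  stopifnot(is.numeric(z))
  empty <- data.frame(channel = character(0), time = numeric(0),
                      peak_z = numeric(0), ptp_z = numeric(0),
                      polarity = integer(0), stringsAsFactors = FALSE)
  class(empty) <- c("ies_events", "data.frame")
  if (!length(z)) return(empty)
  thr <- params$z_threshold
  above <- abs(z) >= thr
  if (!any(above)) return(empty)
  r <- rle(above)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  runs <- which(r$values)
  w <- max(1L, round(params$ptp_window_ms / 1000 * fs))
  n <- length(z)

  cand_idx <- integer(0); cand_ptp <- numeric(0)
  for (k in runs) {
    seg <- run_start[k]:run_end[k]
    p <- seg[which.max(abs(z[seg]))]
    # best peak-to-peak over all w-sample windows containing p
    lo <- max(1L, p - w + 1L)
    hi <- min(n, p + w - 1L)
    win <- z[lo:hi]
    ptp <- slide_ptp(win, w, p - lo + 1L)
    cand_idx <- c(cand_idx, p)
    cand_ptp <- c(cand_ptp, ptp)
  }
  ok <- cand_ptp > thr
  cand_idx <- cand_idx[ok]; cand_ptp <- cand_ptp[ok]
  if (!length(cand_idx)) return(empty)

  dead <- params$dead_time_ms / 1000 * fs
  accept <- logical(length(cand_idx))
  last <- -Inf
  for (i in seq_along(cand_idx)) {
    if (cand_idx[i] - last >= dead) {
      accept[i] <- TRUE
      last <- cand_idx[i]
    }
  }
  idx <- cand_idx[accept]
  out <- data.frame(channel = channel, time = (idx - 1L) / fs,
                    peak_z = z[idx], ptp_z = cand_ptp[accept],
                    polarity = ifelse(z[idx] >= 0, 1L, -1L),
                    stringsAsFactors = FALSE)
  class(out) <- c("ies_events", "data.frame")
  out
}

# Max over all start positions a of (max-min of win[a:(a+w-1)]) such that
# the window covers position p_rel; win is already clipped to [p-w+1, p+w-1].
slide_ptp <- function(win, w, p_rel) {
  m <- length(win)
  if (m <= w) return(max(win) - min(win))
  best <- 0
  for (a in max(1L, p_rel - w + 1L):min(m - w + 1L, p_rel)) {
    s <- win[a:(a + w - 1L)]
    best <- max(best, max(s) - min(s))
  }
  best
}

#' Full detection pipeline on a recording
#'
#' Segments the recording (unless a segmentation is supplied), z-scores the
#' channel against the suppression baseline and runs the spike detector.
#'
#' @param rec a \code{\link{signal_recording}}.
#' @param segmentation optional precomputed \code{segmentation}; computed
#'   with default parameters when \code{NULL} and the baseline needs it.
#' @param params a \code{\link{detection_params}}.
#' @param seg_params a \code{\link{segmentation_params}} used when the
#'   segmentation is computed here.
#' @param channel channel label or index.
#' @return an \code{ies_events} data frame (see \code{\link{detect_ies}}).
#' @export
detect_ies_pipeline <- function(rec, segmentation = NULL,
                                params = detection_params(),
                                seg_params = segmentation_params(),
                                channel = 1L) {
  if (is.null(segmentation) && params$baseline_source == "suppression_epochs")
    segmentation <- segment_bs(rec, seg_params, channel = channel)
  z <- suppression_zscore(rec, segmentation, params, channel)
  ch_name <- if (is.character(channel)) channel else rec$channel_names[channel]
  detect_ies(z, rec$fs, params, channel = ch_name)
}

#' Event rate summary
#'
#' @param events an \code{ies_events} data frame (or any event table with a
#'   \code{channel} column).
#' @param duration_min analyzed duration in minutes (> 0).
#' @return data frame with one row per channel: \code{channel}, \code{n},
#'   \code{duration_min}, \code{rate_per_min}.
#' @export
ies_rate <- function(events, duration_min) {
  stop_if_not_positive(duration_min, "duration_min")
  chans <- unique(events$channel)
  if (!length(chans))
    return(data.frame(channel = character(0), n = integer(0),
                      duration_min = numeric(0), rate_per_min = numeric(0)))
  n <- vapply(chans, function(ch) sum(events$channel == ch), 0L)
  data.frame(channel = chans, n = n, duration_min = duration_min,
             rate_per_min = n / duration_min, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Score detections against ground-truth event times
#'
#' Greedy one-to-one matching: candidate (prediction, truth) pairs within
#' the tolerance are accepted in order of increasing absolute time
#' difference, each event matched at most once.
#'
#' @param pred_times predicted event times (s).
#' @param true_times ground-truth event times (s).
#' @param tolerance_ms matching tolerance in ms (default 25).
#' @return list with \code{precision}, \code{recall}, \code{n_matched}.
#' @export
detection_score <- function(pred_times, true_times, tolerance_ms = 25) {
  stop_if_not_positive(tolerance_ms, "tolerance_ms")
  tol <- tolerance_ms / 1000
  np <- length(pred_times); nt <- length(true_times)
  if (!np || !nt) {
    return(list(precision = if (np) 0 else NA_real_,
                recall = if (nt) 0 else NA_real_,
                n_matched = 0L))
  }
  dmat <- abs(outer(pred_times, true_times, "-"))
  pairs <- which(dmat <= tol, arr.ind = TRUE)
  if (nrow(pairs)) {
    pairs <- pairs[order(dmat[pairs]), , drop = FALSE]
    used_p <- logical(np); used_t <- logical(nt); m <- 0L
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1L]; j <- pairs[k, 2L]
      if (!used_p[i] && !used_t[j]) {
        used_p[i] <- TRUE; used_t[j] <- TRUE; m <- m + 1L
      }
    }
  } else m <- 0L
  list(precision = m / np, recall = m / nt, n_matched = m)
}
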