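#' Read a multi-channel signal from delimited text
#'
#' Reads a rectangular numeric table (comma-separated, "." decimal, mandatory
#' header row) with one column per channel, and attaches the sampling rate.
#' Column order defines channel order; the header supplies channel names.
#' Loaders never resample or rescale: values are taken to be microvolts.
#'
#' @param path path to a CSV file.
#' @param fs sampling rate in Hz.
#' @param state brain-state label for the recording.
#' @param na_action \code{"error"} (default) rejects any missing sample;
#'   \code{"interpolate"} fills NaN gaps up to 10 ms linearly and fails on
#'   longer gaps.
#' @return a \code{\link{signal_recording}}.
#' @export
read_delimited_signal <- function(path, fs, state = c("GA", "awake"),
                                  na_action = c("error", "interpolate")) {
  state <- match.arg(state)
  na_action <- match.arg(na_action)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  nf <- utils::count.fields(path, sep = ",")
  if (length(nf) == 0L) stop(sprintf("empty signal file: %s", path))
  if (length(unique(nf)) != 1L)
    stop(sprintf("ragged rows in %s: first offending row %d",
                 path, which(nf != nf[1L])[1L]))
  tab <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                         strip.white = TRUE)
  if (nrow(tab) == 0L) stop(sprintf("signal file has a header but no samples: %s", path))
  for (j in seq_along(tab)) {
    if (!is.numeric(tab[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(tab[[j]]))))[1L]
      stop(sprintf("non-numeric value in column '%s', data row %d of %s",
                   names(tab)[j], bad, path))
    }
  }
  m <- as.matrix(tab)
  if (anyNA(m)) {
    if (na_action == "error")
      stop(sprintf("missing samples in %s (set na_action = 'interpolate' to fill gaps <= 10 ms)", path))
    m <- apply(m, 2L, fill_na_gaps, fs = fs)
  }
  signal_recording(m, fs = fs, channel_names = colnames(m), state = state)
}

#' Write a recording as delimited text
#'
#' @param rec a \code{\link{signal_recording}}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_delimited_signal <- function(rec, path) {
  stopifnot(inherits(rec, "signal_recording"))
  df <- as.data.frame(rec$samples)
  names(df) <- rec$channel_names
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write event tables
#'
#' An event table records per-channel detected event times (seconds from
#' recording start) with optional named numeric properties.  Times must be
#' non-negative and strictly increasing within a channel.
#'
#' @param events data frame with columns \code{channel}, \code{time} and any
#'   further numeric property columns.
#' @param path CSV path.
#' @return \code{read_events_csv} returns the validated data frame;
#'   \code{write_events_csv} returns \code{path} invisibly.
#' @export
write_events_csv <- function(events, path) {
  validate_event_table(events)
  utils::write.csv(format(events, digits = 15, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  ev <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE)
  validate_event_table(ev)
  ev
}

validate_event_table <- function(events) {
  if (!is.data.frame(events) || !all(c("channel", "time") %in% names(events)))
    stop("event table needs 'channel' and 'time' columns")
  if (nrow(events) && any(events$time < 0))
    stop("event times must be non-negative")
  for (ch in unique(events$channel)) {
    tt <- events$time[events$channel == ch]
    if (is.unsorted(tt, strictly = TRUE))
      stop(sprintf("event times not strictly increasing on channel '%s'", ch))
  }
  invisible(events)
}

#' Read / write burst/suppression interval files
#'
#' Interval files label half-open \code{[start, end)} spans of a recording as
#' \code{"burst"} or \code{"suppression"}.
#'
#' @param intervals data frame with columns \code{label}, \code{start},
#'   \code{end} (seconds).
#' @param path CSV path.
#' @return \code{read_intervals_csv} returns the validated data frame.
#' @export
write_intervals_csv <- function(intervals, path) {
  validate_intervals(intervals)
  utils::write.csv(format(intervals, digits = 15, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_intervals_csv
#' @export
read_intervals_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  iv <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE)
  validate_intervals(iv)
  iv
}

validate_intervals <- function(intervals) {
  if (!is.data.frame(intervals) ||
      !all(c("label", "start", "end") %in% names(intervals)))
    stop("interval table needs 'label', 'start' and 'end' columns")
  if (!all(intervals$label %in% c("burst", "suppression")))
    stop("interval labels must be 'burst' or 'suppression'")
  if (any(intervals$start >= intervals$end))
    stop("intervals must satisfy start < end")
  for (lab in c("burst", "suppression")) {
    iv <- intervals[intervals$label == lab, , drop = FALSE]
    iv <- iv[order(iv$start), , drop = FALSE]
    if (nrow(iv) > 1L && any(iv$start[-1L] < iv$end[-nrow(iv)]))
      stop(sprintf("'%s' intervals overlap", lab))
  }
  invisible(intervals)
}

# Total time (s) covered by rows of an interval table with the given label.
interval_time <- function(intervals, label) {
  iv <- intervals[intervals$label == label, , drop = FALSE]
  if (!nrow(iv)) 0 else sum(iv$end - iv$start)
}

# Logical sample mask for intervals of a label, for a recording of n samples.
interval_mask <- function(intervals, label, n, fs) {
  iv <- intervals[intervals$label == label, , drop = FALSE]
  mask <- logical(n)
  for (k in seq_len(nrow(iv))) {
    i0 <- floor(iv$start[k] * fs) + 1L
    i1 <- min(n, ceiling(iv$end[k] * fs))
    if (i1 >= i0) mask[i0:i1] <- TRUE
  }
  mask
}
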