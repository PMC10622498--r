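#' Segmentation parameters
#'
#' Defaults follow the standard burst-suppression workflow: band-pass
#' 1-1000 Hz, 700-ms rectified-amplitude bins, burst merging across
#' inter-burst gaps shorter than 2 s, acceptance of bursts longer than 2 s,
#' and the burst-suppression ratio (BSR) in 1-min bins.
#'
#' @param band numeric length-2, band-pass edges in Hz.
#' @param bin_width_s rectified-amplitude bin width in seconds.
#' @param merge_gap_s maximum inter-burst gap merged into one burst (s).
#' @param min_burst_s minimum accepted burst duration (s); shorter candidate
#'   bursts are relabelled suppression.
#' @param bsr_bin_s BSR bin width (s).
#' @param fallback_quantile optional quantile in (0, 1) used as the
#'   threshold when the bin histogram has no interior density valley
#'   (default \code{NULL}: raise an error instead).
#' @return an object of class \code{segmentation_params}.
#' @export
segmentation_params <- function(band = c(1, 1000), bin_width_s = 0.7,
                                merge_gap_s = 2, min_burst_s = 2,
                                bsr_bin_s = 60, fallback_quantile = NULL) {
  if (length(band) != 2L || band[1L] <= 0 || band[1L] >= band[2L])
    stop("'band' must satisfy 0 < low < high")
  for (nm in c("bin_width_s", "merge_gap_s", "min_burst_s", "bsr_bin_s"))
    stop_if_not_positive(get(nm), nm)
  if (!is.null(fallback_quantile) &&
      (fallback_quantile <= 0 || fallback_quantile >= 1))
    stop("'fallback_quantile' must be in (0, 1)")
  structure(list(band = band, bin_width_s = bin_width_s,
                 merge_gap_s = merge_gap_s, min_burst_s = min_burst_s,
                 bsr_bin_s = bsr_bin_s, fallback_quantile = fallback_quantile),
            class = "segmentation_params")
}

#' Zero-phase band-pass filter
#'
#' Applies a 4th-order zero-phase Butterworth band-pass (a 2nd-order
#' high-pass and a 2nd-order low-pass, each run forward and backward with
#' \code{signal::filtfilt}; cascading the two halves is numerically better
#' conditioned than one wide band-pass section at high sampling rates).
#'
#' @param rec a \code{\link{signal_recording}}.
#' @param band numeric length-2 band edges in Hz; the upper edge must be
#'   below Nyquist.
#' @return a filtered \code{signal_recording} of the same length.
#' @export
bandpass <- function(rec, band = c(1, 1000)) {
  stopifnot(inherits(rec, "signal_recording"))
  if (length(band) != 2L || band[1L] <= 0 || band[1L] >= band[2L])
    stop("'band' must satisfy 0 < low < high")
  if (band[2L] >= rec$fs / 2)
    stop(sprintf("upper band edge %g Hz is not below Nyquist (%g Hz)",
                 band[2L], rec$fs / 2))
  hp <- signal::butter(2, band[1L] / (rec$fs / 2), type = "high")
  lp <- signal::butter(2, band[2L] / (rec$fs / 2), type = "low")
  out <- rec
  for (j in seq_len(ncol(rec$samples))) {
    x <- signal::filtfilt(hp, rec$samples[, j])
    out$samples[, j] <- signal::filtfilt(lp, x)
  }
  out
}

#' Rectified-amplitude bin series
#'
#' Averages the absolute value of the signal in contiguous bins (default
#' 700 ms); the trailing partial bin is dropped.
#'
#' @param rec a \code{\link{signal_recording}} (first channel is used unless
#'   \code{channel} is given).
#' @param bin_width_s bin width in seconds.
#' @param channel channel label or index.
#' @return an object of class \code{bin_series}: list with \code{starts}
#'   (bin start times, s), \code{values} (mean rectified amplitude, uV) and
#'   \code{bin_width_s}.
#' @export
rectified_bins <- function(rec, bin_width_s = 0.7, channel = 1L) {
  stopifnot(inherits(rec, "signal_recording"))
  stop_if_not_positive(bin_width_s, "bin_width_s")
  x <- abs(channel(rec, channel))
  spb <- round(bin_width_s * rec$fs)
  n_bins <- length(x) %/% spb
  if (n_bins < 2L)
    stop("recording too short: need at least 2 full bins")
  v <- colMeans(matrix(x[seq_len(n_bins * spb)], nrow = spb))
  structure(list(starts = (seq_len(n_bins) - 1L) * bin_width_s,
                 values = v, bin_width_s = bin_width_s),
            class = "bin_series")
}

#' Bimodal valley threshold
#'
#' Locates the amplitude separating the suppression and burst modes of a
#' rectified-amplitude bin histogram: the deepest local minimum of a
#' Gaussian-kernel density estimate (Silverman bandwidth, 512-point grid)
#' between the two largest modes.  The threshold scales exactly with a
#' uniform gain applied to the bins.
#'
#' @param bins a \code{\link{rectified_bins}} result or a numeric vector of
#'   bin values.
#' @param fallback_quantile optional quantile used if no interior valley
#'   exists (see \code{\link{segmentation_params}}).
#' @return threshold in uV.
#' @export
bimodal_threshold <- function(bins, fallback_quantile = NULL) {
  v <- if (inherits(bins, "bin_series")) bins$values else as.numeric(bins)
  if (length(v) < 4L) stop("too few bins for a density estimate")
  if (stats::sd(v) == 0) {
    if (!is.null(fallback_quantile)) return(stats::quantile(v, fallback_quantile)[[1L]])
    stop("no-bimodality: bin values are constant")
  }
  d <- stats::density(v, bw = "nrd0", n = 512)
  y <- d$y
  is_max <- c(FALSE, y[2:511] > y[1:510] & y[2:511] >= y[3:512], FALSE)
  is_min <- c(FALSE, y[2:511] < y[1:510] & y[2:511] <= y[3:512], FALSE)
  peaks <- which(is_max)
  if (length(peaks) < 2L) {
    if (!is.null(fallback_quantile)) return(stats::quantile(v, fallback_quantile)[[1L]])
    stop("no-bimodality: density has fewer than two modes")
  }
  two <- peaks[order(y[peaks], decreasing = TRUE)][1:2]
  lo <- min(two); hi <- max(two)
  valleys <- which(is_min)
  valleys <- valleys[valleys > lo & valleys < hi]
  if (!length(valleys)) {
    if (!is.null(fallback_quantile)) return(stats::quantile(v, fallback_quantile)[[1L]])
    stop("no-bimodality: no density valley between the two main modes")
  }
  d$x[valleys[which.min(y[valleys])]]
}

#' Classify bins into burst and suppression epochs
#'
#' Bins at or above the threshold are burst candidates; candidate bursts
#' separated by less than \code{merge_gap_s} are merged, then merged bursts
#' not longer than \code{min_burst_s} are relabelled suppression
#' (merge-then-accept, in that order).  The BSR series gives the fraction
#' of time in suppression per full \code{bsr_bin_s} window.
#'
#' @param bins a \code{\link{rectified_bins}} result.
#' @param threshold amplitude threshold in uV (from
#'   \code{\link{bimodal_threshold}}).
#' @param params a \code{\link{segmentation_params}}.
#' @return an object of class \code{segmentation}: list with
#'   \code{intervals} (data frame \code{label,start,end} tiling the binned
#'   span), \code{threshold}, \code{bsr} (data frame \code{start,bsr}) and
#'   \code{params}.
#' @export
classify_segments <- function(bins, threshold, params = segmentation_params()) {
  stopifnot(inherits(bins, "bin_series"))
  bw <- bins$bin_width_s
  burst_bin <- bins$values >= threshold
  iv <- runs_to_intervals(burst_bin, bw)

  # merge bursts across short gaps
  b <- iv[iv$label == "burst", , drop = FALSE]
  if (nrow(b) > 1L) {
    keep_sep <- b$start[-1L] - b$end[-nrow(b)] >= params$merge_gap_s
    grp <- cumsum(c(TRUE, keep_sep))
    b <- data.frame(label = "burst",
                    start = tapply(b$start, grp, min),
                    end = tapply(b$end, grp, max), row.names = NULL,
                    stringsAsFactors = FALSE)
  }
  # accept only bursts longer than min_burst_s
  if (nrow(b)) b <- b[b$end - b$start > params$min_burst_s, , drop = FALSE]

  span <- length(bins$values) * bw
  intervals <- complement_to_suppression(b, span)
  bsr <- bsr_series(intervals, span, params$bsr_bin_s)
  structure(list(intervals = intervals, threshold = threshold, bsr = bsr,
                 params = params),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  st <- interval_time(x$intervals, "suppression")
  bt <- interval_time(x$intervals, "burst")
  cat(sprintf("<segmentation> %d bursts, %d suppressions; suppression fraction %.3f; threshold %.3g uV\n",
              sum(x$intervals$label == "burst"),
              sum(x$intervals$label == "suppression"),
              st / (st + bt), x$threshold))
  invisible(x)
}

# TRUE/FALSE runs over bins -> burst/suppression interval table.
runs_to_intervals <- function(flag, bin_width_s) {
  r <- rle(flag)
  ends <- cumsum(r$lengths) * bin_width_s
  starts <- ends - r$lengths * bin_width_s
  data.frame(label = ifelse(r$values, "burst", "suppression"),
             start = starts, end = ends, stringsAsFactors = FALSE)
}

# Given accepted burst intervals, label everything else suppression.
complement_to_suppression <- function(bursts, span) {
  bursts <- bursts[order(bursts$start), , drop = FALSE]
  edges <- c(0, as.vector(rbind(bursts$start, bursts$end)), span)
  out <- list(); lab <- "suppression"
  for (k in seq_len(length(edges) - 1L)) {
    if (edges[k + 1L] > edges[k])
      out[[length(out) + 1L]] <- data.frame(
        label = if (k %% 2L == 1L) "suppression" else "burst",
        start = edges[k], end = edges[k + 1L], stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(label = "suppression", start = 0, end = span,
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# Fraction of time in suppression per full bsr_bin_s window.
bsr_series <- function(intervals, span, bsr_bin_s) {
  n_full <- floor(span / bsr_bin_s + 1e-9)
  if (n_full < 1L)
    return(data.frame(start = numeric(0), bsr = numeric(0)))
  supp <- intervals[intervals$label == "suppression", , drop = FALSE]
  starts <- (seq_len(n_full) - 1L) * bsr_bin_s
  bsr <- vapply(starts, function(s0) {
    s1 <- s0 + bsr_bin_s
    ov <- pmin(supp$end, s1) - pmax(supp$start, s0)
    sum(ov[ov > 0]) / bsr_bin_s
  }, 0)
  data.frame(start = starts, bsr = bsr)
}

#' Segment a recording into burst and suppression epochs
#'
#' Convenience pipeline: band-pass filter, rectified 700-ms bins, bimodal
#' valley threshold, merge-then-accept classification, BSR.
#'
#' @param rec a \code{\link{signal_recording}}.
#' @param params a \code{\link{segmentation_params}}.
#' @param channel channel to segment.
#' @return a \code{segmentation} (see \code{\link{classify_segments}}).
#' @examples
#' sim <- simulate_bs_lfp(bs_model(), 120, fs = 2500, seed = 7)
#' seg <- segment_bs(sim$recording)
#' mean(seg$bsr$bsr)
#' @export
segment_bs <- function(rec, params = segmentation_params(), channel = 1L) {
  filt <- bandpass(rec, params$band)
  bins <- rectified_bins(filt, params$bin_width_s, channel)
  thr <- bimodal_threshold(bins, params$fallback_quantile)
  classify_segments(bins, thr, params)
}

#' Bin-wise segmentation accuracy against ground truth
#'
#' Scores a predicted segmentation against ground-truth intervals as the
#' fraction of \code{bin_width_s} bins whose predicted label matches the
#' label occupying the majority of that bin in the truth.  Both inputs must
#' cover the compared span.
#'
#' @param pred a \code{segmentation}, or an interval data frame.
#' @param truth_intervals ground-truth interval data frame
#'   (\code{label,start,end}).
#' @param bin_width_s scoring bin width (default 0.7 s).
#' @return accuracy in [0, 1].
#' @export
score_segmentation <- function(pred, truth_intervals, bin_width_s = 0.7) {
  pred_iv <- if (inherits(pred, "segmentation")) pred$intervals else pred
  span <- min(max(pred_iv$end), max(truth_intervals$end))
  if (max(pred_iv$end) < max(truth_intervals$end) - bin_width_s - 1e-9 ||
      max(truth_intervals$end) < max(pred_iv$end) - bin_width_s - 1e-9)
    stop("prediction and truth cover different spans")
  n_bins <- floor(span / bin_width_s + 1e-9)
  if (n_bins < 1L) stop("span shorter than one scoring bin")
  mids <- (seq_len(n_bins) - 0.5) * bin_width_s
  mean(label_at(pred_iv, mids, bin_width_s) ==
         label_at(truth_intervals, mids, bin_width_s))
}

# Majority label of each bin centred at mids (width bin_width_s).
label_at <- function(intervals, mids, bin_width_s) {
  supp <- intervals[intervals$label == "suppression", , drop = FALSE]
  s0 <- mids - bin_width_s / 2; s1 <- mids + bin_width_s / 2
  supp_time <- vapply(seq_along(mids), function(i) {
    ov <- pmin(supp$end, s1[i]) - pmax(supp$start, s0[i])
    sum(ov[ov > 0])
  }, 0)
  ifelse(supp_time > bin_width_s / 2, "suppression", "burst")
}
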