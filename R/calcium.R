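#' Filter ROIs by quality metrics
#'
#' Keeps ROIs with peak-to-noise ratio >= 8, size strictly between 30 and
#' 300 pixels, and circularity >= 0.5 (1 = perfect circle).  Size bounds
#' are strict, PNR and circularity bounds inclusive.  Every exclusion is
#' reported with its reason(s).
#'
#' @param rois data frame with columns \code{id}, \code{size_px},
#'   \code{circularity}, \code{pnr}.
#' @param min_pnr,size_range,min_circularity filter thresholds.
#' @return list with \code{kept} (filtered data frame) and
#'   \code{exclusions} (data frame \code{id,reason}).
#' @export
filter_rois <- function(rois, min_pnr = 8, size_range = c(30, 300),
                        min_circularity = 0.5) {
  need <- c("id", "size_px", "circularity", "pnr")
  if (!all(need %in% names(rois)))
    stop(sprintf("ROI table must have columns: %s", paste(need, collapse = ", ")))
  for (col in c("size_px", "circularity", "pnr")) {
    bad <- which(!is.finite(rois[[col]]))
    if (length(bad))
      stop(sprintf("missing/non-finite '%s' for ROI %s", col, rois$id[bad[1L]]))
  }
  fail_pnr <- rois$pnr < min_pnr
  fail_size <- !(rois$size_px > size_range[1L] & rois$size_px < size_range[2L])
  fail_circ <- rois$circularity < min_circularity
  excluded <- fail_pnr | fail_size | fail_circ
  reason <- vapply(seq_len(nrow(rois)), function(i)
    paste(c(if (fail_pnr[i]) "pnr", if (fail_size[i]) "size",
            if (fail_circ[i]) "circularity"), collapse = "+"), "")
  list(kept = rois[!excluded, , drop = FALSE],
       exclusions = data.frame(id = rois$id[excluded],
                               reason = reason[excluded],
                               stringsAsFactors = FALSE))
}

#' Circularity of a binary ROI footprint
#'
#' Standard estimate \code{4 * pi * Area / Perimeter^2} on the footprint
#' binarized at 50 percent of its maximum, for inputs that supply spatial
#' footprints rather than precomputed metrics.  Perimeter is the count of
#' 4-neighbour edges between footprint and background.
#'
#' @param footprint numeric matrix (one ROI's spatial weights).
#' @return circularity estimate (1 = perfect circle; clipped to [0, 1]).
#' @export
roi_circularity <- function(footprint) {
  stopifnot(is.matrix(footprint))
  m <- footprint >= max(footprint) / 2
  area <- sum(m)
  if (!area) stop("empty footprint after binarization")
  pad <- rbind(FALSE, cbind(FALSE, m, FALSE), FALSE)
  nr <- nrow(pad); nc <- ncol(pad)
  perim <- sum(pad[-1L, ] != pad[-nr, ]) + sum(pad[, -1L] != pad[, -nc])
  min(1, 4 * pi * area / perim^2)
}

#' Per-cell event rate
#'
#' Summed inferred spiking activity of a cell divided by the recording
#' time; activity is the unitless deconvolved event weight, so the rate is
#' in those units per second.
#'
#' @param trace nonnegative activity values per frame (one cell).
#' @param duration_s recording time in seconds (> 0).
#' @return events/s.
#' @export
event_rate <- function(trace, duration_s) {
  stop_if_not_positive(duration_s, "duration_s")
  sum(trace) / duration_s
}

#' Session total activity
#'
#' Median of the per-cell rates multiplied by the number of participating
#' cells (even-n medians use the midpoint convention).
#'
#' @param rates per-cell event rates (>= 1 cell).
#' @return total activity.
#' @export
total_activity <- function(rates) {
  if (!length(rates)) stop("no cells: total activity undefined")
  stats::median(rates) * length(rates)
}

#' Summarize one calcium session
#'
#' Applies the ROI filters, computes per-cell event rates and the session
#' total activity.
#'
#' @param session list with \code{activity} (cells x frames), \code{rois},
#'   \code{duration_s} and \code{state}, as from
#'   \code{\link{simulate_ca_matrix}} or assembled from files.
#' @param apply_filter logical; apply \code{\link{filter_rois}} first.
#' @return list of class \code{session_summary}: \code{state},
#'   \code{n_cells}, \code{rates}, \code{total_activity},
#'   \code{exclusions}.
#' @export
summarize_ca_session <- function(session, apply_filter = TRUE) {
  act <- session$activity
  rois <- session$rois
  if (nrow(act) != nrow(rois))
    stop("activity matrix and ROI table disagree on cell count")
  exclusions <- data.frame(id = character(0), reason = character(0))
  if (apply_filter) {
    f <- filter_rois(rois)
    keep <- rois$id %in% f$kept$id
    act <- act[keep, , drop = FALSE]
    exclusions <- f$exclusions
  }
  if (!nrow(act)) stop("no cells remain after filtering")
  rates <- apply(act, 1L, event_rate, duration_s = session$duration_s)
  structure(list(state = session$state, n_cells = nrow(act), rates = rates,
                 total_activity = total_activity(rates),
                 exclusions = exclusions),
            class = "session_summary")
}

#' @export
print.session_summary <- function(x, ...) {
  cat(sprintf("<session_summary> %s: %d cells, median rate %.4g /s, total activity %.4g\n",
              x$state, x$n_cells, stats::median(x$rates), x$total_activity))
  invisible(x)
}

#' Anesthesia state modulation of population activity
#'
#' Total activity under general anesthesia divided by total activity while
#' awake for the same paired session (same animal and day); 1 means no
#' suppression by anesthesia.
#'
#' @param ga,awake \code{session_summary} objects for the GA and awake
#'   halves of a paired session.
#' @return modulation ratio.
#' @export
state_modulation <- function(ga, awake) {
  stopifnot(inherits(ga, "session_summary"), inherits(awake, "session_summary"))
  if (awake$total_activity == 0) stop("awake total activity is zero")
  ga$total_activity / awake$total_activity
}
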