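#' Calcium-activity simulation model
#'
#' Parameters of the synthetic post-deconvolution calcium activity: per-cell
#' event rates drawn from a log-normal distribution, a multiplicative
#' state-modulation factor applied to rates during general anesthesia, and a
#' frame rate matching 10-Hz miniscope imaging.
#'
#' @param n_cells number of cells (> 0).
#' @param rate_meanlog,rate_sdlog log-scale mean and SD of per-cell event
#'   rates (events/s).
#' @param state_modulation multiplicative factor on rates under GA relative
#'   to awake (1 = no state dependence, as in the disinhibited phenotype;
#'   < 1 = physiological suppression by anesthesia).
#' @param frame_rate imaging frame rate in Hz (default 10).
#' @param frac_fail_roi fraction of simulated ROIs given quality metrics
#'   that fail the standard filters (PNR < 8, size outside (30, 300) px or
#'   circularity < 0.5).
#' @return an object of class \code{ca_model}.
#' @export
ca_model <- function(n_cells = 100, rate_meanlog = log(0.1), rate_sdlog = 0.8,
                     state_modulation = 0.5, frame_rate = 10,
                     frac_fail_roi = 0.2) {
  stop_if_not_positive(n_cells, "n_cells")
  stop_if_not_positive(frame_rate, "frame_rate")
  if (state_modulation < 0) stop("'state_modulation' must be non-negative")
  if (frac_fail_roi < 0 || frac_fail_roi > 1)
    stop("'frac_fail_roi' must be in [0, 1]")
  structure(list(n_cells = as.integer(n_cells), rate_meanlog = rate_meanlog,
                 rate_sdlog = rate_sdlog, state_modulation = state_modulation,
                 frame_rate = frame_rate, frac_fail_roi = frac_fail_roi),
            class = "ca_model")
}

#' Simulate a deconvolved calcium-activity session
#'
#' Draws per-cell base rates (log-normal), applies the model's GA
#' modulation when \code{state = "GA"}, and emits a cells-by-frames matrix
#' of Poisson event counts plus ROI quality metadata.  Base rates depend on
#' the seed only, so two calls with the same seed and different states
#' produce a paired awake/GA session of the same cells.
#'
#' @param model a \code{\link{ca_model}}.
#' @param duration_s session duration in seconds.
#' @param seed integer seed.
#' @param state \code{"awake"} or \code{"GA"}.
#' @return list with \code{activity} (n_cells x n_frames matrix of event
#'   weights), \code{rois} (data frame \code{id,size_px,circularity,pnr}),
#'   \code{frame_rate}, \code{duration_s}, \code{state} and \code{truth}
#'   (list with \code{rates} in events/s after state modulation and
#'   \code{passes_filter} flags).
#' @export
simulate_ca_matrix <- function(model, duration_s, seed = NULL,
                               state = c("awake", "GA")) {
  stopifnot(inherits(model, "ca_model"))
  stop_if_not_positive(duration_s, "duration_s")
  state <- match.arg(state)
  n_frames <- round(duration_s * model$frame_rate)
  with_seed(seed, {
    base_rates <- stats::rlnorm(model$n_cells, model$rate_meanlog,
                                model$rate_sdlog)
    n_fail <- round(model$frac_fail_roi * model$n_cells)
    fail <- rep(FALSE, model$n_cells)
    if (n_fail > 0L) fail[sample.int(model$n_cells, n_fail)] <- TRUE
    size <- round(stats::runif(model$n_cells, 60, 250))
    circ <- stats::runif(model$n_cells, 0.6, 0.95)
    pnr <- stats::runif(model$n_cells, 9, 40)
    if (n_fail > 0L) {
      which_fail <- which(fail)
      mode <- sample.int(3L, length(which_fail), replace = TRUE)
      pnr[which_fail[mode == 1L]] <- stats::runif(sum(mode == 1L), 2, 7.9)
      size[which_fail[mode == 2L]] <- sample(c(10:30, 300:400),
                                             sum(mode == 2L), replace = TRUE)
      circ[which_fail[mode == 3L]] <- stats::runif(sum(mode == 3L), 0.1, 0.45)
    }
    rates <- base_rates * if (state == "GA") model$state_modulation else 1
    activity <- matrix(stats::rpois(model$n_cells * n_frames,
                                    rep(rates / model$frame_rate, n_frames)),
                       nrow = model$n_cells)
    rois <- data.frame(id = sprintf("roi%03d", seq_len(model$n_cells)),
                       size_px = size, circularity = circ, pnr = pnr,
                       stringsAsFactors = FALSE)
    list(activity = activity, rois = rois, frame_rate = model$frame_rate,
         duration_s = duration_s, state = state,
         truth = list(rates = rates, passes_filter = !fail))
  })
}
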