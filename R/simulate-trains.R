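#' Simulate a pair of coupled event trains
#'
#' Generates a reference train (homogeneous Poisson) and a target train in
#' which a fraction \code{coupling_prob} of events is time-locked to a
#' randomly chosen reference event with Gaussian lag jitter, the remainder
#' being an independent homogeneous Poisson process.  This is the substrate
#' for the jitter-surrogate synchrony test: coupling at millisecond lags
#' with slow rate structure preserved.
#'
#' @param ref_rate,target_rate event rates in events/min.
#' @param coupling_prob fraction of target events locked to a reference
#'   event, in [0, 1].
#' @param lag_jitter_sd_ms SD of the Gaussian lag of coupled events (ms).
#' @param duration_s total duration in seconds (> 0).
#' @param seed integer seed.
#' @return list with \code{ref} and \code{target} (sorted time vectors, s),
#'   \code{duration_s}, and \code{truth} containing \code{coupled_flags}
#'   (per target event, in time order).
#' @examples
#' tr <- simulate_coupled_trains(3, 3, coupling_prob = 1,
#'                               lag_jitter_sd_ms = 5,
#'                               duration_s = 600, seed = 1)
#' @export
simulate_coupled_trains <- function(ref_rate, target_rate, coupling_prob,
                                    lag_jitter_sd_ms = 5, duration_s,
                                    seed = NULL) {
  if (ref_rate < 0 || target_rate < 0) stop("rates must be non-negative")
  if (coupling_prob < 0 || coupling_prob > 1)
    stop("'coupling_prob' must be in [0, 1]")
  stop_if_not_positive(duration_s, "duration_s")
  with_seed(seed, {
    ref <- sort(stats::runif(stats::rpois(1L, ref_rate * duration_s / 60),
                             0, duration_s))
    n_coupled <- stats::rpois(1L, coupling_prob * target_rate * duration_s / 60)
    n_indep <- stats::rpois(1L, (1 - coupling_prob) * target_rate * duration_s / 60)
    coupled <- numeric(0)
    if (n_coupled > 0L) {
      if (!length(ref)) stop("cannot couple target events to an empty reference train")
      anchors <- ref[sample.int(length(ref), n_coupled, replace = TRUE)]
      coupled <- anchors + stats::rnorm(n_coupled, 0, lag_jitter_sd_ms / 1000)
    }
    indep <- stats::runif(n_indep, 0, duration_s)
    target <- c(coupled, indep)
    flags <- c(rep(TRUE, length(coupled)), rep(FALSE, length(indep)))
    inside <- target >= 0 & target < duration_s
    target <- target[inside]; flags <- flags[inside]
    o <- order(target)
    list(ref = ref, target = target[o], duration_s = duration_s,
         truth = list(coupled_flags = flags[o]))
  })
}
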