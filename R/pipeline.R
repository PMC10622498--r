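#' Run the full analysis on one anesthetized-session recording
#'
#' Fixed stage order: segment the recording into burst/suppression epochs,
#' z-score each channel against its suppression baseline, detect spikes,
#' summarize rates, and (for two or more channels with events) run the
#' jitter-surrogate synchrony test between the first two channels.  The
#' report carries a provenance block (parameter hash, seed, package
#' version), and rerunning with the same inputs and seed reproduces it
#' exactly.
#'
#' @param rec a \code{\link{signal_recording}} (state \code{"GA"}).
#' @param seg_params a \code{\link{segmentation_params}}.
#' @param det_params a \code{\link{detection_params}}.
#' @param jit_params a \code{\link{jitter_params}}.
#' @param seed integer seed (surrogate jitters).
#' @return an object of class \code{run_report}: list with
#'   \code{segmentation}, \code{events}, \code{rates}, \code{synchrony}
#'   (or \code{NULL}), \code{provenance}.
#' @export
run_ga_session <- function(rec, seg_params = segmentation_params(),
                           det_params = detection_params(),
                           jit_params = jitter_params(), seed = 1L) {
  stopifnot(inherits(rec, "signal_recording"))
  if (rec$state != "GA")
    stop("run_ga_session expects a general-anesthesia recording")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  seg <- stage("segment", segment_bs(rec, seg_params, channel = 1L))
  ev <- stage("detect", {
    per_ch <- lapply(seq_along(rec$channel_names), function(j) {
      z <- suppression_zscore(rec, seg, det_params, channel = j)
      detect_ies(z, rec$fs, det_params, channel = rec$channel_names[j])
    })
    do.call(rbind, per_ch)
  })
  rates <- stage("rate", ies_rate(ev, duration(rec) / 60))
  sync <- NULL
  if (length(rec$channel_names) >= 2L) {
    t1 <- ev$time[ev$channel == rec$channel_names[1L]]
    t2 <- ev$time[ev$channel == rec$channel_names[2L]]
    if (length(t1) && length(t2))
      sync <- stage("synchrony",
                    jitter_test(t1, t2, duration(rec), jit_params, seed = seed))
  }
  cfg <- list(seg = unclass(seg_params), det = unclass(det_params),
              jit = unclass(jit_params), seed = seed)
  structure(list(segmentation = seg, events = ev, rates = rates,
                 synchrony = sync,
                 provenance = list(config_hash = config_hash(cfg),
                                   seed = seed,
                                   package_version =
                                     as.character(utils::packageVersion("ieskit")))),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  print(x$segmentation)
  cat(sprintf("  mean BSR: %.3f\n", mean(x$segmentation$bsr$bsr)))
  print(x$rates)
  if (!is.null(x$synchrony)) print(x$synchrony)
  cat(sprintf("  config %s, seed %d\n", x$provenance$config_hash,
              x$provenance$seed))
  invisible(x)
}

# md5 of the canonical JSON form of a parameter list.
config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(cfg, tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

#' Serialize / restore run parameters as JSON
#'
#' @param seg_params,det_params,jit_params parameter objects.
#' @param path JSON path.
#' @return \code{read_run_config} returns a list with the three rebuilt
#'   parameter objects and the seed.
#' @param seed integer seed stored with the configuration.
#' @export
write_run_config <- function(path, seg_params = segmentation_params(),
                             det_params = detection_params(),
                             jit_params = jitter_params(), seed = 1L) {
  cfg <- list(seg = unclass(seg_params), det = unclass(det_params),
              jit = unclass(jit_params), seed = seed)
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(seg_params = do.call(segmentation_params,
                            cfg$seg[setdiff(names(cfg$seg), character(0))]),
       det_params = do.call(detection_params, cfg$det),
       jit_params = do.call(jitter_params, cfg$jit),
       seed = cfg$seed)
}

#' Segmentation-accuracy study on synthetic recordings
#'
#' Generates seeded synthetic burst-suppression recordings, segments each
#' with the given parameters and scores bin-wise accuracy against the
#' generative labels.
#'
#' @param n_recordings number of recordings.
#' @param duration_s duration of each (s).
#' @param fs sampling rate (Hz).
#' @param model a \code{\link{bs_model}}.
#' @param params a \code{\link{segmentation_params}}.
#' @param seeds integer vector of per-recording seeds (length
#'   \code{n_recordings}).
#' @return list with \code{accuracies} (per recording) and
#'   \code{mean_accuracy}.
#' @export
segmentation_accuracy_study <- function(n_recordings = 20, duration_s = 600,
                                        fs = 2500, model = bs_model(),
                                        params = segmentation_params(),
                                        seeds = seq_len(n_recordings)) {
  stopifnot(length(seeds) == n_recordings)
  acc <- vapply(seeds, function(s) {
    sim <- simulate_bs_lfp(model, duration_s, fs = fs, seed = s)
    seg <- segment_bs(sim$recording, params)
    score_segmentation(seg, sim$truth$intervals, params$bin_width_s)
  }, 0)
  list(accuracies = acc, mean_accuracy = mean(acc))
}

#' Empirical null rejection rate of the jitter test
#'
#' Simulates replicate pairs of independent homogeneous Poisson trains and
#' reports the fraction declared significant by the exceed-all-surrogates
#' criterion — the empirical type-I error of the synchrony test.
#'
#' @param n_replicates number of replicate pairs.
#' @param rate_per_min Poisson rate of both trains (events/min).
#' @param duration_s duration of each pair (s).
#' @param half_width_ms analysis half-width (ms).
#' @param n_surrogates surrogates per test.
#' @param seed master integer seed.
#' @return list with \code{rejection_fraction}, \code{n_replicates},
#'   \code{nominal} (1 / (n_surrogates + 1)) and \code{se_binomial} at the
#'   nominal level.
#' @export
jitter_null_study <- function(n_replicates = 5000, rate_per_min = 3,
                              duration_s = 1800, half_width_ms = 100,
                              n_surrogates = 1000, seed = 1L) {
  params <- jitter_params(half_widths_ms = half_width_ms,
                          n_surrogates = n_surrogates)
  rej <- vapply(seq_len(n_replicates), function(i) {
    tr <- simulate_coupled_trains(rate_per_min, rate_per_min,
                                  coupling_prob = 0,
                                  duration_s = duration_s,
                                  seed = derive_seed(seed, i))
    if (!length(tr$ref) || !length(tr$target)) return(FALSE)
    jt <- jitter_test(tr$ref, tr$target, duration_s, params,
                      seed = derive_seed(seed, 1000000 + i))
    jt$significant[1L]
  }, NA)
  nominal <- 1 / (n_surrogates + 1)
  list(rejection_fraction = mean(rej), n_replicates = n_replicates,
       nominal = nominal,
       se_binomial = sqrt(nominal * (1 - nominal) / n_replicates))
}

#' Run the built-in acceptance suite
#'
#' Executes the package's two headline synthetic-validation studies — the
#' segmentation-accuracy study and the jitter-test null-rejection study —
#' at a configurable scale, and returns a machine-readable pass/fail
#' table.  \code{scale = 1} runs the full study sizes (20 recordings /
#' 5000 replicates).
#'
#' @param seed master integer seed.
#' @param scale scale factor on study sizes.
#' @return data frame with columns \code{check}, \code{value}, \code{n},
#'   \code{criterion}, \code{pass}.
#' @export
run_acceptance_suite <- function(seed = 1L, scale = 1) {
  n_rec <- max(2L, round(20 * scale))
  n_rep <- max(50L, round(5000 * scale))
  seg <- segmentation_accuracy_study(
    n_recordings = n_rec,
    seeds = vapply(seq_len(n_rec), function(k) derive_seed(seed, k), 0L))
  jit <- jitter_null_study(n_replicates = n_rep, seed = derive_seed(seed, 777))
  tol <- 3 * jit$se_binomial
  data.frame(
    check = c("segmentation_accuracy_mean", "jitter_null_rejection"),
    value = c(seg$mean_accuracy, jit$rejection_fraction),
    n = c(n_rec, n_rep),
    criterion = c(">= 0.92",
                  sprintf("within %.2g of %.4g", tol, jit$nominal)),
    pass = c(seg$mean_accuracy >= 0.92,
             abs(jit$rejection_fraction - jit$nominal) <= tol),
    stringsAsFactors = FALSE)
}
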