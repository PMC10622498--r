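# Internal helpers shared across modules.

# Evaluate expr with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
      stop("'seed' must be a single integer")
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Deterministic sub-seed fan-out: module-level seeds derived from one master
# seed by a fixed affine step, kept below 2^31.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1000 + k) %% 2147483647)
}

stop_if_not_positive <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive number", what))
  invisible(x)
}
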