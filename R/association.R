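#' Alternation success rate
#'
#' Percentage of correct alternations relative to the number of trials in
#' one delayed-alternation session.
#'
#' @param correct number of correct alternations.
#' @param trials number of trials (>= 1).
#' @return success rate in percent.
#' @export
success_rate <- function(correct, trials) {
  if (trials < 1) stop("'trials' must be at least 1")
  if (correct < 0 || correct > trials)
    stop("'correct' must be between 0 and 'trials'")
  100 * correct / trials
}

#' Spearman rank correlation with exact permutation p-value
#'
#' Computes Spearman's rho on mid-ranks (average ties) with a two-sided
#' p-value: full enumeration of all n! permutations for n <= 8, Monte
#' Carlo with 1e5 permutations for 9 <= n <= 12 (the typical group sizes
#' in small-animal studies, where the asymptotic approximation is
#' unreliable), and the asymptotic t approximation for larger n.  The
#' asymptotic p is reported alongside in all cases.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param method \code{"auto"} (rule above), \code{"exact"} (enumeration,
#'   n <= 8 only), \code{"montecarlo"} or \code{"asymptotic"}.
#' @param n_mc Monte-Carlo permutation count.
#' @param seed integer seed for the Monte-Carlo branch.
#' @return list of class \code{correlation_result}: \code{rho}, \code{p}
#'   (by the selected method), \code{p_asymptotic}, \code{n},
#'   \code{method}.
#' @examples
#' spearman_assoc(1:8, c(2, 1, 4, 3, 6, 5, 8, 7))
#' @export
spearman_assoc <- function(x, y, method = c("auto", "exact", "montecarlo",
                                            "asymptotic"),
                           n_mc = 1e5, seed = NULL) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("rho undefined for a constant input vector")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  p_asym <- spearman_p_asymptotic(rho, n)
  if (method == "auto")
    method <- if (n <= 8L) "exact" else if (n <= 12L) "montecarlo" else "asymptotic"
  p <- switch(method,
    exact = {
      if (n > 8L) stop("full enumeration limited to n <= 8")
      rhos <- apply(permutations_of(n), 1L, function(pm) stats::cor(rx, ry[pm]))
      mean(abs(rhos) >= abs(rho) - 1e-12)
    },
    montecarlo = with_seed(seed, {
      hits <- sum(vapply(seq_len(n_mc), function(i)
        abs(stats::cor(rx, sample(ry))) >= abs(rho) - 1e-12, NA))
      (1 + hits) / (n_mc + 1)
    }),
    asymptotic = p_asym)
  structure(list(rho = rho, p = p, p_asymptotic = p_asym, n = n,
                 method = method),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> Spearman rho = %.4f, p = %.4g (%s), n = %d\n",
              x$rho, x$p, x$method, x$n))
  invisible(x)
}

spearman_p_asymptotic <- function(rho, n) {
  if (abs(rho) >= 1) return(2 / factorial(min(n, 170)))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(-abs(tstat), df = n - 2)
}

# All permutations of 1..n as a matrix (n! rows), recursively.
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 0L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (r in seq_len(nrow(sub))) {
      row <- row + 1L
      out[row, ] <- c(k, rest[sub[r, ]])
    }
  }
  out
}
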