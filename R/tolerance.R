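#' Wilks nonparametric tolerance interval
#'
#' Two-sided distribution-free tolerance interval from the sample extremes
#' (the classical order-statistic construction): the interval is
#' `(min(x), max(x))` and the probability mass it covers follows a
#' `Beta(n - 1, 2)` law regardless of the sampled distribution. The
#' achieved confidence that the interval covers at least a proportion
#' `coverage_p` of the population is therefore
#' `1 - pbeta(coverage_p, n - 1, 2)`. When that confidence falls short of
#' `confidence_gamma` the interval is still returned, flagged
#' `insufficient_n`, with a warning.
#'
#' @param samples Numeric vector (length >= 2, finite).
#' @param coverage_p Population proportion to cover (0 < p < 1); default
#'   0.90.
#' @param confidence_gamma Required confidence level (0 < gamma < 1);
#'   default 0.95.
#' @return An object of class `tolerance_interval`: `lower`, `upper`,
#'   `coverage_p`, `confidence_gamma`, `n`, `achieved_confidence`,
#'   `insufficient_n`.
#' @seealso [min_sample_size()]
#' @export
#' @examples
#' wilks_ti(rnorm(100))
wilks_ti <- function(samples, coverage_p = 0.90, confidence_gamma = 0.95) {
  samples <- samples[!is.na(samples)]
  if (length(samples) < 2) {
    ct_stop("at least 2 finite samples are required", "cthazard_input_error")
  }
  if (any(!is.finite(samples))) {
    ct_stop("samples must be finite", "cthazard_input_error")
  }
  if (coverage_p <= 0 || coverage_p >= 1 || confidence_gamma <= 0 || confidence_gamma >= 1) {
    ct_stop("coverage_p and confidence_gamma must lie in (0, 1)",
            "cthazard_invalid_argument")
  }
  n <- length(samples)
  achieved <- 1 - stats::pbeta(coverage_p, n - 1, 2)
  insufficient <- achieved < confidence_gamma
  if (insufficient) {
    ct_warn(sprintf(
      "n = %d gives confidence %.3f < %.3f for %.0f%% coverage (need n >= %d)",
      n, achieved, confidence_gamma, 100 * coverage_p,
      min_sample_size(coverage_p, confidence_gamma)
    ), "cthazard_insufficient_n")
  }
  structure(
    list(
      lower = min(samples), upper = max(samples),
      coverage_p = coverage_p, confidence_gamma = confidence_gamma,
      n = n, achieved_confidence = achieved,
      insufficient_n = insufficient
    ),
    class = "tolerance_interval"
  )
}

#' @export
print.tolerance_interval <- function(x, ...) {
  cat(sprintf(
    "<tolerance_interval> (%.3f, %.3f), %.0f%%/%.0f%% (coverage/confidence), n = %d, achieved %.4f%s\n",
    x$lower, x$upper, 100 * x$coverage_p, 100 * x$confidence_gamma, x$n,
    x$achieved_confidence, if (x$insufficient_n) " [insufficient n]" else ""
  ))
  invisible(x)
}

#' Minimum sample size for the two-sided Wilks interval
#'
#' Smallest `n` such that the interval from the sample extremes covers at
#' least a proportion `coverage_p` of the population with confidence at
#' least `confidence_gamma`, i.e. the smallest `n` with
#' `1 - pbeta(coverage_p, n - 1, 2) >= confidence_gamma`. Monotone
#' nondecreasing in both arguments.
#'
#' @inheritParams wilks_ti
#' @return An integer sample size (>= 2).
#' @export
#' @examples
#' min_sample_size(0.90, 0.95)   # 46
min_sample_size <- function(coverage_p, confidence_gamma) {
  if (coverage_p <= 0 || coverage_p >= 1 || confidence_gamma <= 0 || confidence_gamma >= 1) {
    ct_stop("coverage_p and confidence_gamma must lie in (0, 1)",
            "cthazard_invalid_argument")
  }
  n <- 2L
  while (1 - stats::pbeta(coverage_p, n - 1, 2) < confidence_gamma) {
    n <- n + 1L
  }
  n
}
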