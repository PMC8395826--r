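#' Calibrate a lognormal distribution from a median and interquartile range
#'
#' Reference tables for TREC/KREC copy numbers report medians and IQRs per
#' gestational-age stratum, not distribution parameters. Copies-per-well
#' distributions are strictly positive and right-skewed, so each stratum is
#' modelled as lognormal and calibrated so that the distribution's median and
#' quartile ratio reproduce the reported summary exactly:
#' `mu = ln(median)` and `sigma = ln(q3/q1) / (2 * z_0.75)` with
#' `z_0.75 = qnorm(0.75) = 0.674490`.
#'
#' @param median Median of the target distribution (copies/well), > 0.
#' @param q1,q3 First and third quartile (copies/well); must satisfy
#'   `0 < q1 <= median <= q3`.
#' @return A list with components `mu` (meanlog) and `sigma` (sdlog), directly
#'   usable with [stats::rlnorm()].
#' @examples
#' lognormal_from_median_iqr(79, 55, 110)
#' @export
lognormal_from_median_iqr <- function(median, q1, q3) {
  if (!is.numeric(median) || !is.numeric(q1) || !is.numeric(q3)) {
    stop("quantiles must be numeric", call. = FALSE)
  }
  if (any(q1 <= 0) || any(median <= 0) || any(q3 <= 0)) {
    stop("invalid parameters: quantiles must be strictly positive", call. = FALSE)
  }
  if (any(q1 > median) || any(median > q3)) {
    stop("invalid parameters: need q1 <= median <= q3", call. = FALSE)
  }
  z75 <- stats::qnorm(0.75)
  list(mu = log(median), sigma = log(q3 / q1) / (2 * z75))
}
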