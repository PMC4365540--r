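# Percentile primitives underlying subgroup-specific centering.
#
# The forward map (value -> percentile) and the inverse (percentile -> value)
# must round-trip exactly on observed values, otherwise the method would not
# reproduce the training baseline when the study cohort IS the training
# subgroup. The pair used here is the midpoint empirical CDF and its exact
# piecewise-linear inverse (the type-5 quantile of Hyndman & Fan's taxonomy).

#' Percentile of a value within an empirical distribution
#'
#' Returns the percentile at which `x` sits within `values` under the midpoint
#' empirical-CDF convention: `100 * (#\{v < x\} + 0.5 * #\{v = x\}) / n`. For a
#' tie-free vector this places the i-th order statistic at
#' `100 * (i - 0.5) / n`; tied blocks are averaged symmetrically. The map is
#' monotone non-decreasing in `x`, returns 0 below the minimum and 100 above
#' the maximum, and is the exact inverse of [quantileAt()] on observed values.
#'
#' @param values numeric vector; `NA`s are dropped. Must contain at least one
#'   non-missing value.
#' @param x numeric vector of query values (vectorised).
#' @return numeric vector of percentiles in `[0, 100]`, one per `x`.
#'
#' @examples
#' percentileOfValue(c(1, 2, 3, 4, 5), 3)  # 50
#' @seealso [quantileAt()]
#' @export
percentileOfValue <- function(values, x) {
  v <- values[!is.na(values)]
  if (length(v) == 0L) stop("'values' must contain at least one non-NA value")
  if (any(!is.finite(v))) stop("'values' must be finite")
  n <- length(v)
  vapply(x, function(xi) {
    if (is.na(xi)) return(NA_real_)
    100 * (sum(v < xi) + 0.5 * sum(v == xi)) / n
  }, numeric(1))
}

#' Value at a given percentile of an empirical distribution
#'
#' The piecewise-linear inverse of [percentileOfValue()]: linear interpolation
#' between order statistics placed at percentiles `100 * (i - 0.5) / n`
#' (`stats::quantile()` type 5), clamped to the observed minimum/maximum
#' outside that range. For any `x` in `values` (tie-free),
#' `quantileAt(values, percentileOfValue(values, x)) == x`.
#'
#' @param values numeric vector; `NA`s are dropped. Must contain at least one
#'   non-missing value.
#' @param q numeric vector of percentiles in `[0, 100]` (vectorised).
#' @return numeric vector of expression values, one per `q`.
#'
#' @examples
#' quantileAt(c(1, 2, 3, 4, 5), 50)  # 3
#' @seealso [percentileOfValue()]
#' @export
quantileAt <- function(values, q) {
  v <- values[!is.na(values)]
  if (length(v) == 0L) stop("'values' must contain at least one non-NA value")
  if (any(!is.finite(v))) stop("'values' must be finite")
  if (any(is.na(q)) || any(q < 0) || any(q > 100)) {
    stop("'q' must lie within [0, 100]")
  }
  unname(quantile(v, probs = q / 100, type = 5, names = FALSE))
}

#' Percentile of a value under a weighted empirical distribution
#'
#' Weighted analogue of [percentileOfValue()]:
#' `100 * (sum(w[v < x]) + 0.5 * sum(w[v = x])) / sum(w)`. With equal weights
#' it reduces exactly to the unweighted midpoint convention.
#'
#' @param values numeric vector.
#' @param weights non-negative weights, same length as `values`; pairs with
#'   `NA` values are dropped.
#' @param x single numeric query value.
#' @return percentile in `[0, 100]`.
#' @keywords internal
#' @noRd
weightedPercentileOfValue <- function(values, weights, x) {
  keep <- !is.na(values)
  v <- values[keep]
  w <- weights[keep]
  if (length(v) == 0L) stop("no non-missing values")
  if (any(w < 0) || sum(w) <= 0) stop("weights must be non-negative, sum > 0")
  100 * (sum(w[v < x]) + 0.5 * sum(w[v == x])) / sum(w)
}
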