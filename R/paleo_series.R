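#' Paleoclimate proxy series
#'
#' A `paleo_series` holds a proxy curve (e.g. benthic \eqn{\delta^{18}}O,
#' atmospheric CO2 in ppm, sea level in m) as paired ages and values. Ages
#' are My before present, strictly increasing, with the present at 0. The
#' proxy is used on its own scale throughout (no conversion of
#' \eqn{\delta^{18}}O to degrees: higher \eqn{\delta^{18}}O means cooler).
#'
#' @param age numeric vector of ages (My, >= 0), need not be sorted.
#' @param value proxy values, same length as `age`.
#' @param unit free-text unit tag carried as metadata.
#' @return a data frame of class `paleo_series` with columns `age`, `value`.
#' @export
paleo_series <- function(age, value, unit = "") {
  if (length(age) != length(value)) stop("age and value must have equal length")
  if (length(age) < 2L) stop("a paleo_series needs at least 2 points")
  if (any(!is.finite(age)) || any(!is.finite(value))) stop("non-finite age or value")
  if (any(age < 0)) stop("ages must be >= 0 (My before present)")
  o <- order(age)
  age <- age[o]; value <- value[o]
  if (any(diff(age) <= 0)) stop("ages must be unique")
  structure(data.frame(age = age, value = value),
            class = c("paleo_series", "data.frame"), unit = unit)
}

#' @export
print.paleo_series <- function(x, ...) {
  cat(sprintf("Paleoclimate series: %d points, %.4g-%.4g My%s\n",
              nrow(x), min(x$age), max(x$age),
              if (nzchar(attr(x, "unit"))) paste0(", unit: ", attr(x, "unit")) else ""))
  invisible(x)
}

#' Read a proxy curve from CSV
#'
#' Expects a header row with columns `age_mya,value` (comma-separated,
#' '.' decimal).
#'
#' @param file CSV path.
#' @param unit unit tag.
#' @return a [paleo_series()].
#' @export
read_paleo_csv <- function(file, unit = "") {
  d <- utils::read.csv(file)
  if (!all(c("age_mya", "value") %in% names(d)))
    stop("expected columns `age_mya,value` in ", file)
  paleo_series(d$age_mya, d$value, unit = unit)
}

#' Tukey-smooth a proxy series
#'
#' Applies the classic Tukey compound running-median smoother 3RS3R
#' (running medians of 3 repeated to convergence, splitting of two-point
#' flats, re-smoothing) with endpoints copied, iterated until the series is
#' a fixed point of the smoother. The result is therefore idempotent:
#' smoothing twice equals smoothing once. Values never leave the range of
#' the input (medians cannot extrapolate).
#'
#' @param series a [paleo_series()] with at least 3 points.
#' @return a [paleo_series()] on the same ages.
#' @export
tukey_smooth <- function(series) {
  stopifnot(inherits(series, "paleo_series"))
  if (nrow(series) < 3L) stop("smoothing needs at least 3 points")
  v <- series$value
  for (i in 1:25) {
    v2 <- as.numeric(stats::smooth(v, kind = "3RS3R", endrule = "copy"))
    if (identical(v2, v)) break
    v <- v2
  }
  paleo_series(series$age, v, unit = attr(series, "unit"))
}

#' Interpolate a proxy series at query ages
#'
#' Piecewise-linear interpolation, exact at the knots. Queries beyond the
#' covered age span clamp to the nearest knot value: proxies are undefined
#' outside their coverage, and clamping is an explicit, monotone rule.
#'
#' @param series a [paleo_series()].
#' @param ages query ages (My, >= 0); may be empty.
#' @return numeric vector of interpolated values, one per query age.
#' @export
interpolate_series <- function(series, ages) {
  stopifnot(inherits(series, "paleo_series"))
  if (length(ages) == 0L) return(numeric(0L))
  if (any(ages < 0)) stop("query ages must be >= 0")
  stats::approx(series$age, series$value, xout = ages, method = "linear",
                rule = 2)$y
}
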