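#' Posterior rate-through-time ensemble
#'
#' Holds posterior realizations of the speciation-rate-through-time curve
#' (e.g. the post-burn-in draws of a Bayesian rate reconstruction) as a
#' samples-by-ages matrix on a shared age grid.
#'
#' @param ages ascending age grid (My).
#' @param rates matrix, one row per posterior sample, `length(ages)` columns;
#'   all entries >= 0.
#' @param sample_id optional per-row provenance tags.
#' @return an object of class `rtt_ensemble`.
#' @export
rtt_ensemble <- function(ages, rates, sample_id = NULL) {
  rates <- as.matrix(rates)
  if (ncol(rates) != length(ages)) stop("ncol(rates) must equal length(ages)")
  if (nrow(rates) < 1L) stop("need at least one posterior sample")
  if (any(diff(ages) <= 0)) stop("ages must be strictly increasing")
  if (any(rates < 0)) stop("rates must be >= 0")
  if (is.null(sample_id)) sample_id <- seq_len(nrow(rates))
  structure(list(ages = as.numeric(ages), rates = rates,
                 sample_id = sample_id), class = "rtt_ensemble")
}

#' @export
print.rtt_ensemble <- function(x, ...) {
  cat(sprintf("Rate-through-time ensemble: %d samples x %d ages (%.4g-%.4g My)\n",
              nrow(x$rates), length(x$ages), min(x$ages), max(x$ages)))
  invisible(x)
}

#' Read a rate-through-time ensemble CSV
#'
#' Expected layout: header `sample_id,<age1>,<age2>,...` with one column per
#' grid age; one row per posterior sample.
#'
#' @param file CSV path.
#' @param burnin_frac fraction of leading rows dropped as burn-in (default 0).
#' @return an [rtt_ensemble()].
#' @export
read_rtt_csv <- function(file, burnin_frac = 0) {
  d <- utils::read.csv(file, check.names = FALSE)
  if (names(d)[1L] != "sample_id") stop("first column must be `sample_id`")
  ages <- as.numeric(names(d)[-1L])
  if (any(is.na(ages))) stop("age columns must have numeric names")
  if (burnin_frac > 0) {
    drop <- floor(nrow(d) * burnin_frac)
    if (drop >= nrow(d)) stop("burn-in removes every sample")
    if (drop > 0) d <- d[-seq_len(drop), , drop = FALSE]
  }
  rtt_ensemble(ages, as.matrix(d[, -1L, drop = FALSE]), sample_id = d$sample_id)
}

#' Detrended cross-correlation coefficient
#'
#' Podobnik-Stanley \eqn{\rho_{DCCA}} at a single scale: both series are
#' integrated to profiles, overlapping boxes of `box_size` consecutive
#' points are detrended by an ordinary least-squares line, and the
#' box-averaged residual covariance is normalised by the box-averaged
#' residual variances. Designed for autocorrelated, nonstationary series
#' where plain product-moment correlation is unreliable.
#'
#' @param x,y numeric series of equal length on a shared (implicit) grid.
#' @param box_size points per box, at least 4 and at most `length(x)`.
#' @return a coefficient in \[-1, 1\]; 1 for `y = x`.
#' @export
dcca_coefficient <- function(x, y, box_size = max(4L, floor(length(x) / 4))) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  box_size <- as.integer(box_size)
  if (box_size < 4L) stop("box_size must be at least 4")
  if (n < box_size) stop("series shorter than box_size")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant series: DCCA coefficient undefined")
  X <- cumsum(x - mean(x))
  Y <- cumsum(y - mean(y))
  t0 <- seq_len(box_size)
  t0 <- t0 - mean(t0)
  stt <- sum(t0^2)
  n_box <- n - box_size + 1L
  f2x <- f2y <- f2xy <- 0
  for (b in seq_len(n_box)) {
    ix <- b:(b + box_size - 1L)
    xb <- X[ix]; yb <- Y[ix]
    rx <- xb - mean(xb) - (sum(t0 * xb) / stt) * t0
    ry <- yb - mean(yb) - (sum(t0 * yb) / stt) * t0
    f2x <- f2x + sum(rx * rx)
    f2y <- f2y + sum(ry * ry)
    f2xy <- f2xy + sum(rx * ry)
  }
  f2xy / sqrt(f2x * f2y)
}

#' DCCA between a posterior rate ensemble and a climate proxy
#'
#' The proxy is Tukey-smoothed and interpolated to the ensemble's age grid
#' (in that order), a DCCA coefficient is computed for every posterior
#' sample, and the distribution of coefficients is tested against zero with
#' a one-sample Wilcoxon signed-rank test (a two-sample rank-sum variant
#' against a zero vector is available via `rank_sum = TRUE`). Posterior
#' samples are correlated draws, not independent observations, so the
#' p-value is descriptive rather than strictly calibrated.
#'
#' @param ens an [rtt_ensemble()].
#' @param proxy a [paleo_series()].
#' @param box_size DCCA box size; default `floor(N/4)` of the grid length.
#' @param max_age optional age cutoff (My): only grid ages `<= max_age`
#'   enter the correlation (shared-window comparisons across proxies).
#' @param rank_sum use the two-sample rank-sum test against a zero vector
#'   instead of the one-sample signed-rank test.
#' @return list of class `dcca_result`: `coefficients`, `mean`, `p_value`,
#'   `box_size`, `n_samples`.
#' @export
ensemble_climate_test <- function(ens, proxy, box_size = NULL, max_age = NULL,
                                  rank_sum = FALSE) {
  stopifnot(inherits(ens, "rtt_ensemble"), inherits(proxy, "paleo_series"))
  ages <- ens$ages
  rates <- ens$rates
  if (!is.null(max_age)) {
    keep <- ages <= max_age
    ages <- ages[keep]; rates <- rates[, keep, drop = FALSE]
  }
  if (is.null(box_size)) box_size <- max(4L, floor(length(ages) / 4))
  if (length(ages) < box_size)
    stop("ensemble grid shorter than the minimum box size")
  pv <- interpolate_series(tukey_smooth(proxy), ages)
  co <- apply(rates, 1L, function(rw) dcca_coefficient(rw, pv, box_size))
  p <- if (length(co) < 2L) 1 else if (rank_sum)
    stats::wilcox.test(co, rep(0, length(co)), exact = FALSE)$p.value
  else stats::wilcox.test(co, mu = 0, exact = FALSE)$p.value
  structure(list(coefficients = co, mean = mean(co), p_value = p,
                 box_size = box_size, n_samples = length(co)),
            class = "dcca_result")
}

#' @export
print.dcca_result <- function(x, ...) {
  cat(sprintf("DCCA: mean rho = %.3f over %d samples (box %d), p = %.3g\n",
              x$mean, x$n_samples, x$box_size, x$p_value))
  invisible(x)
}
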