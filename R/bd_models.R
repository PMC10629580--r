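#' Parametric rate function for a birth-death model
#'
#' Describes an instantaneous per-lineage rate as a function of age `t`
#' (My before present):
#' \itemize{
#'   \item `constant`: \eqn{\rho(t) = \rho_0}
#'   \item `exp_time`: \eqn{\rho(t) = \rho_0 e^{\beta t}}
#'   \item `exp_env`:  \eqn{\rho(t) = \rho_0 e^{\alpha T(t)}}, where `T(t)` is
#'     an environmental covariate, Tukey-smoothed and linearly interpolated
#'     (the same preprocessing the DCCA stage applies).
#' }
#'
#' @param form one of `"constant"`, `"exp_time"`, `"exp_env"`.
#' @param base base rate \eqn{\rho_0} (events/lineage/My); must be > 0 for a
#'   speciation spec, and >= 0 for an extinction spec.
#' @param slope \eqn{\beta} (per My) for `exp_time`, \eqn{\alpha} (per proxy
#'   unit) for `exp_env`; ignored for `constant`.
#' @param covariate a [paleo_series()]; required iff `form = "exp_env"`.
#'   Smoothed once at construction.
#' @return an object of class `rate_spec`.
#' @export
rate_spec <- function(form = c("constant", "exp_time", "exp_env"),
                      base, slope = 0, covariate = NULL) {
  form <- match.arg(form)
  if (!is.finite(base) || base < 0) stop("`base` must be finite and >= 0")
  if (!is.finite(slope)) stop("`slope` must be finite")
  if (form == "exp_env") {
    if (is.null(covariate)) stop("form 'exp_env' requires a covariate series")
    stopifnot(inherits(covariate, "paleo_series"))
    covariate <- tukey_smooth(covariate)
  } else if (!is.null(covariate)) {
    stop("a covariate is only allowed with form 'exp_env'")
  }
  structure(list(form = form, base = base,
                 slope = if (form == "constant") 0 else slope,
                 covariate = covariate),
            class = "rate_spec")
}

#' Evaluate a rate spec at one or more ages
#'
#' @param spec a [rate_spec()].
#' @param age ages in My before present.
#' @return rate(s) at `age`, same length as `age`.
#' @export
rate_at <- function(spec, age) {
  stopifnot(inherits(spec, "rate_spec"))
  switch(spec$form,
    constant = rep_len(spec$base, length(age)),
    exp_time = spec$base * exp(spec$slope * age),
    exp_env  = spec$base * exp(spec$slope *
                               interpolate_series(spec$covariate, age)))
}

#' Birth-death diversification model
#'
#' Pairs a speciation [rate_spec()] with an optional extinction spec and a
#' conditioning scheme. The model set used for temperature-vs-time
#' comparisons is exponential speciation (in time or in the covariate)
#' crossed with no, constant, or exponential extinction.
#'
#' @param speciation speciation [rate_spec()] (base must be > 0).
#' @param extinction extinction [rate_spec()] or `NULL` for no extinction.
#' @param conditioning `"crown_survival"` (default: condition on both crown
#'   lineages leaving at least one sampled descendant) or `"none"`.
#' @return an object of class `bd_model`.
#' @export
bd_model <- function(speciation, extinction = NULL,
                     conditioning = c("crown_survival", "none")) {
  conditioning <- match.arg(conditioning)
  stopifnot(inherits(speciation, "rate_spec"))
  if (speciation$base <= 0) stop("speciation base rate must be > 0")
  if (!is.null(extinction)) stopifnot(inherits(extinction, "rate_spec"))
  structure(list(speciation = speciation, extinction = extinction,
                 conditioning = conditioning),
            class = "bd_model")
}

# Number of free parameters of a model form.
bd_n_params <- function(model) {
  kf <- function(s) if (is.null(s)) 0L else if (s$form == "constant") 1L else 2L
  kf(model$speciation) + kf(model$extinction)
}

# Precompute the per-tree structures the likelihood reuses across parameter
# values: branching times, the quadrature grid (node ages inserted so no
# interpolation is needed at branching times), and covariate values on it.
bd_context <- function(tree, n_grid = 2000L, covariate = NULL) {
  stopifnot(inherits(tree, "time_tree"))
  bt <- branching_times(tree)
  ca <- bt[1L]
  grid <- sort(unique(c(seq(0, ca, length.out = n_grid), bt)))
  env <- if (!is.null(covariate))
    interpolate_series(tukey_smooth(covariate), grid)
  list(n = length(tree$tip.label), f = sampling_fraction(tree),
       bt = bt, crown = ca, grid = grid,
       node_idx = match(bt, grid), env = env)
}

# Cumulative integral of a positive integrand sampled on `grid`, using
# log-linear (geometric trapezoid) segments: exact when the integrand is
# exponential between grid points, which it is for constant and exp-in-time
# rates. Falls back to the arithmetic trapezoid on near-flat or
# non-positive segments.
cum_loglinear <- function(y, grid) {
  m <- length(grid)
  h <- grid[-1L] - grid[-m]
  y0 <- y[-m]; y1 <- y[-1L]
  seg <- h * (y0 + y1) / 2
  ok <- y0 > 0 & y1 > 0
  lr <- rep(0, m - 1L)
  lr[ok] <- log(y1[ok] / y0[ok])
  use <- ok & abs(lr) > 1e-9
  seg[use] <- h[use] * (y1[use] - y0[use]) / lr[use]
  c(0, cumsum(seg))
}

# Core likelihood given a precomputed context and rates evaluated on the
# grid. Structure: with r(t) = int_0^t (lambda - mu), g(t) = 1/f +
# int_0^t lambda e^r, Psi(0,t) = e^{r(t)} (g(0)/g(t))^2,
# logL = sum_nodes log lambda(t_i) + sum_edges log Psi + n log f
#        [- 2 log(1 - Phi(crown)) under crown-survival conditioning].
# Psi is multiplicative along root-to-tip paths, so the edge sum telescopes
# onto the node ages.
bd_loglik_core <- function(ctx, lam, mu, conditioning) {
  if (any(!is.finite(lam)) || any(lam <= 0) || any(!is.finite(mu)) || any(mu < 0))
    stop("degenerate rates on the integration grid")
  r <- cum_loglinear(lam, ctx$grid) -
       (if (all(mu == 0)) 0 else cum_loglinear(mu, ctx$grid))
  if (max(r) > 600) stop("numerically degenerate parameters: exp(r) overflow")
  g <- 1 / ctx$f + cum_loglinear(lam * exp(r), ctx$grid)
  r_n <- r[ctx$node_idx]; logg_n <- log(g[ctx$node_idx])
  n <- ctx$n
  sum_loglam <- sum(log(lam[ctx$node_idx]))
  # node 1 is the crown (counted twice: both crown edges trace back to it)
  psi_sum <- sum(r_n - 2 * logg_n) + (r_n[1L] - 2 * logg_n[1L]) +
    n * 2 * log(1 / ctx$f)
  ll <- sum_loglam + psi_sum + n * log(ctx$f)
  if (conditioning == "crown_survival") {
    # 1 - Phi(crown) = e^{r(crown)} / g(crown)
    ll <- ll - 2 * (r_n[1L] - logg_n[1L])
  }
  if (!is.finite(ll)) stop("non-finite log-likelihood")
  ll
}

#' Log-likelihood of a birth-death model on a time tree
#'
#' Likelihood of the reconstructed tree (sampled extant lineages only)
#' under time-varying speciation and extinction with uniform sampling
#' fraction `f`, in the environment-dependent birth-death framework.
#' Integrals are accumulated on a dense grid (node ages inserted) with
#' log-linear segment quadrature, exact for constant and exponential-in-time
#' rates.
#'
#' @param tree a [time_tree()] with at least 3 tips (2 allowed).
#' @param model a [bd_model()].
#' @param n_grid number of quadrature grid points between 0 and the crown
#'   age (default 2000; doubling it should move the log-likelihood by far
#'   less than the optimizer tolerance).
#' @return finite log-likelihood (errors on degenerate parameters rather
#'   than returning NaN).
#' @export
bd_loglik <- function(tree, model, n_grid = 2000L) {
  stopifnot(inherits(model, "bd_model"))
  cov <- covariate_of(model)
  ctx <- bd_context(tree, n_grid = n_grid, covariate = cov)
  lam <- rate_on_grid(model$speciation, ctx)
  mu <- if (is.null(model$extinction)) rep(0, length(ctx$grid))
        else rate_on_grid(model$extinction, ctx)
  bd_loglik_core(ctx, lam, mu, model$conditioning)
}

covariate_of <- function(model) {
  if (model$speciation$form == "exp_env") model$speciation$covariate
  else if (!is.null(model$extinction) && model$extinction$form == "exp_env")
    model$extinction$covariate
  else NULL
}

rate_on_grid <- function(spec, ctx) {
  switch(spec$form,
    constant = rep(spec$base, length(ctx$grid)),
    exp_time = spec$base * exp(spec$slope * ctx$grid),
    exp_env  = {
      if (is.null(ctx$env)) stop("context has no covariate values")
      spec$base * exp(spec$slope * ctx$env)
    })
}

# ---- ML fitting --------------------------------------------------------

# Pack/unpack free parameters: base rates on log scale (positivity by
# construction), slopes raw, bounded in [-10, 10] by penalty.
bd_build_model <- function(template, par, covariate) {
  i <- 1L
  mk <- function(spec, is_mu) {
    if (is.null(spec)) return(NULL)
    base <- exp(par[i]); i <<- i + 1L
    slope <- 0
    if (spec$form != "constant") { slope <- par[i]; i <<- i + 1L }
    s <- list(form = spec$form, base = base, slope = slope,
              covariate = if (spec$form == "exp_env") covariate else NULL)
    class(s) <- "rate_spec"
    s
  }
  sp <- mk(template$speciation, FALSE)
  ex <- mk(template$extinction, TRUE)
  structure(list(speciation = sp, extinction = ex,
                 conditioning = template$conditioning), class = "bd_model")
}

#' Fit a birth-death model by maximum likelihood
#'
#' Multi-start derivative-free (Nelder-Mead) optimization of
#' [bd_loglik()]. Base rates are optimized on the log scale; slopes are
#' constrained to \[-10, 10\]. Starts are a fixed, deterministic fan around
#' a Yule-style initial guess, so refitting the same tree and model yields
#' identical estimates.
#'
#' @param tree a [time_tree()] with >= 3 tips.
#' @param model a [bd_model()] giving the functional forms to fit (its
#'   base/slope values are ignored).
#' @param n_starts number of optimizer starts (default 5).
#' @param n_grid quadrature grid size, see [bd_loglik()].
#' @return an object of class `bd_fit`: list with `model` (at the ML
#'   estimates), `estimates`, `logL`, `k`, `AICc`, `converged`,
#'   `n_starts_used`, `n_tips`.
#' @export
fit_bd_model <- function(tree, model, n_starts = 5L, n_grid = 2000L) {
  stopifnot(inherits(tree, "time_tree"), inherits(model, "bd_model"))
  n <- length(tree$tip.label)
  if (n < 3L) stop("fitting needs at least 3 tips")
  cov <- covariate_of(model)
  ctx <- bd_context(tree, n_grid = n_grid, covariate = cov)
  # the covariate was smoothed once while building the context; keep a
  # matching (already-smoothed) copy for the fitted rate_spec objects
  cov_s <- if (!is.null(cov)) tukey_smooth(cov) else NULL

  slope_idx <- integer(0); i <- 1L; par0 <- numeric(0); nm <- character(0)
  lam0_init <- max((n - 2) / sum(tree$edge.length), 1e-4)
  add <- function(spec, tag) {
    if (is.null(spec)) return()
    par0 <<- c(par0, log(if (tag == "lambda") lam0_init else lam0_init / 2))
    nm <<- c(nm, paste0(tag, "0")); i <<- i + 1L
    if (spec$form != "constant") {
      par0 <<- c(par0, 0)
      nm <<- c(nm, paste0(if (tag == "lambda") "alpha" else "alpha_mu",
                          if (spec$form == "exp_time") "_time" else ""))
      slope_idx <<- c(slope_idx, i); i <<- i + 1L
    }
  }
  add(model$speciation, "lambda"); add(model$extinction, "mu")
  nm <- sub("alpha_time", "beta", nm); nm <- sub("alpha_mu_time", "beta_mu", nm)

  negll <- function(par) {
    if (length(slope_idx) && any(abs(par[slope_idx]) > 10)) return(1e10)
    m <- bd_build_model(model, par, cov_s)
    lam <- rate_on_grid(m$speciation, ctx)
    mu <- if (is.null(m$extinction)) rep(0, length(ctx$grid))
          else rate_on_grid(m$extinction, ctx)
    out <- tryCatch(-bd_loglik_core(ctx, lam, mu, model$conditioning),
                    error = function(e) 1e10)
    if (!is.finite(out)) 1e10 else out
  }

  # deterministic fan of starting points around par0
  fan <- c(0, 0.7, -0.7, 1.4, -0.4, 0.35, -1.1, 2.1, -0.2, 1.0)
  starts <- lapply(seq_len(n_starts), function(s) {
    d <- par0
    d <- d + fan[((s - 1L) %% length(fan)) + 1L] *
      rep_len(c(1, 0.05, 0.6, 0.04), length(d))[seq_along(d)] *
      (if (s %% 2L == 0L) -1 else 1)
    if (length(slope_idx)) d[slope_idx] <- pmax(pmin(d[slope_idx], 9.9), -9.9)
    d
  })
  best <- NULL; failures <- character(0)
  for (st in starts) {
    res <- tryCatch(
      if (length(st) == 1L) {
        # single free parameter (constant pure birth): bracketed Brent
        o <- stats::optimize(function(p) negll(p), lower = log(1e-6),
                             upper = log(100), tol = 1e-12)
        list(par = o$minimum, value = o$objective, convergence = 0L)
      } else {
        stats::optim(st, negll, method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-8))
      },
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value) || res$value >= 1e10) {
      failures <- c(failures, paste(signif(st, 3), collapse = ","))
      next
    }
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    stop("all optimizer starts failed; start points tried: ",
         paste(failures, collapse = " | "))
  est <- stats::setNames(best$par, nm)
  fitted_model <- bd_build_model(model, best$par, cov_s)
  est_natural <- est
  base_idx <- setdiff(seq_along(est), slope_idx)
  est_natural[base_idx] <- exp(est[base_idx])
  k <- bd_n_params(model)
  ll <- -best$value
  structure(list(model = fitted_model, estimates = est_natural, logL = ll,
                 k = k, AICc = aicc(ll, k, n), converged = best$convergence == 0,
                 n_starts_used = n_starts, n_tips = n),
            class = "bd_fit")
}

#' @export
print.bd_fit <- function(x, ...) {
  sp <- x$model$speciation
  cat(sprintf("BD fit: lambda %s%s | logL %.3f, k %d, AICc %.3f%s\n",
              sp$form,
              if (is.null(x$model$extinction)) ", no extinction"
              else paste0(", mu ", x$model$extinction$form),
              x$logL, x$k, x$AICc,
              if (x$converged) "" else " (not converged)"))
  print(signif(x$estimates, 4))
  invisible(x)
}

#' Corrected Akaike Information Criterion
#'
#' \eqn{AICc = -2\log L + 2k + 2k(k+1)/(n-k-1)} with `n` the number of tips.
#'
#' @param logL log-likelihood.
#' @param k number of free parameters.
#' @param n sample size (tips).
#' @export
aicc <- function(logL, k, n) {
  if (n - k - 1 <= 0) stop("AICc undefined: n - k - 1 <= 0")
  -2 * logL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Delta-AICc and Akaike weights for a set of fits
#'
#' @param fits list of `bd_fit` objects (or a numeric vector of AICc
#'   values) computed on the same tree.
#' @return data frame with columns `AICc`, `dAICc`, `weight`; weights are
#'   positive and sum to 1.
#' @export
aicc_weights <- function(fits) {
  a <- if (is.numeric(fits)) fits else {
    ns <- vapply(fits, function(f) f$n_tips, numeric(1))
    if (length(unique(ns)) > 1L) stop("fits are not on the same tree (n differs)")
    vapply(fits, function(f) f$AICc, numeric(1))
  }
  d <- a - min(a)
  w <- exp(-d / 2)
  data.frame(AICc = a, dAICc = d, weight = w / sum(w))
}

#' Evidence ratio of environment-dependent vs time-dependent models
#'
#' Akaike weights are computed jointly over the combined model set; the
#' ratio is the summed weight of the environment (temperature) family over
#' the summed weight of the time family. Values above 1 favor the
#' environmental covariate.
#'
#' @param env_fits,time_fits lists of `bd_fit` objects on the same tree
#'   (typically 3 each: exponential speciation with no, constant, or
#'   exponential extinction).
#' @return positive scalar.
#' @export
evidence_ratio <- function(env_fits, time_fits) {
  w <- aicc_weights(c(env_fits, time_fits))$weight
  ne <- length(env_fits)
  sum(w[seq_len(ne)]) / sum(w[-seq_len(ne)])
}

#' Fit the standard six-model temperature-vs-time comparison
#'
#' Fits exponential speciation in the environmental covariate and in time,
#' each with no, constant, or exponential (same driver) extinction, and
#' summarises AICc support.
#'
#' @param tree a [time_tree()].
#' @param climate a [paleo_series()] covariate.
#' @inheritParams fit_bd_model
#' @param conditioning passed to [bd_model()]. The comparison defaults to
#'   `"none"`: under crown-survival conditioning the exponential-extinction
#'   models admit a degenerate subcritical ridge (\eqn{\mu(t)>\lambda(t)}
#'   with both growing into the past) whose likelihood gain comes almost
#'   entirely from the conditioning denominator, which distorts AICc
#'   comparisons across the model set.
#' @return list with `fits` (named list of 6 `bd_fit`s), `table` (summary
#'   data frame with joint dAICc and weights), and `evidence_ratio`.
#' @export
fit_bd_modelset <- function(tree, climate, n_starts = 5L, n_grid = 2000L,
                            conditioning = "none") {
  spec_env <- rate_spec("exp_env", base = 0.1, covariate = climate)
  spec_time <- rate_spec("exp_time", base = 0.1)
  mods <- list(
    env_noext    = bd_model(spec_env, NULL, conditioning),
    env_constext = bd_model(spec_env, rate_spec("constant", 0.05), conditioning),
    env_expext   = bd_model(spec_env, rate_spec("exp_env", 0.05, covariate = climate),
                            conditioning),
    time_noext    = bd_model(spec_time, NULL, conditioning),
    time_constext = bd_model(spec_time, rate_spec("constant", 0.05), conditioning),
    time_expext   = bd_model(spec_time, rate_spec("exp_time", 0.05), conditioning))
  fits <- lapply(mods, function(m)
    fit_bd_model(tree, m, n_starts = n_starts, n_grid = n_grid))
  tab <- aicc_weights(fits)
  tab <- cbind(data.frame(model = names(mods),
                          logL = vapply(fits, function(f) f$logL, numeric(1)),
                          k = vapply(fits, function(f) f$k, numeric(1))),
               tab)
  rownames(tab) <- NULL
  list(fits = fits, table = tab,
       evidence_ratio = evidence_ratio(fits[1:3], fits[4:6]))
}

#' Exponential rate-versus-temperature curve fit
#'
#' Least-squares fit of `rate = a * exp(b * T)` between a mean
#' rate-through-time curve and a climate proxy over a recent age window,
#' mirroring per-bioregion rate-through-temperature summaries.
#'
#' @param rates mean speciation rates on `ages`.
#' @param ages age grid (My) matching `rates`.
#' @param climate a [paleo_series()]; smoothed and interpolated to `ages`.
#' @param window only ages `<= window` (My) enter the fit (default 10).
#' @return list with `a`, `b`, `r_squared`, `n_points`.
#' @export
fit_rate_temperature_curve <- function(rates, ages, climate, window = 10) {
  stopifnot(length(rates) == length(ages))
  keep <- ages <= window
  if (sum(keep) < 3L) stop("fewer than 3 grid points within the age window")
  y <- rates[keep]; tt <- ages[keep]
  if (any(y <= 0)) stop("rates must be positive for the exponential fit")
  Tv <- interpolate_series(tukey_smooth(climate), tt)
  lm0 <- stats::lm(log(y) ~ Tv)
  st <- list(a = exp(unname(stats::coef(lm0)[1])), b = unname(stats::coef(lm0)[2]))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(b * Tv), start = st,
                      control = minpack.lm::nls.lm.control(maxiter = 200,
                                                           ftol = 1e-14)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # degenerate least-squares surface (e.g. constant rates): the
    # log-linear solution is already exact
    cf <- c(a = st$a, b = st$b)
    res <- y - st$a * exp(st$b * Tv)
  } else {
    cf <- stats::coef(fit)
    res <- y - stats::fitted(fit)
  }
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(res^2) / sst else NA_real_
  list(a = unname(cf["a"]), b = unname(cf["b"]), r_squared = r2,
       n_points = length(y))
}
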