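test_that("rate specs evaluate their closed forms", {
  expect_equal(rate_at(rate_spec("constant", 0.2), c(0, 7, 30)), rep(0.2, 3))
  expect_equal(rate_at(rate_spec("exp_time", 0.1, 0.05), 10), 0.1 * exp(0.5))
  clim <- paleo_series(c(0, 10, 20), c(2, 2, 2))   # constant covariate T = 2
  expect_equal(rate_at(rate_spec("exp_env", 0.1, -0.3, clim), 10),
               0.1 * exp(-0.6))
  expect_error(rate_spec("exp_env", 0.1, -0.3), "covariate")
  expect_error(rate_spec("constant", 0.1, covariate = clim), "only allowed")
})

test_that("likelihood matches the constant-rate closed form", {
  set.seed(42)
  for (i in 1:8) {
    lam <- runif(1, 0.05, 0.5)
    mu <- lam * runif(1, 0, 0.8)
    f <- runif(1, 0.3, 1)
    tr <- rand_tree(50, crown = runif(1, 10, 30), f = f)
    for (cond in c("crown_survival", "none")) {
      m <- bd_model(rate_spec("constant", lam), rate_spec("constant", mu),
                    conditioning = cond)
      expect_equal(bd_loglik(tr, m),
                   nee_loglik(branching_times(tr), lam, mu, f, cond),
                   tolerance = 1e-9)
    }
  }
})

test_that("exponential models nest the constant model at zero slope", {
  set.seed(12)
  clim <- simulate_climate(span = 30, seed = 4)
  for (i in 1:10) {
    lam <- runif(1, 0.05, 0.5)
    mu <- lam * runif(1, 0, 0.8)
    tr <- rand_tree(sample(10:60, 1), crown = 25, f = runif(1, 0.3, 1))
    m0 <- bd_model(rate_spec("constant", lam), rate_spec("constant", mu))
    ll0 <- bd_loglik(tr, m0)
    mt <- bd_model(rate_spec("exp_time", lam, 0), rate_spec("constant", mu))
    me <- bd_model(rate_spec("exp_env", lam, 0, clim), rate_spec("constant", mu))
    expect_equal(bd_loglik(tr, mt), ll0, tolerance = 1e-10)
    expect_equal(bd_loglik(tr, me), ll0, tolerance = 1e-10)
  }
})

test_that("doubling the quadrature grid leaves the likelihood stable", {
  set.seed(2)
  clim <- simulate_climate(span = 30, seed = 9)
  tr <- rand_tree(60, crown = 28, f = 0.6)
  m <- bd_model(rate_spec("exp_env", 0.15, -0.4, clim),
                rate_spec("exp_env", 0.05, 0.2, clim))
  expect_lt(abs(bd_loglik(tr, m, n_grid = 4000L) -
                bd_loglik(tr, m, n_grid = 2000L)), 1e-4)
})

test_that("degenerate parameters fail loudly instead of returning NaN", {
  tr <- rand_tree(20, crown = 50)
  m <- bd_model(rate_spec("exp_time", 5, 9.9), NULL)
  expect_error(bd_loglik(tr, m), "degenerate")
})

test_that("constant-rate fit recovers the pure-birth analytic MLE", {
  set.seed(31)
  tr <- rand_tree(80, crown = 20, f = 1)
  fit <- fit_bd_model(tr, bd_model(rate_spec("constant", 0.1), NULL,
                                   conditioning = "crown_survival"))
  # closed form for this likelihood: lambda_hat = (n-1) / total tree length
  lam_cf <- (length(tr$tip.label) - 1) / sum(tr$edge.length)
  expect_equal(unname(fit$estimates["lambda0"]), lam_cf, tolerance = 1e-4)
  expect_true(fit$converged)
  # refit is bit-identical: deterministic starts
  fit2 <- fit_bd_model(tr, bd_model(rate_spec("constant", 0.1), NULL,
                                    conditioning = "crown_survival"))
  expect_identical(fit$estimates, fit2$estimates)
})

test_that("AICc arithmetic, weights and evidence ratio", {
  expect_equal(aicc(-100, 2, 50), 204 + 12 / 47)
  expect_error(aicc(-10, 5, 6), "undefined")
  w <- aicc_weights(c(100, 100))
  expect_equal(w$weight, c(0.5, 0.5))
  expect_equal(w$dAICc, c(0, 0))
  w2 <- aicc_weights(c(100, 102))
  expect_equal(w2$weight, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)
  set.seed(8)
  for (i in 1:50) {
    a <- runif(sample(2:10, 1), 50, 400)
    expect_equal(sum(aicc_weights(a)$weight), 1, tolerance = 1e-12)
  }
  mkfit <- function(aicc_val) structure(list(AICc = aicc_val, n_tips = 50),
                                        class = "bd_fit")
  # joint weights temp {0.5,0.2,0.1} vs time {0.1,0.05,0.05} -> 0.8/0.2
  a_from_w <- -2 * log(c(0.5, 0.2, 0.1, 0.1, 0.05, 0.05))
  fits <- lapply(a_from_w, mkfit)
  expect_equal(evidence_ratio(fits[1:3], fits[4:6]), 4.0, tolerance = 1e-12)
  same <- lapply(rep(120, 6), mkfit)
  expect_equal(evidence_ratio(same[1:3], same[4:6]), 1.0)
})

test_that("rate-vs-temperature exponential fit recovers noiseless truth", {
  clim <- paleo_series(seq(0, 15, 0.5), seq(1, 4, length.out = 31))
  ages <- seq(0, 10, 0.25)
  Tv <- interpolate_series(tukey_smooth(clim), ages)
  fit <- fit_rate_temperature_curve(0.3 * exp(-0.8 * Tv), ages, clim,
                                    window = 10)
  expect_equal(fit$a, 0.3, tolerance = 1e-8)
  expect_equal(fit$b, -0.8, tolerance = 1e-8)
  flat <- fit_rate_temperature_curve(rep(0.2, length(ages)), ages, clim,
                                     window = 10)
  expect_equal(flat$b, 0, tolerance = 1e-6)
  expect_error(fit_rate_temperature_curve(c(1, 2), c(0, 20), clim, window = 1),
               "fewer than 3")
})

test_that("noisy rate-vs-temperature fits recover the slope within 10%", {
  clim <- paleo_series(seq(0, 15, 0.5), seq(1, 4, length.out = 31))
  ages <- seq(0, 10, 0.25)
  Tv <- interpolate_series(tukey_smooth(clim), ages)
  truth <- 0.3 * exp(-0.8 * Tv)
  set.seed(99)
  bs <- replicate(100, {
    y <- truth + rnorm(length(truth), 0, 0.01 * mean(truth))
    fit_rate_temperature_curve(y, ages, clim, window = 10)$b
  })
  expect_lt(abs(median(bs) - (-0.8)) / 0.8, 0.1)
})
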