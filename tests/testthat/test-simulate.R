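test_that("climate scenarios are deterministic and reduce to the trend", {
  lin <- simulate_climate(span = 30, start = 1, end = 5, amplitude = 0,
                          noise_sd = 0, step = 1, seed = 1)
  expect_equal(interpolate_series(lin, 15), 3.0)
  expect_equal(lin$value[lin$age == 0], 5)
  expect_equal(lin$value[lin$age == 30], 1)
  a <- simulate_climate(seed = 42)
  b <- simulate_climate(seed = 42)
  expect_identical(a$value, b$value)
})

test_that("oscillation leaves a periodic signature in the detrended residual", {
  s <- simulate_climate(span = 60, start = 4, end = 0.5, amplitude = 0.5,
                        period = 5, noise_sd = 0, step = 0.5, seed = 1)
  trend <- simulate_climate(span = 60, start = 4, end = 0.5, amplitude = 0,
                            noise_sd = 0, step = 0.5, seed = 1)
  resid <- s$value - trend$value
  ac <- stats::acf(resid, lag.max = 14, plot = FALSE)$acf[-1]
  # autocorrelation peaks at one full period (5 My = 10 steps of 0.5)
  expect_equal(which.max(ac), 10L)
})

test_that("pure-birth tip counts match the branching-process expectation", {
  lam <- 0.1; ca <- 20
  n1 <- n_half <- numeric(300)
  for (i in seq_along(n1)) {
    n1[i] <- simulate_bd_tree(rate_spec("constant", lam), NULL, crown_ag = ca,
                              f = 1, min_tips = 0L, condition_on_crown = FALSE,
                              seed = 2000 + i)$n_tips
    n_half[i] <- simulate_bd_tree(rate_spec("constant", lam), NULL,
                                  crown_ag = ca, f = 0.5, min_tips = 0L,
                                  condition_on_crown = FALSE,
                                  seed = 2000 + i)$n_tips
  }
  expected <- 2 * exp(lam * ca)
  se <- stats::sd(n1) / sqrt(length(n1))
  expect_lt(abs(mean(n1) - expected), 3 * se)
  # binomial thinning halves the expectation
  se2 <- stats::sd(n_half - n1 / 2) / sqrt(length(n1))
  expect_lt(abs(mean(n_half) - mean(n1) / 2), 3 * se2 + 1e-9)
})

test_that("tree simulation is reproducible and returns valid time trees", {
  clim <- simulate_climate(span = 25, seed = 8)
  spec <- rate_spec("exp_env", 0.2, -0.2, clim)
  s1 <- simulate_bd_tree(spec, NULL, crown_ag = 25, f = 0.8, min_tips = 10,
                         max_tips = 500, seed = 99)
  s2 <- simulate_bd_tree(spec, NULL, crown_ag = 25, f = 0.8, min_tips = 10,
                         max_tips = 500, seed = 99)
  expect_identical(write_time_tree(s1$tree), write_time_tree(s2$tree))
  expect_s3_class(s1$tree, "time_tree")
  expect_equal(crown_age(s1$tree), 25, tolerance = 1e-6)
  expect_gte(s1$n_tips, 10)
  expect_true(all(s1$true_lambda$lambda > 0))
  # birth-death with extinction also yields a valid ultrametric tree
  s3 <- simulate_bd_tree(rate_spec("constant", 0.25),
                         rate_spec("constant", 0.1), crown_ag = 20, f = 1,
                         min_tips = 5, max_tips = 5000, seed = 7)
  expect_s3_class(s3$tree, "time_tree")
  expect_error(simulate_bd_tree(rate_spec("constant", 0.01), NULL,
                                crown_ag = 5, f = 1, min_tips = 50,
                                max_tips = 60, seed = 1, max_rejects = 20),
               "rejected")
})

test_that("rtt ensembles have mean-one noise around the true curve", {
  ages <- seq(0, 20, 0.5)
  truth <- 0.1 * exp(0.05 * ages)
  e0 <- simulate_rtt_ensemble(ages, truth, n_samples = 10, noise_sd = 0,
                              seed = 1)
  expect_true(all(apply(e0$rates, 1, function(r) all(r == truth))))
  sd <- 0.2
  e1 <- simulate_rtt_ensemble(ages, truth, n_samples = 2000, noise_sd = sd,
                              seed = 2)
  rel_dev <- abs(colMeans(e1$rates) - truth) / truth
  expect_lt(max(rel_dev), 3 * sd / sqrt(2000) * 2)
  expect_true(all(e1$rates > 0))
  e2 <- simulate_rtt_ensemble(ages, truth, n_samples = 5, noise_sd = 0.1,
                              seed = 3)
  e3 <- simulate_rtt_ensemble(ages, truth, n_samples = 5, noise_sd = 0.1,
                              seed = 3)
  expect_identical(e2$rates, e3$rates)
})

test_that("BM tip variance grows with root-to-tip depth", {
  set.seed(64)
  tr <- rand_tree(30, crown = 10)
  reps <- vapply(1:500, function(i)
    simulate_traits(tr, "bm", sigma2 = 1, seed = 3000 + i)[1], numeric(1))
  # sd of a sample variance of 500 normal draws with var 10: ~0.63
  expect_lt(abs(stats::var(reps) - 10), 3 * 10 * sqrt(2 / 499))
})

test_that("threshold and regime traits respect their contracts", {
  set.seed(3)
  tr <- rand_tree(100)
  bin <- simulate_traits(tr, "threshold_binary", prevalence = 0.3, seed = 4)
  expect_equal(sum(bin), 30)
  expect_error(simulate_traits(tr, "threshold_binary", prevalence = 1),
               "prevalence")
  reg1 <- simulate_traits(tr, "regime_rates", k = 1, seed = 5)
  expect_equal(length(unique(reg1$tip_rate)), 1L)
  reg <- simulate_traits(tr, "regime_rates", k = 5, seed = 6)
  expect_true(all(reg$tip_rate > 0))
  expect_equal(sort(unique(reg$regime)), seq_along(reg$rates))
  # regimes partition the tips
  expect_equal(length(reg$regime), 100L)
})

test_that("occurrence generator scatters around the assigned centers", {
  centers <- default_region_centers()
  occ <- simulate_occurrences(paste0("s", 1:5), centers, spread_deg = 0,
                              n_per_species = 10, seed = 1)
  expect_equal(nrow(occ), 50L)
  expect_true(all(occ$lon %in% centers$lon & occ$lat %in% centers$lat))
  set.seed(12)
  species <- paste0("sp", 1:200)
  occ2 <- simulate_occurrences(species, centers, spread_deg = 2,
                               n_per_species = 10, seed = 13)
  # majority-vote region recovery: nearest center of the occurrence medians
  hit <- vapply(split(occ2, occ2$species), function(d) {
    dd <- (centers$lon - stats::median(d$lon))^2 +
          (centers$lat - stats::median(d$lat))^2
    centers$bioregion[which.min(dd)] == d$bioregion[1]
  }, logical(1))
  expect_gte(mean(hit), 0.95)
})
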