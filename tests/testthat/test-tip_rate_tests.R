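test_that("equal-splits statistic matches hand and brute-force oracles", {
  # two-tip cherry with a unit stem edge: ES = 1 + 1/2, DR = 2/3 for both
  # (raw phylo: the stem segment is a plain path edge for the statistic)
  cherry <- ape::read.tree(text = "((A:1,B:1):1);")
  es <- es_statistic(cherry)
  expect_equal(es$ES, c(1.5, 1.5))
  expect_equal(es$DR, c(2 / 3, 2 / 3))
  # perfectly balanced tree with equal edges: all tips identical
  bal <- read_time_tree(text = paste0(
    "(((a:1,b:1):1,(c:1,d:1):1):1,((e:1,f:1):1,(g:1,h:1):1):1);"))
  expect_equal(length(unique(round(es_statistic(bal)$ES, 12))), 1L)
  set.seed(14)
  for (i in 1:5) {
    tr <- rand_tree(50)
    expect_equal(stats::setNames(es_statistic(tr)$ES, tr$tip.label),
                 es_oracle(tr), tolerance = 1e-12)
    expect_true(all(es_statistic(tr)$DR > 0))
  }
})

test_that("essim is extreme for a self-trait, deterministic under a seed", {
  set.seed(5)
  tr <- rand_tree(40)
  logdr <- log(es_statistic(tr)$DR)
  res <- essim_test(tr, logdr, n_sim = 200, seed = 10)
  expect_lte(res$p_value, 2 / 201)
  res2 <- essim_test(tr, logdr, n_sim = 200, seed = 10)
  expect_identical(res$p_value, res2$p_value)
  expect_error(essim_test(tr, rep(1, 40), n_sim = 200), "constant")
})

test_that("essim type-I error is near nominal under a BM null", {
  set.seed(71)
  alpha_hits <- 0; n_rep <- 120
  for (i in 1:n_rep) {
    tr <- rand_tree(40)
    trait <- simulate_traits(tr, "bm", seed = 5000 + i)
    p <- essim_test(tr, trait, n_sim = 120, seed = 9000 + i)$p_value
    if (p <= 0.05) alpha_hits <- alpha_hits + 1
  }
  rate <- alpha_hits / n_rep
  expect_gte(rate, 0.005)
  expect_lte(rate, 0.12)
})

test_that("strapp handles invariance, calibration inputs and power", {
  set.seed(9)
  tips1 <- data.frame(tip_rate = runif(30, 0.1, 1), regime = 1L)
  expect_warning(res1 <- strapp_test(tips1, rnorm(30), "spearman",
                                     n_perm = 200, seed = 1),
                 "single")
  expect_equal(res1$p_value, 1)
  # strong signal: trait equals regime mean rate, well-separated regimes
  k <- 10; per <- 6
  rates <- 2^(seq_len(k))
  tips2 <- data.frame(tip_rate = rep(rates, each = per),
                      regime = rep(seq_len(k), each = per))
  trait <- rep(rates, each = per)
  hits <- 0
  for (i in 1:20) {
    p <- strapp_test(tips2, trait, "spearman", n_perm = 500, seed = i)$p_value
    if (p <= 0.01) hits <- hits + 1
  }
  expect_gte(hits, 18)
  # deterministic under seed
  pa <- strapp_test(tips2, trait, "spearman", n_perm = 200, seed = 3)$p_value
  pb <- strapp_test(tips2, trait, "spearman", n_perm = 200, seed = 3)$p_value
  expect_identical(pa, pb)
})

test_that("strapp type-I error is near nominal for all three statistics", {
  set.seed(55)
  n_rep <- 150
  for (st in c("spearman", "mann_whitney", "kruskal_wallis")) {
    hits <- 0
    for (i in 1:n_rep) {
      k <- 8; per <- 8
      tips <- data.frame(tip_rate = rep(exp(rnorm(k)), each = per),
                         regime = rep(seq_len(k), each = per))
      trait <- switch(st,
        spearman = rnorm(k * per),
        mann_whitney = sample(c(0, 1), k * per, replace = TRUE),
        kruskal_wallis = sample(letters[1:4], k * per, replace = TRUE))
      p <- strapp_test(tips, trait, st, n_perm = 120,
                       seed = 100 * i)$p_value
      if (p <= 0.05) hits <- hits + 1
    }
    rate <- hits / n_rep
    expect_gte(rate, 0.005)
    expect_lte(rate, 0.12)
  }
})

test_that("D statistic is calibrated at its two reference points", {
  set.seed(404)
  d_rand <- d_bm <- numeric(30)
  for (i in 1:30) {
    tr <- rand_tree(60)
    shuffled <- stats::setNames(sample(rep(c(0, 1), c(40, 20))), tr$tip.label)
    d_rand[i] <- d_statistic(tr, shuffled, n_perm = 150, n_sim = 150,
                             seed = 600 + i)$D
    clumped <- simulate_traits(tr, "threshold_binary", prevalence = 1 / 3,
                               seed = 700 + i)
    d_bm[i] <- d_statistic(tr, clumped, n_perm = 150, n_sim = 150,
                           seed = 800 + i)$D
  }
  expect_gt(mean(d_rand), 0.8)
  expect_lt(mean(d_rand), 1.2)
  expect_gt(mean(d_bm), -0.2)
  expect_lt(mean(d_bm), 0.2)
  tr <- rand_tree(20)
  expect_error(d_statistic(tr, rep(1, 20), n_perm = 150, n_sim = 150),
               "monomorphic")
})

test_that("tropical classification follows the strict-majority rules", {
  occ <- data.frame(species = rep(c("a", "b", "c"), each = 4),
                    lon = 0,
                    lat = c(10, -5, 3, 40,     # a: 3/4 inside
                            10, -5, 40, 60,    # b: exactly half
                            23.5, 0, 1, 2))    # c: boundary counts inside
  cl <- classify_tropical(occ, "latitude")
  expect_true(cl[["a"]])
  expect_false(cl[["b"]])
  expect_true(cl[["c"]])
  occ$mean_temp_c <- rep(19, 12)
  expect_true(all(classify_tropical(occ, "temperature")))
  occ$mean_temp_c <- rep(18, 12)   # not strictly above threshold
  expect_false(any(classify_tropical(occ, "temperature")))
  expect_error(classify_tropical(occ[, 1:3], "temperature"), "mean_temp_c")
})
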