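test_that("thinning takes a uniform stride and preserves membership", {
  x <- rnorm(4000)
  th <- thin_to_independent(x, 399, n_eff = 600)
  expect_length(th, 399)
  expect_identical(th, x[seq(1, by = 10, length.out = 399)])
  expect_true(all(th %in% x))
  # already-iid draws of length L: identity
  y <- rnorm(399)
  expect_identical(thin_to_independent(y, 399, n_eff = 399 + 1), y)
  expect_error(thin_to_independent(x, 399, n_eff = 300), "escalate")
})

test_that("tie-randomized rank statistic matches exhaustive enumeration", {
  expect_identical(rank_statistic(c(1, 2, 3, 4), 10), 4L)
  expect_identical(rank_statistic(c(1, 2, 3, 4), 0), 0L)
  # values [1,2,2,3], truth 2: r_less = 1, r_equals = 2 -> uniform on {1,2,3}
  set.seed(61)
  out <- replicate(3e4, rank_statistic(c(1, 2, 2, 3), 2))
  expect_setequal(unique(out), 1:3)
  freq <- tabulate(out, 3) / 3e4
  se <- sqrt((1 / 3) * (2 / 3) / 3e4)
  for (k in 1:3) expect_lt(abs(freq[k] - 1 / 3), 3 * se)
})

test_that("rank histograms carry a correct 99% binomial band", {
  h <- uniformity_histogram(rep(0:399, length.out = 2000), B = 100, L = 399)
  expect_identical(sum(h$counts), 2000L)
  expect_identical(h$expected, 20)
  expect_identical(h$band, qbinom(c(0.005, 0.995), 2000, 0.01))
  # perfectly uniform ranks sit inside the band
  expect_true(all(h$counts >= h$band[1] & h$counts <= h$band[2]))
  expect_error(uniformity_histogram(c(0, 400), B = 100, L = 399), "outside")
  expect_error(uniformity_histogram(0:9, B = 3, L = 9), "divide")
})

test_that("chi-square uniformity test and its reference critical value", {
  # the 5% critical value with 100 bins
  expect_equal(qchisq(0.95, df = 99), 123.23, tolerance = 0.005)
  r <- chi2_uniformity(rep(5, 100))
  expect_identical(r$statistic, 0)
  expect_identical(r$p_value, 1)
  r2 <- chi2_uniformity(c(30, 10))
  expect_equal(r2$statistic, 10)
  expect_identical(r2$df, 1L)
})

test_that("Fisher's combined probability test", {
  f1 <- fisher_combined(c(1, 1, 1))
  expect_identical(f1$statistic, 0)
  expect_equal(f1$p_value, 1)
  # one p-value: identity
  expect_equal(fisher_combined(0.37)$p_value, 0.37, tolerance = 1e-12)
  f2 <- fisher_combined(c(0.5, 0.5))
  expect_equal(f2$statistic, -4 * log(0.5), tolerance = 1e-12)
  expect_equal(f2$p_value, pchisq(-4 * log(0.5), 4, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_error(fisher_combined(c(0.5, 0)), "infinite")
})

test_that("an exact sampler passes calibration in a conjugate toy model", {
  # mu ~ N(0,1); y_i ~ N(mu, 1), n = 5; posterior is available exactly.
  # With exact posterior draws the rank of the truth must be uniform.
  L <- 79; B <- 10; N <- 150
  n_fail <- 0
  for (seed in 1:10) {
    set.seed(seed)
    ranks <- replicate(N, {
      mu <- rnorm(1)
      y <- rnorm(5, mu, 1)
      post_mean <- sum(y) / 6
      post_sd <- sqrt(1 / 6)
      draws <- rnorm(L, post_mean, post_sd)
      rank_statistic(draws, mu)
    })
    h <- uniformity_histogram(ranks, B = B, L = L)
    if (chi2_uniformity(h$counts)$p_value < 0.01) n_fail <- n_fail + 1
  }
  expect_identical(n_fail, 0)
})

test_that("the full-model batch yields uniform calibration ranks", {
  batch <- get_study_batch()
  rep <- sbc_study(STUDY_N, STUDY_TRIALS, results = batch,
                   B = STUDY_B, L = STUDY_L, config = study_config())
  expect_identical(ncol(rep$ranks), 9L)
  expect_true("log_density" %in% colnames(rep$ranks))
  expect_true(all(rep$ranks >= 0 & rep$ranks <= STUDY_L))
  expect_true(all(vapply(rep$histograms, function(h) sum(h$counts), 0L) ==
                    rep$n_used))
  # no systematic uniformity failure: at most 1 of 9 tests rejects at 5%
  pvals <- vapply(rep$chi2, `[[`, numeric(1), "p_value")
  expect_lte(sum(pvals < 0.05), 1)
  expect_gt(rep$fisher$p_value, 0.01)
})

test_that("calibration detects a deliberately broken fitter", {
  cfg <- study_config(seed = 5555L)
  res <- wiener7:::run_study(STUDY_N, 40, default_priors(), cfg,
                             keep_thinned = STUDY_L, fitter = broken_fitter)
  rep <- sbc_study(STUDY_N, 40, results = res, B = STUDY_B, L = STUDY_L,
                   config = cfg)
  # the shifted boundary-separation marginal must fail uniformity hard
  expect_lt(rep$chi2$a$p_value, 0.01)
})

test_that("the log-density test quantity ignores trial order", {
  set.seed(62)
  truth <- sample_ground_truth()
  d <- simulate_dataset(truth, 30)
  thinned <- t(vapply(1:5, function(i) unlist(sample_ground_truth()),
                      numeric(8)))
  colnames(thinned) <- c("a", "v1", "v2", "w", "t0", "sv", "sw", "st0")
  q1 <- test_quantities(truth, thinned, d)
  q2 <- test_quantities(truth, thinned, d[sample(nrow(d)), ])
  expect_equal(q1$log_density$values, q2$log_density$values, tolerance = 1e-10)
  expect_length(q1, 9L)
})
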