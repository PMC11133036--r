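# Frozen reference values for the rank-normalized diagnostics were
# computed once with an independent implementation of the same published
# definitions on the exact chains generated below.

test_that("rank-normalized R-hat and bulk ESS match reference values", {
  set.seed(123)
  n <- 400; m <- 4
  x <- matrix(0, n, m)
  for (j in 1:m) {
    e <- rnorm(n)
    for (i in 2:n) e[i] <- 0.7 * e[i - 1] + rnorm(1) * sqrt(1 - 0.49)
    x[, j] <- e + 0.1 * j
  }
  expect_equal(rhat(x), 1.0160438180820406, tolerance = 1e-6)
  expect_equal(ess_bulk(x), 246.5301651981876, tolerance = 1e-6)

  set.seed(99)
  y <- matrix(rnorm(1000), 250, 4)
  expect_equal(rhat(y), 1.0011519202894568, tolerance = 1e-6)
  expect_equal(ess_bulk(y), 906.4214247082228, tolerance = 1e-6)
})

test_that("diagnostic rules pass healthy chains and fail broken ones", {
  set.seed(41)
  good <- matrix(rnorm(4000), 1000, 4)
  expect_lt(rhat(good), 1.01)
  bad <- cbind(rnorm(1000), rnorm(1000) + 5)
  expect_gt(rhat(bad), 1.5)

  fake <- function(neff, rh, div = 0L, nsamp = 4000) {
    structure(list(diagnostics = data.frame(param = "a", rhat = rh, n_eff = neff),
                   divergences = div, n_samp = nsamp),
              class = "posterior_result")
  }
  expect_true(diagnose(fake(2000, 1.001))$pass)
  expect_false(diagnose(fake(399, 1.001))$pass)       # N_eff > 400 rule
  expect_false(diagnose(fake(2000, 1.02))$pass)        # R-hat < 1.01 rule
  expect_true(diagnose(fake(2000, 1.02))$soft_pass)    # but < 1.05 soft tier
  expect_false(diagnose(fake(2000, 1.001, div = 3))$pass)
  # relative N_eff rule in isolation: 450/8000 < 0.1 while N_eff > 400
  expect_false(diagnose(fake(450, 1.001, nsamp = 8000))$pass)
})

test_that("relabeling responses and mirroring parameters leaves the likelihood unchanged", {
  set.seed(42)
  truth <- sample_ground_truth()
  d <- simulate_dataset(truth, 60)
  ps <- lapply(1:2, function(c) truth_params(truth, c))
  d_flip <- d; d_flip$response <- 1L - d$response
  ps_flip <- lapply(ps, function(p)
    dm_params(a = p$a, v = -p$v, w = 1 - p$w, t0 = p$t0,
              sv = p$sv, sw = p$sw, st0 = p$st0))
  expect_identical(loglik_dataset(d, ps), loglik_dataset(d_flip, ps_flip))
})

test_that("the z-space posterior gradient matches finite differences", {
  set.seed(43)
  truth <- sample_ground_truth()
  d <- simulate_dataset(truth, 40)
  m <- wiener7:::build_model(d, default_priors(), list(),
                             precision_spec(refine = FALSE))
  z <- wiener7:::params_to_z(m, unlist(truth))
  an <- wiener7:::log_posterior(m, z, gradient = TRUE)
  fd <- vapply(seq_along(z), function(k) {
    h <- 1e-5
    up <- z; up[k] <- z[k] + h
    dn <- z; dn[k] <- z[k] - h
    (wiener7:::log_posterior(m, up, FALSE)$lp -
       wiener7:::log_posterior(m, dn, FALSE)$lp) / (2 * h)
  }, numeric(1))
  expect_equal(an$grad, fd, tolerance = 1e-5)
})

test_that("fits are deterministic under a fixed seed", {
  set.seed(44)
  truth <- sample_ground_truth()
  d <- simulate_dataset(truth, 20)
  f1 <- fit_dm(d, config = tiny_config(seed = 5))
  f2 <- fit_dm(d, config = tiny_config(seed = 5))
  expect_identical(f1$draws, f2$draws)
})

test_that("with no data the posterior reproduces the prior", {
  empty <- data.frame(rt = numeric(0), response = integer(0),
                      condition = integer(0))
  cfg <- fit_config(n_chains = 2, warmup = c(150L, 200L),
                    sampling = c(400L, 400L), seed = 9,
                    neff_min = 50, releff_min = 0.01, rhat_max = 1.05)
  fit <- fit_dm(empty, config = cfg)
  # independent Monte-Carlo prior means (rejection for the joint constraint)
  set.seed(91)
  mc <- t(vapply(1:20000, function(i) unlist(sample_ground_truth()),
                 numeric(8)))
  for (p in fit$free[fit$free != "v2"]) {
    draws <- pooled_draws(fit, p)
    ne <- fit$diagnostics$n_eff[fit$diagnostics$param == p]
    tol <- 3 * mcse(draws, ne) + 3 * sd(mc[, p]) / sqrt(nrow(mc))
    expect_lt(abs(mean(draws) - mean(mc[, p])), tol)
  }
})

test_that("restricted one-parameter posterior matches a grid computation", {
  set.seed(45)
  truth <- sample_ground_truth()
  d <- simulate_dataset(truth, 60)
  fixed <- list(a = truth$a, v2 = truth$v2, w = truth$w, t0 = truth$t0,
                sv = truth$sv, sw = truth$sw, st0 = truth$st0)
  cfg <- fit_config(n_chains = 2, warmup = c(150L, 200L),
                    sampling = c(500L, 500L), seed = 11,
                    neff_min = 50, releff_min = 0.01, rhat_max = 1.05)
  fit <- fit_dm(d, config = cfg, fixed = fixed)
  expect_identical(fit$free, "v1")
  draws <- pooled_draws(fit, "v1")

  # grid posterior over v1 on [0, 5] (Riemann normalization)
  pr <- default_priors()
  grid <- seq(0.002, 4.998, length.out = 400)
  lp <- vapply(grid, function(v) {
    ps <- list(dm_params(a = truth$a, v = v, w = truth$w, t0 = truth$t0,
                         sv = truth$sv, sw = truth$sw, st0 = truth$st0),
               truth_params(truth, 2))
    loglik_dataset(d, ps, precision_spec(refine = FALSE)) + dprior(pr$v, v)
  }, numeric(1))
  wgt <- exp(lp - max(lp)); wgt <- wgt / sum(wgt)
  gm <- sum(grid * wgt)
  gs <- sqrt(sum((grid - gm)^2 * wgt))
  ne <- fit$diagnostics$n_eff[1]
  expect_lt(abs(mean(draws) - gm), 3 * mcse(draws, ne))
  expect_lt(abs(sd(draws) - gs), 3 * gs / sqrt(ne))
})

test_that("escalation stops at the first passing level and records it", {
  set.seed(46)
  truth <- sample_ground_truth()
  d <- simulate_dataset(truth, 20)
  cfg <- tiny_config(seed = 8)
  fit <- fit_with_escalation(d, config = cfg)
  expect_true(fit$status %in% c("pass", "soft_pass", "fail"))
  if (fit$status == "pass") expect_lte(fit$level, length(cfg$warmup))
  # degenerate dataset errors out
  bad <- data.frame(rt = c(0.05, 0.06), response = c(0L, 1L),
                    condition = c(1L, 2L))
  expect_error(fit_dm(bad, config = cfg), "degenerate")
})

test_that("the random-walk backend samples the same posterior shape", {
  set.seed(47)
  truth <- sample_ground_truth()
  d <- simulate_dataset(truth, 20)
  cfg <- tiny_config(seed = 21)
  cfg$sampler <- "rwm"
  fit <- fit_dm(d, config = cfg)
  # divergences are not applicable to a non-HMC backend and must not fail
  # the diagnosis on their own
  expect_true(is.na(fit$divergences))
  dg <- diagnose(fit, neff_min = 1, releff_min = 1e-6, rhat_max = 10)
  expect_true(dg$pass)
  # draws respect the constrained support
  expect_true(all(fit$draws[, , "a"] >= 0.5 & fit$draws[, , "a"] <= 3))
  expect_true(all(fit$draws[, , "w"] - fit$draws[, , "sw"] / 2 > 0))
})
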