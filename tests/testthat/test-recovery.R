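test_that("highest-density intervals behave on canonical samples", {
  # uniform grid: every window ties in width, lowest start wins
  expect_identical(hdi(1:100, 0.95), c(1, 95))
  # standard normal: matches the symmetric quantile interval
  set.seed(51)
  x <- rnorm(1e5)
  h <- hdi(x, 0.95)
  expect_lt(abs(h[1] + 1.96), 0.05)
  expect_lt(abs(h[2] - 1.96), 0.05)
  # point mass: zero-width interval at the value
  expect_identical(hdi(rep(2.5, 200), 0.5), c(2.5, 2.5))
  expect_error(hdi(1:50, 0.95), "at least 100")
  expect_error(hdi(1:200, 1.2), "mass")
})

test_that("Monte-Carlo standard error is SD over sqrt(N_eff)", {
  set.seed(52)
  x <- rnorm(4000)
  expect_equal(mcse(x, 400), sd(x) / 20, tolerance = 1e-12)
  expect_identical(mcse(rep(1, 100), 50), 0)
  expect_error(mcse(x, 0), "n_eff")
})

test_that("a two-dataset smoke study produces a structurally valid report", {
  rep2 <- recovery_study(2, n_trials = 20, config = tiny_config(seed = 3))
  expect_s3_class(rep2, "recovery_report")
  expect_identical(nrow(rep2$table), 8L)
  expect_true(all(c("r", "coverage50", "coverage95", "mMCSE") %in%
                    names(rep2$table)))
  expect_true(all(rep2$table$coverage95 >= 0 & rep2$table$coverage95 <= 100))
  expect_true(all(rep2$table$mMCSE >= 0, na.rm = TRUE))
  expect_identical(rep2$n_datasets, 2L)
})

test_that("four-parameter recovery: medians track the truth across replicates", {
  # restricted model: generator and model both have no variabilities
  set.seed(53)
  pr <- default_priors()
  cfg <- fit_config(n_chains = 2, warmup = c(100L, 250L),
                    sampling = c(250L, 400L), seed = 77,
                    neff_min = 60, releff_min = 0.01, rhat_max = 1.05)
  n_rep <- 6
  hit <- 0; total <- 0
  for (i in 1:n_rep) {
    set.seed(700 + i)
    g <- sample_ground_truth(pr)
    g$sv <- 0; g$sw <- 0; g$st0 <- 0
    d <- simulate_dataset(g, 100)
    fit <- fit_dm(d, pr, cfg, fixed = list(sv = 0, sw = 0, st0 = 0))
    for (p in c("a", "v1", "w", "t0")) {
      dr <- pooled_draws(fit, p)
      total <- total + 1
      if (abs(median(dr) - unlist(g)[[p]]) < 3 * sd(dr)) hit <- hit + 1
    }
  }
  # posterior medians within 3 posterior SDs of truth on >= 90% of checks
  expect_gte(hit / total, 0.9)
})

test_that("the full-model batch recovers parameters with calibrated intervals", {
  batch <- get_study_batch()
  rep <- recovery_study(STUDY_N, STUDY_TRIALS, results = batch)
  expect_identical(rep$n_datasets, STUDY_N)
  expect_lte(rep$n_excluded, 3L)
  # the main structural parameters correlate strongly with the truth
  tab <- rep$table
  for (p in c("a", "v1", "v2", "t0"))
    expect_gt(tab$r[tab$param == p], 0.5)
  # empirical HDI coverage is consistent with its nominal mass: compare
  # per-dataset coverage proportions with a 3-SE band computed from their
  # observed spread (accounts for within-dataset correlation)
  used <- batch[vapply(batch, function(r) r$status != "fail", logical(1))]
  for (mass in c("hdi50", "hdi95")) {
    nominal <- if (mass == "hdi50") 0.5 else 0.95
    ci <- vapply(used, function(r) {
      tr <- unlist(r$truth)
      mean(vapply(names(r$median), function(p) {
        h <- r[[mass]][[p]]
        tr[[p]] >= h[1] && tr[[p]] <= h[2]
      }, logical(1)))
    }, numeric(1))
    se <- max(sd(ci) / sqrt(length(ci)), sqrt(nominal * (1 - nominal) / (8 * length(ci))))
    expect_lt(abs(mean(ci) - nominal), 3 * se)
  }
})

test_that("recovery quality improves with trial count", {
  rep_big <- recovery_study(STUDY_N, STUDY_TRIALS, results = get_study_batch())
  rep_small <- recovery_study(SMALL_N, SMALL_TRIALS,
                              results = get_small_trial_batch())
  tb <- rep_big$table; ts_ <- rep_small$table
  # mean MCSE decreases with more trials for the drift parameters, whose
  # posterior scale shrinks most clearly with information
  expect_lt(mean(tb$mMCSE[tb$param %in% c("v1", "v2")]),
            mean(ts_$mMCSE[ts_$param %in% c("v1", "v2")]))
  # average truth-median correlation is higher with more trials
  expect_gt(mean(tb$r), mean(ts_$r) - 0.05)
})

test_that("variability parameters recover less well than structural ones", {
  rep <- recovery_study(STUDY_N, STUDY_TRIALS, results = get_study_batch())
  tab <- rep$table
  r_struct <- mean(tab$r[tab$param %in% c("a", "v1", "v2", "t0", "w")])
  r_var <- mean(tab$r[tab$param %in% c("sv", "sw")])
  expect_gt(r_struct, r_var)
})
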