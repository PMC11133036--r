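# Shared simulation-study batch, computed once per test run and reused by
# the recovery and calibration tests (the same simulated data are analyzed
# both ways).  Sizes are scaled to keep a full test run on one CPU within
# minutes; the calibration identity (truth drawn from the prior implies
# nominal coverage and uniform ranks) holds at any scale, only the
# Monte-Carlo resolution changes.

STUDY_N <- 10L          # datasets in the main batch
STUDY_TRIALS <- 100L    # trials per dataset (50 per condition)
STUDY_L <- 79L          # thinned draws -> ranks in 0..79
STUDY_B <- 4L           # rank-histogram bins (expected count N/B = 4)

study_config <- function(seed = 20260L) {
  fit_config(n_chains = 2L, warmup = c(150L, 400L), sampling = c(400L, 500L),
             seed = seed, neff_min = STUDY_L + 1, releff_min = 0.05,
             rhat_max = 1.02, rhat_soft = 1.05)
}

.study_cache <- new.env(parent = emptyenv())

get_study_batch <- function() {
  if (is.null(.study_cache$batch)) {
    .study_cache$batch <- wiener7:::run_study(
      STUDY_N, STUDY_TRIALS, default_priors(), study_config(),
      keep_thinned = STUDY_L)
  }
  .study_cache$batch
}

# smaller-information arm (fewer trials, same protocol) for directional
# comparisons of recovery quality with trial count
SMALL_N <- 6L
SMALL_TRIALS <- 24L

get_small_trial_batch <- function() {
  if (is.null(.study_cache$small)) {
    .study_cache$small <- wiener7:::run_study(
      SMALL_N, SMALL_TRIALS, default_priors(), study_config(seed = 4813L))
  }
  .study_cache$small
}

# a deliberately broken "fitter": ignores the data and returns iid prior
# draws with the boundary-separation draws shifted upward; simulation-based
# calibration must detect this
broken_fitter <- function(data, priors, config, fixed = list()) {
  n_s <- 400L
  pars <- c("a", "v1", "v2", "w", "t0", "sv", "sw", "st0")
  draws <- array(NA_real_, c(n_s, 2L, 8L), dimnames = list(NULL, NULL, pars))
  for (ch in 1:2) for (i in seq_len(n_s)) {
    g <- unlist(sample_ground_truth(priors))
    g["a"] <- min(g[["a"]] + 0.5, 3)
    draws[i, ch, ] <- g[pars]
  }
  diag_df <- data.frame(param = pars, rhat = 1.0, n_eff = 2 * n_s)
  structure(list(draws = draws, diagnostics = diag_df, divergences = 0L,
                 n_samp = 2L * n_s, level = 1L, free = pars,
                 status = "pass"),
            class = "posterior_result")
}
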