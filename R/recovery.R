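#' Highest-density interval of a posterior sample
#'
#' Shortest contiguous interval of the sorted draws containing
#' `ceiling(mass * n)` of them; ties in width are broken towards the
#' lowest start.
#'
#' @param draws numeric vector of posterior draws (>= 100).
#' @param mass interval mass in (0,1), typically 0.5 or 0.95.
#' @return Numeric vector `c(lo, hi)`.
#' @export
hdi <- function(draws, mass = 0.95) {
  if (length(draws) < 100) stop("need at least 100 draws for an HDI")
  if (mass <= 0 || mass >= 1) stop("'mass' must be in (0,1)")
  x <- as.numeric(sort(draws))
  n <- length(x)
  k <- ceiling(mass * n)
  if (k >= n) return(c(x[1], x[n]))
  widths <- x[(k):n] - x[1:(n - k + 1)]
  i <- which.min(widths)
  c(x[i], x[i + k - 1])
}

#' Monte Carlo standard error of a posterior summary
#'
#' Defined as the posterior sample SD divided by the square root of the
#' effective sample size.
#'
#' @param draws posterior draws.
#' @param n_eff effective sample size (> 0).
#' @return Scalar MCSE.
#' @export
mcse <- function(draws, n_eff) {
  if (!is.finite(n_eff) || n_eff <= 0) stop("'n_eff' must be > 0")
  sd(draws) / sqrt(n_eff)
}

# one simulated dataset: truth -> data -> escalated fit -> summaries
run_one_dataset <- function(index, n_trials, priors, config, dt = 1e-4,
                            keep_thinned = 0L, fitter = fit_with_escalation) {
  set.seed(child_seed(config$seed, index))
  truth <- sample_ground_truth(priors)
  data <- simulate_dataset(truth, n_trials, dt = dt)
  cfg <- config
  cfg$seed <- child_seed(config$seed, 500000L + index)
  fit <- fitter(data, priors, cfg)
  pars <- fit$free
  med <- hdi50 <- hdi95 <- ms <- list()
  for (p in pars) {
    dr <- pooled_draws(fit, p)
    med[[p]] <- median(dr)
    hdi50[[p]] <- hdi(dr, 0.5)
    hdi95[[p]] <- hdi(dr, 0.95)
    ne <- fit$diagnostics$n_eff[fit$diagnostics$param == p]
    ms[[p]] <- mcse(dr, ne)
  }
  out <- list(index = index, truth = truth, status = fit$status,
              level = fit$level, divergences = fit$divergences,
              median = unlist(med), hdi50 = hdi50, hdi95 = hdi95,
              mcse = unlist(ms),
              diagnostics = fit$diagnostics)
  if (keep_thinned > 0L) {
    # a fit that ended the escalation schedule under-resolved cannot be
    # thinned to keep_thinned near-independent draws; leave it unthinned
    # (the calibration study excludes it and reports the exclusion)
    if (min(fit$diagnostics$n_eff) >= keep_thinned + 1) {
      thinned <- sapply(pars, function(p)
        thin_to_independent(pooled_draws(fit, p), keep_thinned,
                            n_eff = min(fit$diagnostics$n_eff)))
      out$thinned <- thinned         # L x n_params matrix
    }
    out$data <- data
  }
  out
}

# shared batch engine for the recovery and calibration studies
run_study <- function(n_datasets, n_trials, priors = default_priors(),
                      config = fit_config(), dt = 1e-4, keep_thinned = 0L,
                      fitter = fit_with_escalation, progress = FALSE) {
  lapply(seq_len(n_datasets), function(i) {
    if (progress) message("dataset ", i, "/", n_datasets)
    run_one_dataset(i, n_trials, priors, config, dt, keep_thinned, fitter)
  })
}

#' Parameter-recovery study
#'
#' Repeatedly samples a ground truth from the priors, simulates a
#' two-condition dataset, fits it with the escalation protocol, and
#' aggregates per parameter: the Pearson correlation between truths and
#' posterior medians, the percentage of datasets whose truth lies in the
#' 50% and 95% HDIs, the mean Monte Carlo standard error, and the bias
#' samples (median minus truth).  Datasets whose diagnostics still fail
#' after escalation are excluded from the aggregates and reported.
#'
#' @param n_datasets number of simulated datasets (>= 2).
#' @param n_trials trials per dataset (even; 100 and 500 are the
#'   reference designs).
#' @param priors named prior list.
#' @param config a [fit_config()]; `config$seed` is the study root seed.
#' @param dt simulator step size.
#' @param results optional precomputed `run_study()` output to aggregate
#'   (used to share fits with an SBC study).
#' @param progress print per-dataset progress messages.
#' @return Object of class `recovery_report`: data frame `table` with
#'   columns `param, r, coverage50, coverage95, mMCSE`, matrix `bias`,
#'   counts of excluded datasets, and the raw per-dataset summaries.
#' @export
recovery_study <- function(n_datasets, n_trials = 100,
                           priors = default_priors(), config = fit_config(),
                           dt = 1e-4, results = NULL, progress = FALSE) {
  if (is.null(results)) {
    if (n_datasets < 2) stop("'n_datasets' must be >= 2")
    results <- run_study(n_datasets, n_trials, priors, config, dt,
                         progress = progress)
  }
  ok <- vapply(results, function(r) r$status != "fail", logical(1))
  used <- results[ok]
  if (!length(used)) stop("all datasets failed diagnostics")
  pars <- names(used[[1]]$median)
  truths <- sapply(used, function(r) unlist(r$truth)[pars])
  medians <- sapply(used, function(r) r$median[pars])
  tab <- data.frame(param = pars, r = NA_real_, coverage50 = NA_real_,
                    coverage95 = NA_real_, mMCSE = NA_real_)
  bias <- matrix(NA_real_, length(used), length(pars),
                 dimnames = list(NULL, pars))
  for (k in seq_along(pars)) {
    p <- pars[k]
    tr <- truths[k, ]; md <- medians[k, ]
    tab$r[k] <- cor(tr, md)
    in50 <- mapply(function(r, t) {
      h <- r$hdi50[[p]]; t >= h[1] && t <= h[2]
    }, used, tr)
    in95 <- mapply(function(r, t) {
      h <- r$hdi95[[p]]; t >= h[1] && t <= h[2]
    }, used, tr)
    tab$coverage50[k] <- 100 * mean(in50)
    tab$coverage95[k] <- 100 * mean(in95)
    tab$mMCSE[k] <- mean(vapply(used, function(r) r$mcse[[p]], numeric(1)))
    bias[, k] <- md - tr
  }
  structure(list(table = tab, bias = bias,
                 n_datasets = length(results), n_used = length(used),
                 n_excluded = sum(!ok), n_trials = n_trials,
                 levels_used = table(vapply(results, `[[`, 0L, "level")),
                 results = results),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Parameter recovery:", x$n_used, "of", x$n_datasets, "datasets used (",
      x$n_excluded, "excluded after failed diagnostics ),",
      x$n_trials, "trials each\n")
  tab <- x$table
  tab$r <- round(tab$r, 3)
  tab$coverage50 <- round(tab$coverage50, 1)
  tab$coverage95 <- round(tab$coverage95, 1)
  tab$mMCSE <- signif(tab$mMCSE, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}
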