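#' Thin posterior draws to near-independent draws
#'
#' Uniform-stride thinning of the pooled chains down to `L` draws, used
#' before rank statistics so that the draws are approximately independent
#' (the stride is `floor(N / L)`).  Requires the effective sample size to
#' exceed `L`, otherwise more warmup/sampling is needed first.
#'
#' @param draws pooled posterior draws (vector or matrix with draws in
#'   rows).
#' @param L target number of thinned draws (399 in the reference
#'   protocol, giving ranks in 0..399).
#' @param n_eff effective sample size of the draws (checked against `L`).
#' @return The `L` thinned draws (same column structure as the input).
#' @export
thin_to_independent <- function(draws, L, n_eff = NULL) {
  x <- if (is.matrix(draws)) draws else matrix(draws, ncol = 1)
  N <- nrow(x)
  if (N < L) stop("need at least L draws")
  if (!is.null(n_eff) && is.finite(n_eff) && n_eff < L + 1)
    stop("effective sample size (", round(n_eff), ") below L + 1 = ", L + 1,
         ": escalate warmup/sampling before thinning")
  stride <- max(1L, floor(N / L))
  idx <- seq(1L, by = stride, length.out = L)
  out <- x[idx, , drop = FALSE]
  if (is.matrix(draws)) out else as.vector(out)
}

#' Tie-randomized rank statistic
#'
#' Rank of the ground-truth value within `L` posterior values of a test
#' quantity: the count of posterior values strictly below the truth, plus
#' a uniform integer on `0..r_equals` to randomize ties.  Under a correct
#' sampler the rank is uniform on the integers `0..L`.
#'
#' @param values numeric vector of `L` posterior test-quantity values.
#' @param truth_value the same quantity at the ground truth.
#' @return Integer rank in `0..L`.
#' @export
rank_statistic <- function(values, truth_value) {
  r_less <- sum(values < truth_value)
  r_equal <- sum(values == truth_value)
  K <- if (r_equal > 0) sample.int(r_equal + 1L, 1L) - 1L else 0L
  as.integer(r_less + K)
}

#' Test quantities for simulation-based calibration
#'
#' Nine scalar functions of (parameters, data): the identity map of each
#' of the 8 model parameters, plus the joint log-likelihood of the dataset
#' at the parameters (the data-space extension of the calibration check;
#' the prior term is deliberately excluded).
#'
#' @param truth a `ground_truth`.
#' @param thinned L x 8 matrix of thinned posterior draws (columns named
#'   `a, v1, v2, w, t0, sv, sw, st0`).
#' @param data the dataset the posterior was fitted to.
#' @param prec [precision_spec()] for the log-likelihood evaluations.
#' @return Named list per quantity: `list(truth = scalar, values = L
#'   posterior values)`.
#' @export
test_quantities <- function(truth, thinned, data,
                            prec = precision_spec(refine = FALSE)) {
  pars <- colnames(thinned)
  out <- list()
  tvec <- unlist(truth)
  for (p in pars)
    out[[p]] <- list(truth = tvec[[p]], values = thinned[, p])
  ll_of <- function(x) {
    ps <- lapply(1:2, function(cc)
      dm_params(a = x[["a"]], v = if (cc == 1) x[["v1"]] else x[["v2"]],
                w = x[["w"]], t0 = x[["t0"]], sv = x[["sv"]],
                sw = x[["sw"]], st0 = x[["st0"]]))
    loglik_dataset(data, ps, prec)
  }
  out$log_density <- list(
    truth = ll_of(tvec),
    values = apply(thinned, 1, ll_of)
  )
  out
}

#' Rank-uniformity histogram with a 99% binomial band
#'
#' Bins ranks on `0..L` into `B` equal bins ( `(L+1)/B` consecutive rank
#' values per bin) and computes the 99% central band of a per-bin count
#' under uniformity, i.e. the 0.005 and 0.995 quantiles of
#' `Binomial(N, 1/B)`.
#'
#' @param ranks integer ranks in `0..L`.
#' @param B number of bins; must divide `L + 1`.
#' @param L maximum rank.
#' @return List with `counts` (length `B`, summing to `length(ranks)`),
#'   `band` (`c(lo, hi)`), and `expected` (`N / B`).
#' @export
uniformity_histogram <- function(ranks, B, L = max(ranks)) {
  if ((L + 1) %% B != 0)
    stop("'B' must divide L + 1 for equal-width rank bins")
  if (any(ranks < 0 | ranks > L)) stop("ranks outside 0..L")
  per <- (L + 1) / B
  bin <- floor(ranks / per) + 1L
  counts <- tabulate(bin, nbins = B)
  N <- length(ranks)
  band <- qbinom(c(0.005, 0.995), N, 1 / B)
  list(counts = counts, band = band, expected = N / B)
}

#' Chi-square test of rank uniformity
#'
#' Pearson chi-square of observed bin counts against the uniform
#' expectation `N/B` per bin, with `B - 1` degrees of freedom (critical
#' value 123.23 at the 5% level for 100 bins).
#'
#' @param counts per-bin counts.
#' @return List with `statistic`, `df`, `p_value` (upper tail).
#' @export
chi2_uniformity <- function(counts) {
  B <- length(counts)
  if (B < 2) stop("need at least 2 bins")
  N <- sum(counts)
  e <- N / B
  if (e <= 0) stop("zero expected count")
  stat <- sum((counts - e)^2 / e)
  list(statistic = stat, df = B - 1L,
       p_value = pchisq(stat, B - 1, lower.tail = FALSE))
}

#' Fisher's combined probability test
#'
#' Aggregates independent p-values via `X = -2 sum(log p)`, referred to a
#' chi-square distribution with `2k` degrees of freedom (upper tail).
#'
#' @param pvalues vector of p-values in (0, 1].
#' @return List with `statistic`, `df`, `p_value`.
#' @export
fisher_combined <- function(pvalues) {
  if (any(pvalues <= 0)) stop("p-values must be > 0 (log of zero is infinite)")
  if (any(pvalues > 1)) stop("p-values must be <= 1")
  X <- -2 * sum(log(pvalues))
  k <- length(pvalues)
  list(statistic = X, df = 2L * k,
       p_value = pchisq(X, 2 * k, lower.tail = FALSE))
}

#' Simulation-based calibration study
#'
#' For each simulated dataset: sample a truth from the priors, simulate,
#' fit with the same priors, thin the pooled draws to `L` near-independent
#' draws, and compute the tie-randomized rank of the truth for each of the
#' 9 test quantities.  Aggregates rank histograms (with the 99% binomial
#' band), per-quantity chi-square uniformity tests, and Fisher's combined
#' probability test across quantities.  If a correctly implemented
#' sampler produced the posteriors, every rank histogram is uniform.
#'
#' @param n_datasets number of simulated datasets.
#' @param n_trials trials per dataset.
#' @param priors named prior list (generator and fitting priors must be
#'   identical for the calibration identity to hold).
#' @param config a [fit_config()].
#' @param B number of histogram bins; must divide `L + 1`.
#' @param L thinned sample size (ranks lie in `0..L`).
#' @param dt simulator step size.
#' @param results optional precomputed `run_study(..., keep_thinned = L)`
#'   output, e.g. shared with [recovery_study()].
#' @param progress print per-dataset progress messages.
#' @return Object of class `sbc_report`: per-quantity ranks, histograms,
#'   chi-square results, and the Fisher combination.
#' @export
sbc_study <- function(n_datasets, n_trials = 100, priors = default_priors(),
                      config = fit_config(), B = 100, L = 399, dt = 1e-4,
                      results = NULL, progress = FALSE) {
  if (is.null(results))
    results <- run_study(n_datasets, n_trials, priors, config, dt,
                         keep_thinned = L, progress = progress)
  ok <- vapply(results, function(r) r$status != "fail" &&
                 !is.null(r$thinned), logical(1))
  used <- results[ok]
  if (!length(used)) stop("no usable fits for SBC")
  qnames <- c(colnames(used[[1]]$thinned), "log_density")
  ranks <- matrix(NA_integer_, length(used), length(qnames),
                  dimnames = list(NULL, qnames))
  for (i in seq_along(used)) {
    r <- used[[i]]
    set.seed(child_seed(config$seed, 900000L + r$index))  # tie randomization
    tq <- test_quantities(r$truth, r$thinned, r$data, config$prec)
    for (q in qnames)
      ranks[i, q] <- rank_statistic(tq[[q]]$values, tq[[q]]$truth)
  }
  hist_list <- list(); chi2 <- list()
  for (q in qnames) {
    hist_list[[q]] <- uniformity_histogram(ranks[, q], B, L)
    chi2[[q]] <- chi2_uniformity(hist_list[[q]]$counts)
  }
  pv <- vapply(chi2, `[[`, numeric(1), "p_value")
  structure(list(ranks = ranks, histograms = hist_list, chi2 = chi2,
                 fisher = fisher_combined(pv),
                 B = B, L = L, n_datasets = length(results),
                 n_used = length(used), n_excluded = sum(!ok),
                 n_trials = n_trials),
            class = "sbc_report")
}

#' Rank-uniformity histograms of a calibration report
#'
#' One panel per test quantity: bin counts with the 99% binomial band of
#' a uniform histogram drawn as horizontal lines.
#'
#' @param x an `sbc_report`.
#' @param ... passed to [graphics::barplot()].
#' @return The report, invisibly.
#' @export
plot.sbc_report <- function(x, ...) {
  qn <- names(x$histograms)
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(qn)),
                       mar = c(2, 2, 2, 0.5))
  on.exit(graphics::par(old))
  for (q in qn) {
    h <- x$histograms[[q]]
    graphics::barplot(h$counts, main = q, border = NA, col = "firebrick",
                      ylim = c(0, max(h$counts, h$band[2]) * 1.05), ...)
    graphics::abline(h = h$band, col = "grey40", lty = 2)
    graphics::abline(h = h$expected, col = "grey70")
  }
  invisible(x)
}

#' @export
print.sbc_report <- function(x, ...) {
  cat("Simulation-based calibration:", x$n_used, "datasets (",
      x$n_excluded, "excluded ),", x$n_trials, "trials, L =", x$L,
      ", B =", x$B, "\n")
  tab <- data.frame(
    quantity = names(x$chi2),
    chi2 = round(vapply(x$chi2, `[[`, numeric(1), "statistic"), 2),
    df = vapply(x$chi2, `[[`, numeric(1), "df"),
    p = round(vapply(x$chi2, `[[`, numeric(1), "p_value"), 3))
  print(tab, row.names = FALSE)
  cat(sprintf("Fisher combined: chi2(%d) = %.2f, p = %.3f\n",
              x$fisher$df, x$fisher$statistic, x$fisher$p_value))
  invisible(x)
}
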