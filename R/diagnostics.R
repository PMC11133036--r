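# Convergence diagnostics for MCMC output: rank-normalized split R-hat and
# bulk effective sample size, following the rank-normalization approach of
# Vehtari, Gelman, Simpson, Carpenter & Buerkner (2021).

# split each chain in half -> iterations x (2 * chains) matrix
split_chains <- function(x) {
  n <- nrow(x)
  h <- floor(n / 2)
  cbind(x[seq_len(h), , drop = FALSE],
        x[(n - h + 1):n, , drop = FALSE])
}

# rank-normalize all draws jointly (fractional offset 3/8)
rank_normalize <- function(x) {
  r <- rank(x, ties.method = "average")
  z <- qnorm((r - 3 / 8) / (length(x) + 1 / 4))
  array(z, dim = dim(x))
}

# basic split R-hat on a (possibly transformed) iterations x chains matrix
rhat_basic <- function(x) {
  x <- split_chains(x)
  n <- nrow(x); m <- ncol(x)
  mu <- colMeans(x)
  s2 <- apply(x, 2, var)
  W <- mean(s2)
  B <- n * var(mu)
  varplus <- (n - 1) / n * W + B / n
  sqrt(varplus / W)
}

#' Rank-normalized split R-hat
#'
#' Maximum of the rank-normalized split R-hat of the draws and of their
#' folded (absolute deviation from the median) counterpart, so both
#' location and scale disagreements between chains are detected.
#'
#' @param x iterations x chains matrix of draws for one quantity.
#' @return Scalar R-hat.
#' @export
rhat <- function(x) {
  x <- as.matrix(x)
  zb <- rank_normalize(x)
  zf <- rank_normalize(abs(x - median(x)))
  max(rhat_basic(zb), rhat_basic(zf))
}

# ESS of an iterations x chains matrix via per-chain autocovariance and
# Geyer's initial monotone positive sequence
ess_mean <- function(x) {
  n <- nrow(x); m <- ncol(x)
  if (n < 4 || var(as.vector(x)) == 0) return(NA_real_)
  acov <- matrix(0, n, m)
  for (j in seq_len(m)) {
    acov[, j] <- acf(x[, j], lag.max = n - 1, type = "covariance",
                     plot = FALSE, demean = TRUE)$acf[, 1, 1]
  }
  chain_var <- acov[1, ] * n / (n - 1)
  mean_var <- mean(chain_var)
  var_plus <- mean_var * (n - 1) / n
  if (m > 1) var_plus <- var_plus + var(colMeans(x))
  macov <- rowMeans(acov)

  # Geyer initial positive sequence on lag pairs (0,1), (2,3), ...
  rho <- numeric(n)
  rho[1] <- 1
  rho[2] <- 1 - (mean_var - macov[2]) / var_plus
  rho_even <- rho[1]; rho_odd <- rho[2]
  t <- 1L
  while (t < n - 3 && (rho_even + rho_odd) > 0) {
    rho_even <- 1 - (mean_var - macov[t + 2]) / var_plus
    rho_odd <- 1 - (mean_var - macov[t + 3]) / var_plus
    if ((rho_even + rho_odd) >= 0) {
      rho[t + 2] <- rho_even
      rho[t + 3] <- rho_odd
    }
    t <- t + 2L
  }
  max_t <- t - 2L
  if (rho_even > 0) rho[max_t + 2] <- rho_even
  # initial monotone sequence: pair sums never increase
  t <- 1L
  while (t <= max_t - 2L) {
    if (rho[t + 2] + rho[t + 3] > rho[t] + rho[t + 1]) {
      rho[t + 2] <- (rho[t] + rho[t + 1]) / 2
      rho[t + 3] <- rho[t + 2]
    }
    t <- t + 2L
  }
  ess0 <- n * m
  tau <- -1 + 2 * sum(rho[1:(max_t + 1)]) + rho[max_t + 2]
  tau <- max(tau, 1 / log10(ess0))
  ess0 / tau
}

#' Rank-normalized bulk effective sample size
#'
#' Effective sample size of the rank-normalized split chains.
#'
#' @param x iterations x chains matrix of draws for one quantity.
#' @return Scalar effective sample size.
#' @export
ess_bulk <- function(x) {
  x <- as.matrix(x)
  z <- split_chains(rank_normalize(x))
  ess_mean(z)
}

#' Check the convergence diagnostics of a fit
#'
#' A fit passes when every parameter has effective sample size above
#' `neff_min`, relative effective sample size above `releff_min`,
#' rank-normalized split R-hat below `rhat_max`, and the sampler recorded
#' no divergent transitions.  A soft-pass tier (used after the warmup
#' escalation schedule is exhausted) accepts R-hat below `rhat_soft`.
#'
#' @param result a `posterior_result` from [fit_dm()].
#' @param neff_min minimum effective sample size (default 400).
#' @param releff_min minimum `N_eff / N_samp` (default 0.1).
#' @param rhat_max strict R-hat threshold (default 1.01).
#' @param rhat_soft soft-pass R-hat threshold (default 1.05).
#' @return List with logicals `pass` and `soft_pass`, and a character
#'   vector `reasons` naming each failed rule.
#' @export
diagnose <- function(result, neff_min = 400, releff_min = 0.1,
                     rhat_max = 1.01, rhat_soft = 1.05) {
  d <- result$diagnostics
  reasons <- character(0)
  nsamp <- result$n_samp
  bad <- d$param[d$n_eff <= neff_min]
  if (length(bad)) reasons <- c(reasons, paste0("n_eff<=", neff_min, ": ",
                                                paste(bad, collapse = ",")))
  bad <- d$param[d$n_eff / nsamp <= releff_min]
  if (length(bad)) reasons <- c(reasons, paste0("releff<=", releff_min, ": ",
                                                paste(bad, collapse = ",")))
  bad <- d$param[d$rhat >= rhat_max]
  if (length(bad)) reasons <- c(reasons, paste0("rhat>=", rhat_max, ": ",
                                                paste(bad, collapse = ",")))
  # NA divergences = backend without divergence semantics: rule skipped
  if (!is.na(result$divergences) && result$divergences > 0)
    reasons <- c(reasons, paste0("divergences=", result$divergences))
  soft <- all(d$rhat < rhat_soft) &&
    all(d$n_eff > neff_min) && all(d$n_eff / nsamp > releff_min) &&
    (is.na(result$divergences) || result$divergences == 0)
  list(pass = length(reasons) == 0L, soft_pass = soft, reasons = reasons)
}
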