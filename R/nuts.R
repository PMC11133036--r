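# No-U-Turn sampler (multinomial variant, diagonal metric, dual-averaging
# step-size adaptation).  The target is supplied as a function returning
# the log density and its gradient; the implementation follows the
# standard recursive doubling scheme with a generalized U-turn criterion
# and Stan-style warmup phases (step-size buffer, metric estimation
# window, terminal step-size buffer).

# one leapfrog step; minv is the diagonal inverse metric
leapfrog <- function(lpg, z, p, grad, eps, minv) {
  p1 <- p + 0.5 * eps * grad
  z1 <- z + eps * minv * p1
  e1 <- lpg(z1)
  p1 <- p1 + 0.5 * eps * e1$grad
  list(z = z1, p = p1, lp = e1$lp, grad = e1$grad)
}

hamiltonian <- function(lp, p, minv) -lp + 0.5 * sum(minv * p * p)

DIVERGENCE_THRESHOLD <- 1000

# recursive subtree builder; returns NULL weights on divergence
build_tree <- function(lpg, state, depth, dir, eps, minv, H0, env) {
  if (depth == 0L) {
    st <- leapfrog(lpg, state$z, state$p, state$grad, dir * eps, minv)
    H <- if (is.finite(st$lp)) hamiltonian(st$lp, st$p, minv) else Inf
    dH <- H - H0
    env$n_leapfrog <- env$n_leapfrog + 1L
    env$sum_accept <- env$sum_accept + min(1, exp(-dH))
    env$n_accept <- env$n_accept + 1L
    if (!is.finite(dH) || dH > DIVERGENCE_THRESHOLD) {
      env$divergent <- TRUE
      return(list(minus = st, plus = st, prop = st, lw = -Inf, turning = TRUE))
    }
    list(minus = st, plus = st, prop = st, lw = -dH, turning = FALSE)
  } else {
    t1 <- build_tree(lpg, state, depth - 1L, dir, eps, minv, H0, env)
    if (t1$turning) return(t1)
    inner <- if (dir == 1) t1$plus else t1$minus
    t2 <- build_tree(lpg, inner, depth - 1L, dir, eps, minv, H0, env)
    minus <- if (dir == 1) t1$minus else t2$minus
    plus <- if (dir == 1) t2$plus else t1$plus
    turning <- t2$turning || uturn(minus, plus, minv)
    lw <- logsumexp2(t1$lw, t2$lw)
    prop <- t1$prop
    if (is.finite(t2$lw) && log(runif(1)) < t2$lw - lw) prop <- t2$prop
    list(minus = minus, plus = plus, prop = prop, lw = lw, turning = turning)
  }
}

uturn <- function(minus, plus, minv) {
  dz <- plus$z - minus$z
  sum(dz * (minv * minus$p)) < 0 || sum(dz * (minv * plus$p)) < 0
}

logsumexp2 <- function(a, b) {
  if (a == -Inf) return(b)
  if (b == -Inf) return(a)
  m <- max(a, b)
  m + log(exp(a - m) + exp(b - m))
}

nuts_transition <- function(lpg, z, eps, minv, max_treedepth, cur = NULL) {
  if (is.null(cur)) cur <- lpg(z)
  p0 <- rnorm(length(z)) / sqrt(minv)
  H0 <- hamiltonian(cur$lp, p0, minv)
  state <- list(z = z, p = p0, lp = cur$lp, grad = cur$grad)
  minus <- state; plus <- state; prop <- state
  lw <- 0.0
  env <- new.env()
  env$divergent <- FALSE; env$sum_accept <- 0; env$n_accept <- 0L
  env$n_leapfrog <- 0L
  depth <- 0L
  while (depth < max_treedepth) {
    dir <- if (runif(1) < 0.5) -1 else 1
    sub <- build_tree(lpg, if (dir == 1) plus else minus, depth, dir, eps,
                      minv, H0, env)
    if (dir == 1) plus <- sub$plus else minus <- sub$minus
    if (sub$turning) break    # discard a turning or divergent subtree
    # biased progressive sampling towards the new subtree
    if (log(runif(1)) < sub$lw - lw) prop <- sub$prop
    lw <- logsumexp2(lw, sub$lw)
    if (uturn(minus, plus, minv)) break
    depth <- depth + 1L
  }
  accept_stat <- if (env$n_accept > 0) env$sum_accept / env$n_accept else 0
  list(z = prop$z, lp = prop$lp, grad = prop$grad, cur = prop,
       divergent = env$divergent, accept_stat = accept_stat,
       treedepth = depth, n_leapfrog = env$n_leapfrog)
}

# reasonable initial step size: halve/double until acceptance crosses 1/2
find_epsilon <- function(lpg, z, minv) {
  eps <- 0.1
  cur <- lpg(z)
  p <- rnorm(length(z)) / sqrt(minv)
  H0 <- hamiltonian(cur$lp, p, minv)
  st <- leapfrog(lpg, z, p, cur$grad, eps, minv)
  dH <- H0 - (if (is.finite(st$lp)) hamiltonian(st$lp, st$p, minv) else Inf)
  dir <- if (dH > log(0.5)) 1 else -1
  for (i in 1:30) {
    eps <- eps * 2^dir
    st <- leapfrog(lpg, z, p, cur$grad, eps, minv)
    dH <- H0 - (if (is.finite(st$lp)) hamiltonian(st$lp, st$p, minv) else Inf)
    if ((dir == 1 && dH < log(0.5)) || (dir == -1 && dH > log(0.5))) break
  }
  eps
}

#' @noRd
nuts_chain <- function(lpg, z0, n_warmup, n_sample, max_treedepth = 5L,
                       target_accept = 0.8) {
  d <- length(z0)
  minv <- rep(1, d)
  eps <- find_epsilon(lpg, z0, minv)

  # dual averaging state
  mu <- log(10 * eps); lebar <- 0; hbar <- 0
  gamma <- 0.05; t0da <- 10; kappa <- 0.75; da_i <- 0L
  da_update <- function(a) {
    da_i <<- da_i + 1L
    hbar <<- (1 - 1 / (da_i + t0da)) * hbar + (target_accept - a) / (da_i + t0da)
    le <- mu - sqrt(da_i) / gamma * hbar
    lebar <<- da_i^(-kappa) * le + (1 - da_i^(-kappa)) * lebar
    eps <<- exp(le)
  }
  da_reset <- function() { mu <<- log(10 * eps); hbar <<- 0; lebar <<- log(eps); da_i <<- 0L }

  # warmup phases: step-size buffer, expanding metric-estimation windows
  # (doubling sizes), terminal step-size buffer
  w1 <- max(5L, floor(0.15 * n_warmup))
  w3 <- max(5L, floor(0.10 * n_warmup))
  adapt_end <- n_warmup - w3
  win_ends <- integer(0)
  pos <- w1; size <- 25L
  while (pos < adapt_end) {
    nxt <- min(pos + size, adapt_end)
    if (adapt_end - nxt < 2L * size) nxt <- adapt_end
    win_ends <- c(win_ends, nxt)
    pos <- nxt; size <- 2L * size
  }

  z <- z0; cur <- NULL
  window_draws <- NULL
  draws <- matrix(NA_real_, n_sample, d)
  lps <- numeric(n_sample)
  divergences <- 0L
  treedepths <- integer(n_sample)

  for (it in seq_len(n_warmup + n_sample)) {
    tr <- nuts_transition(lpg, z, eps, minv, max_treedepth, cur)
    z <- tr$z; cur <- tr$cur
    if (it <= n_warmup) {
      da_update(tr$accept_stat)
      if (it > w1 && it <= adapt_end) {
        window_draws <- rbind(window_draws, z)
        if (it %in% win_ends && nrow(window_draws) >= 10) {
          # regularized diagonal metric from the window draws
          nw <- nrow(window_draws)
          v <- apply(window_draws, 2, var)
          minv <- pmax(v * nw / (nw + 5) + 1e-3 * 5 / (nw + 5), 1e-8)
          window_draws <- NULL
          eps <- find_epsilon(lpg, z, minv)
          da_reset()
        }
      }
      if (it == n_warmup) eps <- exp(lebar)
    } else {
      k <- it - n_warmup
      draws[k, ] <- z
      lps[k] <- tr$lp
      treedepths[k] <- tr$treedepth
      if (tr$divergent) divergences <- divergences + 1L
    }
  }
  list(draws = draws, lp = lps, divergences = divergences,
       eps = eps, minv = minv, treedepth = treedepths)
}

# Adaptive random-walk Metropolis chain: a gradient-free fallback for
# debugging the posterior (never used for calibration runs; mixes far more
# slowly than NUTS).  Componentwise-scaled Gaussian proposals; the global
# scale adapts towards the classical 0.234 acceptance rate and the
# proposal covariance diagonal is re-estimated mid-warmup.
rwm_chain <- function(lpg, z0, n_warmup, n_sample, max_treedepth = NULL,
                      target_accept = 0.234) {
  d <- length(z0)
  scale <- 2.38 / sqrt(d)
  sds <- rep(1, d)
  z <- z0
  lp <- lpg(z)$lp
  half <- floor(n_warmup / 2)
  window <- matrix(NA_real_, half, d)
  draws <- matrix(NA_real_, n_sample, d)
  lps <- numeric(n_sample)
  acc <- 0
  for (it in seq_len(n_warmup + n_sample)) {
    zp <- z + scale * sds * rnorm(d)
    lpp <- lpg(zp)$lp
    if (log(runif(1)) < lpp - lp) { z <- zp; lp <- lpp; a <- 1 } else a <- 0
    if (it <= n_warmup) {
      acc <- acc + a
      scale <- scale * exp((a - target_accept) / sqrt(it))
      if (it > half - nrow(window) && it <= half) window[it - (half - nrow(window)), ] <- z
      if (it == half) {
        v <- apply(window, 2, var)
        if (all(is.finite(v)) && all(v > 0)) sds <- sqrt(v)
      }
    } else {
      k <- it - n_warmup
      draws[k, ] <- z
      lps[k] <- lp
    }
  }
  list(draws = draws, lp = lps, divergences = NA_integer_,
       eps = scale, minv = sds^2, treedepth = rep(NA_integer_, n_sample))
}
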