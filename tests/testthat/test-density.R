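test_that("both series expansions agree with brute-force oracles", {
  expect_lt(abs(f_small(0.1, 0.3, tol = 1e-12) - oracle_f_small(0.1, 0.3)),
            1e-12)
  expect_lt(abs(f_large(2.0, 0.5, tol = 1e-9) - oracle_f_large(2.0, 0.5)),
            1e-9)
  expect_lt(abs(f_small(2.0, 0.5, tol = 1e-9) - f_large(2.0, 0.5, tol = 1e-9)),
            1e-9)
  # positivity on support and large-time decay to zero
  expect_gt(f_large(0.5, 0.5), 0)
  fs <- vapply(c(3, 5, 8, 12), function(ts) f_large(ts, 0.5), numeric(1))
  expect_true(all(diff(fs) < 0))
  expect_lt(fs[4], 1e-20)
  expect_error(f_large(-1, 0.5), "tstar")
  expect_error(f_small(0, 0.5), "tstar")
})

test_that("series cross-agreement holds over 1000 random points", {
  set.seed(11)
  mx <- 0
  for (i in 1:1000) {
    ts <- exp(runif(1, log(0.01), log(5)))
    w <- runif(1, 0.05, 0.95)
    mx <- max(mx, abs(f_small(ts, w, 1e-9) - f_large(ts, w, 1e-9)))
  }
  expect_lt(mx, 2e-9)
})

test_that("expansion selection picks the cheaper series and stays accurate", {
  expect_identical(choose_expansion(0.05, 0.5, 1e-6)$method, "small")
  expect_identical(choose_expansion(5, 0.5, 1e-6)$method, "large")
  set.seed(12)
  for (i in 1:50) {
    ts <- exp(runif(1, log(0.02), log(4)))
    w <- runif(1, 0.1, 0.9)
    sel <- choose_expansion(ts, w, 1e-6)
    val <- if (sel$method == "small") f_small(ts, w, 1e-6) else f_large(ts, w, 1e-6)
    expect_lt(abs(val - oracle_f_small(ts, w)), 1e-6)
  }
})

test_that("four-parameter density matches the kernel and normalizes", {
  # below the non-decision time the density is zero
  expect_identical(wiener4_density(0.5, a = 1, v = 0, w = 0.5, t0 = 0.6), 0)
  # v = 0 reduces to the bare kernel / a^2
  expect_lt(abs(wiener4_density(1.0, a = 1, v = 0, w = 0.5, t0 = 0) -
                  oracle_f_small(1.0, 0.5)), 1e-9)
  # total mass over both boundaries is 1
  pu <- integrate(function(y) wiener4_density(y, 1, -1.2, 1 - 0.4, 0),
                  0, 60, rel.tol = 1e-8)$value
  pl <- integrate(function(y) wiener4_density(y, 1, 1.2, 0.4, 0),
                  0, 60, rel.tol = 1e-8)$value
  expect_equal(pu + pl, 1, tolerance = 1e-4)
})

test_that("drift-variability factor reproduces the normal mixture integral", {
  expect_identical(m_factor(0.7, a = 1.3, v = 1.1, omega = 0.4, sv = 0), 1)
  # t -> 0 limit: the drift-dependence of the kernel does not vanish at
  # t = 0, so M tends to exp(sv^2 a^2 omega^2 / 2) (equals 1 only at sv = 0)
  expect_equal(m_factor(1e-12, a = 1.3, v = 1.1, omega = 0.4, sv = 0.8),
               exp(0.8^2 * 1.3^2 * 0.4^2 / 2), tolerance = 1e-9)
  # against direct integration of p3 over nu ~ N(v, sv^2)
  for (case in list(c(0.7, 1.3, 1.1, 0.4, 0.8), c(0.4, 0.9, -2, 0.6, 1.7))) {
    t <- case[1]; a <- case[2]; v <- case[3]; om <- case[4]; sv <- case[5]
    lhs <- m_factor(t, a, v, om, sv) * wiener4_density(t, a, v, om, 0, tol = 1e-12)
    rhs <- integrate(function(nu) vapply(nu, function(x)
      wiener4_density(t, a, x, om, 0, tol = 1e-12), numeric(1)) * dnorm(nu, v, sv),
      v - 9 * sv, v + 9 * sv, rel.tol = 1e-10, subdivisions = 600L)$value
    expect_equal(lhs, rhs, tolerance = 1e-7)
  }
})

test_that("seven-parameter log-density: reduction, mirroring, support", {
  p0 <- dm_params(a = 1.2, v = 1.5, w = 0.4, t0 = 0.3)
  # all variabilities zero: equals the closed form exactly (same kernel tol)
  pr9 <- precision_spec(1e-9)
  expect_lt(abs(wiener7_logdensity(0.9, 1, p0, pr9) -
                  wiener4_density(0.9, 1.2, -1.5, 0.6, 0.3, log = TRUE)), 1e-13)
  expect_lt(abs(wiener7_logdensity(0.9, 0, p0, pr9) -
                  wiener4_density(0.9, 1.2, 1.5, 0.4, 0.3, log = TRUE)), 1e-13)
  # mirroring identity is exact by construction
  p <- dm_params(a = 1.2, v = 1.5, w = 0.4, t0 = 0.3, sv = 0.5, sw = 0.1, st0 = 0.1)
  pm <- dm_params(a = 1.2, v = -1.5, w = 0.6, t0 = 0.3, sv = 0.5, sw = 0.1, st0 = 0.1)
  expect_identical(wiener7_logdensity(0.8, 0, p), wiener7_logdensity(0.8, 1, pm))
  # off support: -Inf, not an error
  expect_identical(wiener7_logdensity(0.2, 1, p0), -Inf)
  expect_identical(wiener7_logdensity(0.3, 1, p), -Inf)
  # structurally invalid parameters raise
  expect_error(dm_params(a = -1, v = 0, w = 0.5, t0 = 0.1), "must be > 0")
  expect_error(dm_params(a = 1, v = 0, w = 0.3, t0 = 0.1, sw = 0.7), "joint constraint", fixed = TRUE)
})

test_that("full density matches a Monte-Carlo mixture oracle", {
  set.seed(13)
  p <- dm_params(a = 1.2, v = 1.5, w = 0.4, t0 = 0.3, sv = 0.5, sw = 0.1, st0 = 0.1)
  for (resp in c(1, 0)) {
    y <- 0.8
    n <- 5e5
    nu <- rnorm(n, p$v, p$sv)
    om <- runif(n, p$w - p$sw / 2, p$w + p$sw / 2)
    tau <- runif(n, p$t0, p$t0 + p$st0)
    # mirror by hand for the requested boundary
    vv <- if (resp == 1) -nu else nu
    ww <- if (resp == 1) 1 - om else om
    vals <- exp(.logp3_mix_cpp(y - tau, p$a, vv, ww, 1e-10))
    mc <- mean(vals); se <- sd(vals) / sqrt(n)
    expect_lt(abs(exp(wiener7_logdensity(y, resp, p, precision_spec(1e-9))) - mc),
              3 * se)
  }
})

test_that("normalization holds with variabilities on random parameter sets", {
  set.seed(14)
  for (i in 1:6) {
    p <- random_params()
    mass <- oracle_boundary_mass(p, 1) + oracle_boundary_mass(p, 0)
    expect_equal(mass, 1, tolerance = 1e-3)
  }
})

test_that("tightening the tolerance changes the density by less than tol", {
  set.seed(15)
  for (i in 1:10) {
    p <- random_params()
    y <- p$t0 + rexp(1, 2) + 0.01
    d1 <- exp(wiener7_logdensity(y, 1, p, precision_spec(1e-6)))
    d2 <- exp(wiener7_logdensity(y, 1, p, precision_spec(1e-12)))
    expect_lt(abs(d1 - d2), 2e-6)
  }
})

test_that("dataset log-likelihood is the sum of per-trial terms", {
  p1 <- dm_params(a = 1.1, v = 1.2, w = 0.45, t0 = 0.25, sv = 0.4, sw = 0.1, st0 = 0.1)
  p2 <- dm_params(a = 1.1, v = -0.8, w = 0.45, t0 = 0.25, sv = 0.4, sw = 0.1, st0 = 0.1)
  empty <- data.frame(rt = numeric(0), response = integer(0), condition = integer(0))
  expect_identical(loglik_dataset(empty, list(p1, p2)), 0)
  two <- data.frame(rt = c(0.7, 0.7), response = c(1, 1), condition = c(1, 1))
  expect_equal(loglik_dataset(two, list(p1, p2)),
               2 * wiener7_logdensity(0.7, 1, p1), tolerance = 1e-12)
  set.seed(16)
  d <- data.frame(rt = 0.3 + rexp(10, 2), response = rbinom(10, 1, 0.5),
                  condition = rep(1:2, 5))
  by_hand <- sum(vapply(seq_len(10), function(i)
    wiener7_logdensity(d$rt[i], d$response[i], if (d$condition[i] == 1) p1 else p2),
    numeric(1)))
  expect_equal(loglik_dataset(d, list(p1, p2)), by_hand, tolerance = 1e-10)
  expect_error(loglik_dataset(data.frame(rt = 1, response = 1, condition = 3),
                              list(p1, p2)), "condition")
})

test_that("analytic gradient matches finite differences and mirrors drift", {
  set.seed(17)
  # mirroring symmetry of the drift component at v = 0
  p0 <- dm_params(a = 1, v = 0, w = 0.5, t0 = 0.2)
  gu <- grad_logdensity(0.8, 1, p0)
  gl <- grad_logdensity(0.8, 0, p0)
  expect_equal(unname(gu["v"]), -unname(gl["v"]), tolerance = 1e-9)
  # full gradient vs plain central differences
  p <- dm_params(a = 1, v = 1, w = 0.5, t0 = 0.2, sv = 0.3, sw = 0.1, st0 = 0.1)
  g <- grad_logdensity(0.9, 1, p)
  fd <- oracle_grad_fd(0.9, 1, as.numeric(unlist(p)))
  expect_equal(as.numeric(g), fd, tolerance = 1e-4)
  # time-shift identity: d/dt0 = -d/dy when st0 = 0
  p2 <- dm_params(a = 1.2, v = 0.8, w = 0.45, t0 = 0.3, sv = 0.4, sw = 0.12, st0 = 0)
  g2 <- grad_logdensity(0.9, 1, p2)
  h <- 1e-6
  dy <- (wiener7_logdensity(0.9 + h, 1, p2, precision_spec(1e-12, refine = FALSE)) -
           wiener7_logdensity(0.9 - h, 1, p2, precision_spec(1e-12, refine = FALSE))) / (2 * h)
  expect_equal(unname(g2["t0"]), -dy, tolerance = 1e-4)
  # boundary components are flagged, not silently returned
  expect_true("st0" %in% attr(g2, "on_boundary"))
  expect_true(is.na(g2["st0"]))
})
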