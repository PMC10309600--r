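# Skew-t density, CDF, moments and the CP<->DP conversions.

test_that("density reduces to the known symmetric limits", {
  expect_equal(dskewt(0, 0, 1, 0, Inf), 1 / sqrt(2 * pi), tolerance = 1e-12)
  expect_equal(dskewt(0, 0, 1, 0, 1), 1 / pi, tolerance = 1e-12)  # Cauchy
  # alpha = 0 equals the Student-t density on a grid
  grid <- seq(-6, 6, by = 0.25)
  expect_equal(dskewt(grid, 0, 1, 0, 7), stats::dt(grid, 7),
               tolerance = 1e-10)
  # location/scale version
  expect_equal(dskewt(grid, 2, 3, 0, 7), stats::dt((grid - 2) / 3, 7) / 3,
               tolerance = 1e-10)
})

test_that("density integrates to one, also for randomized parameters", {
  expect_equal(
    stats::integrate(dskewt, -Inf, Inf, xi = 2, omega = 3, alpha = 4, nu = 8,
                     rel.tol = 1e-10)$value,
    1, tolerance = 1e-6)
  set.seed(401)
  for (i in 1:15) {
    xi <- stats::runif(1, -5, 5); omega <- stats::runif(1, 0.2, 4)
    alpha <- stats::runif(1, -8, 8); nu <- stats::runif(1, 0.5, 30)
    total <- stats::integrate(dskewt, -Inf, Inf, xi = xi, omega = omega,
                              alpha = alpha, nu = nu, rel.tol = 1e-10)$value
    expect_equal(total, 1, tolerance = 1e-6)
  }
})

test_that("CDF has the right limits, symmetry point and quadrature values", {
  expect_equal(pskewt(5, 5, 2, 0, 10), 0.5, tolerance = 1e-12)
  expect_equal(pskewt(Inf, 0, 1, 3, 6), 1)
  expect_equal(pskewt(-Inf, 0, 1, 3, 6), 0)
  oracle <- stats::integrate(dskewt, -Inf, 1, alpha = 3, nu = 6,
                             rel.tol = 1e-12)$value
  expect_equal(pskewt(1, 0, 1, 3, 6), oracle, tolerance = 1e-8)
  # monotone on an increasing grid
  p <- pskewt(seq(-8, 8, by = 0.5), 0, 1, -4, 5)
  expect_true(all(diff(p) >= 0))
})

test_that("quantile function inverts the CDF", {
  probs <- c(0.05, 0.25, 0.5, 0.9, 0.99)
  q <- qskewt(probs, 1, 2, 3, 6)
  expect_equal(pskewt(q, 1, 2, 3, 6), probs, tolerance = 1e-6)
})

test_that("dp2cp matches closed-form limits and the quadrature oracle", {
  expect_equal(unname(dp2cp(c(0, 1, 0, Inf))), c(0, 1, 0, 0),
               tolerance = 1e-12)
  # symmetric Student-t: excess kurtosis 6/(nu - 4)
  cp <- dp2cp(c(0, 1, 0, 10))
  expect_equal(cp[["gamma1"]], 0, tolerance = 1e-12)
  expect_equal(cp[["gamma2"]], 1, tolerance = 1e-12)
  # skewed case against independent numerical integration
  expect_equal(dp2cp(c(1, 2, 5, 8)), quadrature_cp(1, 2, 5, 8),
               tolerance = 1e-6)
  expect_equal(dp2cp(c(-3, 0.5, -2, 12)), quadrature_cp(-3, 0.5, -2, 12),
               tolerance = 1e-6)
})

test_that("dp2cp refuses undefined moments, naming the offending one", {
  expect_error(dp2cp(c(0, 1, 1, 4)), "kurtosis")
  expect_error(dp2cp(c(0, 1, 1, 2.5)), "skewness")
  expect_error(dskewt(0, 0, -1, 0, 5), "omega")
  expect_error(dskewt(0, 0, 1, 0, -2), "nu")
})

test_that("cp2dp handles the normal member and inverts dp2cp", {
  dp <- cp2dp(c(mean = 10, sd = 3, gamma1 = 0, gamma2 = 0))
  expect_equal(unname(dp), c(10, 3, 0, Inf))
  dp0 <- c(xi = 1, omega = 2, alpha = 5, nu = 8)
  expect_equal(cp2dp(dp2cp(dp0)), dp0, tolerance = 1e-5)
  # skewed summary: returned dp must reproduce the cp through independent
  # quadrature, not just through dp2cp
  cp <- c(mean = 18.1, sd = 12, gamma1 = 1.5, gamma2 = 4)
  dp <- cp2dp(cp)
  expect_equal(quadrature_cp(dp[["xi"]], dp[["omega"]], dp[["alpha"]],
                             dp[["nu"]]),
               cp, tolerance = 1e-6)
})

test_that("cp2dp and dp2cp are mutual inverses on randomized parameters", {
  set.seed(402)
  for (i in 1:100) {
    dp0 <- c(xi = stats::runif(1, -10, 10), omega = stats::runif(1, 0.1, 5),
             alpha = stats::runif(1, -10, 10), nu = stats::runif(1, 4.5, 50))
    dp1 <- cp2dp(dp2cp(dp0))
    expect_equal(dp1, dp0, tolerance = 1e-5)
  }
})

test_that("cp2dp rejects infeasible shape pairs and projects near-boundary ones", {
  # gamma2 below the attainable envelope at gamma1 = 1.5 (envelope ~ 3.76)
  expect_error(cp2dp(c(0, 1, 1.5, 1)), "infeasible")
  expect_error(cp2dp(c(0, 1, 0, -0.5)), "infeasible")
  expect_error(cp2dp(c(0, 0, 0, 0)), "sd")
  # epsilon outside the symmetric boundary: projected with a warning
  expect_warning(dp <- cp2dp(c(0, 1, 0, -1e-8)), "projected")
  expect_equal(unname(dp), c(0, 1, 0, Inf))
})

test_that("sample_moments follows the population-moment convention", {
  sm <- sample_moments(c(1, 2, 3, 4))
  expect_equal(sm[["mean"]], 2.5)
  expect_equal(sm[["sd"]], stats::sd(c(1, 2, 3, 4)))
  expect_equal(sm[["gamma1"]], 0)           # symmetric sample
  # direct arithmetic: m4/m2^2 - 3 with 1/n central moments
  d <- c(1, 2, 3, 4) - 2.5
  expect_equal(sm[["gamma2"]], mean(d^4) / mean(d^2)^2 - 3)
  expect_error(sample_moments(c(1, 2, 3)), "at least 4")
  expect_error(sample_moments(c(5, 5, 5, 5)), "degenerate")
})

test_that("bias-adjusted moment estimators apply the usual corrections", {
  x <- c(1, 2, 4, 8, 16)
  n <- length(x)
  raw <- sample_moments(x)
  adj <- sample_moments(x, adjusted = TRUE)
  expect_equal(adj[["gamma1"]],
               raw[["gamma1"]] * sqrt(n * (n - 1)) / (n - 2))
  expect_equal(adj[["gamma2"]],
               ((n + 1) * raw[["gamma2"]] + 6) * (n - 1) /
                 ((n - 2) * (n - 3)))
})

test_that("moment fit recovers parameters from a large sample", {
  set.seed(403)
  x <- rskewt(1e6, 1, 2, 4, 8)
  dp <- cp2dp(sample_moments(x))
  dp0 <- c(xi = 1, omega = 2, alpha = 4, nu = 8)
  expect_equal(dp[["xi"]], 1, tolerance = 0.05)
  expect_equal(dp[["omega"]], 2, tolerance = 0.05)
  expect_equal(dp[["alpha"]], 4, tolerance = 0.05 * 4)
  expect_equal(dp[["nu"]], 8, tolerance = 0.20 * 8)
})
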