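# Skew-t distribution: density, CDF, quantiles, random draws, closed-form
# moments, and the conversion between direct parameters (DP) and centred
# parameters (CP).
#
# Parameterisation (Azzalini & Capitanio): location xi, scale omega > 0,
# slant alpha, tail degrees of freedom nu > 0.  nu = Inf is the skew-normal
# member; additionally alpha = 0, nu = Inf is the normal.
# CP = (mean, sd, gamma1, gamma2) with gamma2 the EXCESS kurtosis
# (normal = 0).  Finite skewness needs nu > 3, finite kurtosis nu > 4.

.check_dp <- function(omega, nu) {
  if (!is.numeric(omega) || length(omega) != 1L || !is.finite(omega) || omega <= 0)
    stop("'omega' (scale) must be a single finite value > 0", call. = FALSE)
  if (!is.numeric(nu) || length(nu) != 1L || is.na(nu) || nu <= 0)
    stop("'nu' (tail df) must be > 0 (Inf allowed for the skew-normal limit)",
         call. = FALSE)
  invisible(TRUE)
}

#' Skew-t density
#'
#' Density of the four-parameter skew-t distribution with location \code{xi},
#' scale \code{omega}, slant \code{alpha} and tail degrees of freedom
#' \code{nu}:
#' \deqn{f(x) = \frac{2}{\omega}\, t_\nu(z)\,
#'       T_{\nu+1}\!\left(\alpha z \sqrt{\frac{\nu+1}{\nu+z^2}}\right),
#'       \quad z = (x-\xi)/\omega,}
#' where \eqn{t_\nu} and \eqn{T_\nu} are the Student-t density and CDF.
#' \code{nu = Inf} gives the skew-normal; \code{alpha = 0} the Student-t.
#'
#' @param x numeric vector of quantiles (ng in the yield application).
#' @param xi location parameter.
#' @param omega scale parameter, > 0.
#' @param alpha slant parameter; 0 means symmetric.
#' @param nu tail degrees of freedom, > 0; \code{Inf} for the skew-normal
#'   limit.
#' @param log logical; return log-density?
#' @return numeric vector of densities (1/ng).
#' @seealso [pskewt()], [qskewt()], [rskewt()], [dp2cp()], [cp2dp()]
#' @examples
#' dskewt(0, 0, 1, 0, Inf)       # standard normal density at 0
#' dskewt(2, 1, 2, 4, 8)
#' @export
dskewt <- function(x, xi = 0, omega = 1, alpha = 0, nu = Inf, log = FALSE) {
  .check_dp(omega, nu)
  z <- (x - xi) / omega
  if (is.infinite(nu)) {
    logf <- stats::dnorm(z, log = TRUE) +
      stats::pnorm(alpha * z, log.p = TRUE) + log(2) - log(omega)
  } else {
    w <- alpha * z * sqrt((nu + 1) / (nu + z^2))
    logf <- stats::dt(z, df = nu, log = TRUE) +
      stats::pt(w, df = nu + 1, log.p = TRUE) + log(2) - log(omega)
  }
  if (log) logf else exp(logf)
}

#' Skew-t cumulative distribution function
#'
#' Computed by adaptive quadrature of [dskewt()]; accurate to roughly 1e-10.
#'
#' @inheritParams dskewt
#' @param q numeric vector of quantiles.
#' @return numeric vector of probabilities.
#' @export
pskewt <- function(q, xi = 0, omega = 1, alpha = 0, nu = Inf) {
  .check_dp(omega, nu)
  if (alpha == 0) {
    z <- (q - xi) / omega
    return(if (is.infinite(nu)) stats::pnorm(z) else stats::pt(z, df = nu))
  }
  vapply(q, function(qi) {
    if (!is.finite(qi)) return(if (qi > 0) 1 else 0)
    # split at the location to keep the integrand well-scaled
    if (qi <= xi) {
      v <- stats::integrate(dskewt, -Inf, qi, xi = xi, omega = omega,
                            alpha = alpha, nu = nu,
                            rel.tol = 1e-11, abs.tol = 1e-12)$value
    } else {
      v <- 1 - stats::integrate(dskewt, qi, Inf, xi = xi, omega = omega,
                                alpha = alpha, nu = nu,
                                rel.tol = 1e-11, abs.tol = 1e-12)$value
    }
    min(max(v, 0), 1)
  }, numeric(1))
}

#' Skew-t quantile function
#'
#' Inverts [pskewt()] by bracketed root finding.
#'
#' @inheritParams dskewt
#' @param p numeric vector of probabilities in (0, 1).
#' @return numeric vector of quantiles.
#' @export
qskewt <- function(p, xi = 0, omega = 1, alpha = 0, nu = Inf) {
  .check_dp(omega, nu)
  vapply(p, function(pi) {
    if (is.na(pi) || pi < 0 || pi > 1) stop("'p' must be in [0, 1]", call. = FALSE)
    if (pi == 0) return(-Inf)
    if (pi == 1) return(Inf)
    lo <- xi - 10 * omega; hi <- xi + 10 * omega
    while (pskewt(lo, xi, omega, alpha, nu) > pi) lo <- xi - 2 * (xi - lo)
    while (pskewt(hi, xi, omega, alpha, nu) < pi) hi <- xi + 2 * (hi - xi)
    stats::uniroot(function(x) pskewt(x, xi, omega, alpha, nu) - pi,
                   c(lo, hi), tol = 1e-10)$root
  }, numeric(1))
}

#' Skew-t random draws
#'
#' Uses the stochastic representation: a skew-normal variate
#' \eqn{\delta |U_0| + \sqrt{1-\delta^2}\, U_1} divided by
#' \eqn{\sqrt{W/\nu}} with \eqn{W \sim \chi^2_\nu}, then rescaled.
#'
#' @inheritParams dskewt
#' @param n number of draws.
#' @return numeric vector of length \code{n}.
#' @export
rskewt <- function(n, xi = 0, omega = 1, alpha = 0, nu = Inf) {
  .check_dp(omega, nu)
  delta <- alpha / sqrt(1 + alpha^2)
  u0 <- stats::rnorm(n)
  u1 <- stats::rnorm(n)
  z <- delta * abs(u0) + sqrt(1 - delta^2) * u1
  if (is.finite(nu)) z <- z / sqrt(stats::rchisq(n, df = nu) / nu)
  xi + omega * z
}

# Central moments of the standardised skew-t(0, 1, alpha, nu) in terms of
# delta = alpha/sqrt(1+alpha^2).  Returns mu_z, var_z and, where defined,
# gamma1 / gamma2 (NA when nu too small).
.st_std_moments <- function(delta, nu) {
  if (is.infinite(nu)) {
    b <- sqrt(2 / pi)
    mu <- b * delta
    v <- 1 - mu^2
    g1 <- (4 - pi) / 2 * mu^3 / v^1.5
    g2 <- 2 * (pi - 3) * mu^4 / v^2
    return(c(mu_z = mu, var_z = v, gamma1 = g1, gamma2 = g2))
  }
  b <- sqrt(nu / pi) * exp(lgamma((nu - 1) / 2) - lgamma(nu / 2))
  mu <- if (nu > 1) b * delta else NA_real_
  m2 <- if (nu > 2) nu / (nu - 2) else NA_real_
  v <- m2 - mu^2
  g1 <- if (nu > 3)
    mu * (nu * (3 - delta^2) / (nu - 3) - 3 * m2 + 2 * mu^2) / v^1.5
  else NA_real_
  g2 <- if (nu > 4)
    (3 * nu^2 / ((nu - 2) * (nu - 4)) -
       4 * mu^2 * nu * (3 - delta^2) / (nu - 3) +
       6 * mu^2 * m2 - 3 * mu^4) / v^2 - 3
  else NA_real_
  c(mu_z = mu, var_z = v, gamma1 = g1, gamma2 = g2)
}

#' Direct to centred skew-t parameters
#'
#' Converts direct parameters (xi, omega, alpha, nu) to the centred
#' parameterisation (mean, sd, skewness, excess kurtosis) using the
#' closed-form skew-t moments.  Requires \code{nu > 4} so that all four
#' moments exist (\code{nu = Inf} allowed).
#'
#' @param dp numeric vector (or list) with elements \code{xi}, \code{omega},
#'   \code{alpha}, \code{nu} (in that order if unnamed).
#' @return named numeric vector \code{c(mean, sd, gamma1, gamma2)};
#'   \code{gamma2} is excess kurtosis (normal = 0).
#' @examples
#' dp2cp(c(xi = 0, omega = 1, alpha = 0, nu = 10))  # gamma2 = 6/(nu-4) = 1
#' @export
dp2cp <- function(dp) {
  dp <- .as_dp(dp)
  if (dp[["nu"]] <= 4)
    stop(if (dp[["nu"]] <= 3) "skewness undefined: nu <= 3"
         else "kurtosis undefined: nu <= 4", call. = FALSE)
  delta <- dp[["alpha"]] / sqrt(1 + dp[["alpha"]]^2)
  m <- .st_std_moments(delta, dp[["nu"]])
  c(mean = dp[["xi"]] + dp[["omega"]] * m[["mu_z"]],
    sd = dp[["omega"]] * sqrt(m[["var_z"]]),
    gamma1 = m[["gamma1"]],
    gamma2 = m[["gamma2"]])
}

.as_dp <- function(dp) {
  dp <- unlist(dp)
  if (length(dp) != 4L) stop("'dp' must have 4 elements (xi, omega, alpha, nu)",
                             call. = FALSE)
  if (is.null(names(dp)) || !all(c("xi", "omega", "alpha", "nu") %in% names(dp)))
    names(dp) <- c("xi", "omega", "alpha", "nu")
  .check_dp(dp[["omega"]], dp[["nu"]])
  dp[c("xi", "omega", "alpha", "nu")]
}

.as_cp <- function(cp) {
  cp <- unlist(cp)
  if (length(cp) != 4L)
    stop("'cp' must have 4 elements (mean, sd, gamma1, gamma2)", call. = FALSE)
  if (is.null(names(cp)) || !all(c("mean", "sd", "gamma1", "gamma2") %in% names(cp)))
    names(cp) <- c("mean", "sd", "gamma1", "gamma2")
  cp[c("mean", "sd", "gamma1", "gamma2")]
}

# gamma1 as a function of delta at fixed nu (odd and increasing in delta)
.g1_of_delta <- function(delta, nu) .st_std_moments(delta, nu)[["gamma1"]]

.delta_max <- 1 - 1e-9
# largest |gamma1| attainable by a skew-normal (delta -> 1)
.g1_max_sn <- local({
  m <- .st_std_moments(.delta_max, Inf)
  m[["gamma1"]]
})

# solve delta >= 0 with gamma1(delta, nu) = g1 (g1 >= 0); NA if unattainable
.solve_delta <- function(g1, nu) {
  if (g1 <= 0) return(0)
  gmax <- .g1_of_delta(.delta_max, nu)
  if (g1 > gmax) return(NA_real_)
  stats::uniroot(function(d) .g1_of_delta(d, nu) - g1,
                 c(0, .delta_max), tol = 1e-13)$root
}

#' Centred to direct skew-t parameters
#'
#' Inverts [dp2cp()]: given a moment summary (mean, sd, skewness gamma1,
#' excess kurtosis gamma2) finds the direct parameters (xi, omega, alpha,
#' nu) whose analytic moments match.  The pair (gamma1, gamma2) must lie in
#' the attainable region of the skew-t family, whose lower boundary is the
#' skew-normal curve (nu = Inf) and which requires nu > 4.  Inputs within
#' \code{boundary.tol} of the boundary are projected onto it with a warning
#' (moment estimates from data frequently land epsilon-outside).
#'
#' The solver is deterministic nested 1-D root finding: for candidate nu,
#' delta (hence alpha) is solved from gamma1, then nu is solved so the
#' implied gamma2 matches; finally omega from the sd and xi from the mean.
#' At alpha = 0 this reduces to the Student-t curve gamma2 = 6/(nu - 4).
#'
#' @param cp numeric vector (or list) with elements \code{mean}, \code{sd},
#'   \code{gamma1}, \code{gamma2} (excess kurtosis).
#' @param boundary.tol tolerance within which an infeasible (gamma1, gamma2)
#'   is projected onto the attainable boundary instead of rejected.
#' @param project logical; if \code{TRUE}, any infeasible (gamma1, gamma2)
#'   is projected onto the attainable boundary (with a warning) instead of
#'   raising an error — the usual method-of-moments practice when sample
#'   moments from small heavy-tailed samples fall outside the parameter
#'   space.
#' @return named numeric vector \code{c(xi, omega, alpha, nu)}; \code{nu}
#'   is \code{Inf} for the skew-normal/normal members.
#' @examples
#' cp2dp(c(mean = 10, sd = 3, gamma1 = 0, gamma2 = 0))   # normal member
#' dp2cp(cp2dp(c(mean = 5, sd = 2, gamma1 = 1.5, gamma2 = 4)))
#' @export
cp2dp <- function(cp, boundary.tol = 1e-6, project = FALSE) {
  if (isTRUE(project)) boundary.tol <- Inf
  cp <- .as_cp(cp)
  sd <- cp[["sd"]]
  if (!is.finite(sd) || sd <= 0) stop("'sd' must be > 0", call. = FALSE)
  g1 <- cp[["gamma1"]]; g2 <- cp[["gamma2"]]
  s <- if (g1 < 0) -1 else 1
  a1 <- abs(g1)
  eps <- 1e-12

  if (a1 < 1e-10) {
    # symmetric: Student-t curve gamma2 = 6/(nu - 4), or normal
    if (abs(g2) < 1e-10) {
      alpha <- 0; nu <- Inf
    } else if (g2 > 0) {
      alpha <- 0; nu <- 4 + 6 / g2
    } else if (g2 > -boundary.tol) {
      warning("gamma2 slightly below the normal boundary; projected to 0")
      alpha <- 0; nu <- Inf
    } else {
      stop("infeasible (gamma1, gamma2): with gamma1 = 0 the smallest ",
           "attainable excess kurtosis is 0 (normal)", call. = FALSE)
    }
  } else {
    # lower envelope: smallest gamma2 attainable at this gamma1
    if (a1 < .g1_max_sn) {
      nu_hi <- Inf
    } else {
      # gamma1 this large needs heavy tails: find largest nu that attains it
      f <- function(nu) .g1_of_delta(.delta_max, nu) - a1
      if (f(4 + 1e-8) < 0) {
        if (!is.infinite(boundary.tol))
          stop("infeasible (gamma1, gamma2): |gamma1| = ", signif(a1, 6),
               " exceeds the skew-t maximum at nu > 4", call. = FALSE)
        warning("|gamma1| beyond the skew-t maximum; clipped to the boundary")
        a1 <- .g1_of_delta(.delta_max, 4 + 1e-6) * (1 - 1e-9)
      }
      nu_hi <- stats::uniroot(f, c(4 + 1e-8, 1e8), tol = 1e-10)$root * (1 - 1e-9)
    }
    g2_env <- {
      d <- .solve_delta(a1, nu_hi)
      if (is.na(d)) d <- .delta_max   # numerically at the slant boundary
      .st_std_moments(d, nu_hi)[["gamma2"]]
    }
    if (g2 <= g2_env) {
      if (g2 > g2_env - boundary.tol) {
        warning("(gamma1, gamma2) epsilon-outside the attainable region; ",
                "projected onto the boundary (gamma2 = ", signif(g2_env, 8), ")")
        g2 <- g2_env + eps
        nu <- nu_hi
        delta <- .solve_delta(a1, nu)
      } else {
        stop("infeasible (gamma1, gamma2): at gamma1 = ", signif(s * a1, 6),
             " the smallest attainable excess kurtosis is ",
             signif(g2_env, 6), call. = FALSE)
      }
    } else {
      # solve gamma2 residual in nu on (4, nu_hi]
      resid <- function(nu) {
        d <- .solve_delta(a1, nu)
        if (is.na(d)) d <- .delta_max  # at the slant boundary for this nu
        .st_std_moments(d, nu)[["gamma2"]] - g2
      }
      lo <- 4 + 1e-8
      hi <- if (is.finite(nu_hi)) nu_hi else 1e7
      r_hi <- resid(hi)
      if (r_hi > 0) {           # even at the envelope gamma2 too big: nu ~ hi
        nu <- hi
      } else {
        nu <- stats::uniroot(resid, c(lo, hi), tol = 1e-12,
                             f.upper = r_hi)$root
      }
      if (is.infinite(nu_hi) && nu > 0.5e7) nu <- Inf  # numerically normal tail
      delta <- .solve_delta(a1, nu)
      if (is.na(delta)) delta <- .delta_max
    }
    alpha <- s * delta / sqrt(1 - delta^2)
  }

  m <- .st_std_moments(abs(alpha) / sqrt(1 + alpha^2), nu)
  omega <- sd / sqrt(m[["var_z"]])
  xi <- cp[["mean"]] - omega * s * m[["mu_z"]]
  c(xi = xi, omega = omega, alpha = alpha, nu = nu)
}

#' Sample moment summary
#'
#' Mean, sd, skewness and excess kurtosis of a sample, in the centred-
#' parameter convention consumed by [cp2dp()].  The sd uses the n-1
#' denominator.  By default skewness/kurtosis are the population-moment
#' estimators \eqn{g_1 = m_3/m_2^{3/2}} and \eqn{g_2 = m_4/m_2^2 - 3}
#' (central moments \eqn{m_k} with 1/n denominators); \code{adjusted = TRUE}
#' applies the usual small-sample bias corrections (G1, G2).
#'
#' @param x numeric vector, length >= 4.
#' @param adjusted logical; use bias-adjusted skewness/kurtosis estimators?
#' @return named numeric vector \code{c(mean, sd, gamma1, gamma2)}.
#' @export
sample_moments <- function(x, adjusted = FALSE) {
  x <- as.numeric(x)
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 4) stop("need at least 4 observations to estimate four moments",
                  call. = FALSE)
  m <- mean(x)
  d <- x - m
  m2 <- mean(d^2)
  if (m2 == 0) stop("degenerate sample: zero variance", call. = FALSE)
  g1 <- mean(d^3) / m2^1.5
  g2 <- mean(d^4) / m2^2 - 3
  if (adjusted) {
    g1 <- g1 * sqrt(n * (n - 1)) / (n - 2)
    g2 <- ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
  }
  c(mean = m, sd = stats::sd(x), gamma1 = g1, gamma2 = g2)
}
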