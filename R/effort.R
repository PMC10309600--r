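# Minimal-filter-sheet estimation: per-sheet rate from a training set of
# sessions, Monte-Carlo simulation of total yields for each candidate sheet
# count, a one-tailed lower confidence bound per count, an OLS line through
# the bounds, and the smallest integer sheet count at or above the line's
# crossing with the target yield.

#' Configuration for the minimal-sheet estimator
#'
#' Defaults mirror the study design: a 10 ng target, one-tailed 90%
#' confidence, 100 simulated totals per sheet count, a t-quantile with
#' n_train - 1 degrees of freedom (40 for a 41-session training set), and a
#' sheet grid of 1..200.
#'
#' @param target_yield_ng target DNA yield in ng (> 0).
#' @param confidence one-tailed confidence level in (0.5, 1).
#' @param n_sim simulated totals per sheet count (>= 2).
#' @param ci_df degrees of freedom for the t-quantile of the bound;
#'   \code{NULL} means n_train - 1, resolved when the training data are seen.
#' @param sheet_grid integer grid of candidate sheet counts.
#' @param sim_family \code{"scaled_poisson"} (counts at 1/poisson_scale ng
#'   resolution), \code{"gamma"} (matches mean and empirical dispersion) or
#'   \code{"bootstrap"} (sums resampled per-sheet yields).
#' @param poisson_scale counts per ng for the scaled-Poisson family (> 0).
#' @param bound_mode \code{"mean_sd"} (mean - t * sd, per-observation style),
#'   \code{"mean_se"} (mean - t * sd / sqrt(n)) or
#'   \code{"empirical_quantile"} (the (1 - confidence) sample quantile).
#' @param rng_seed integer seed; per-sheet-count streams are derived from it
#'   so results do not depend on grid order.
#' @return a validated list of class \code{"effort_config"}.
#' @export
effort_config <- function(target_yield_ng = 10, confidence = 0.90,
                          n_sim = 100, ci_df = NULL, sheet_grid = 1:200,
                          sim_family = c("scaled_poisson", "gamma",
                                         "bootstrap"),
                          poisson_scale = 100,
                          bound_mode = c("mean_sd", "mean_se",
                                         "empirical_quantile"),
                          rng_seed = NULL) {
  sim_family <- match.arg(sim_family)
  bound_mode <- match.arg(bound_mode)
  if (!is.numeric(target_yield_ng) || target_yield_ng <= 0)
    stop("target_yield_ng must be > 0", call. = FALSE)
  if (!is.numeric(confidence) || confidence <= 0.5 || confidence >= 1)
    stop("confidence must be in (0.5, 1)", call. = FALSE)
  if (!is.numeric(n_sim) || n_sim < 2) stop("n_sim must be >= 2", call. = FALSE)
  if (!is.numeric(poisson_scale) || poisson_scale <= 0)
    stop("poisson_scale must be > 0", call. = FALSE)
  sheet_grid <- sort(unique(as.integer(sheet_grid)))
  if (any(sheet_grid < 1)) stop("sheet_grid must be >= 1", call. = FALSE)
  structure(list(target_yield_ng = target_yield_ng, confidence = confidence,
                 n_sim = as.integer(n_sim), ci_df = ci_df,
                 sheet_grid = sheet_grid, sim_family = sim_family,
                 poisson_scale = poisson_scale, bound_mode = bound_mode,
                 rng_seed = rng_seed),
            class = "effort_config")
}

#' Per-sheet yield rate from training sessions
#'
#' @param x yield dataset (or numeric vector already on the per-sheet
#'   scale).  For a dataset, per-sheet yield is
#'   \code{total_yield_ng / n_sheets}.
#' @return list with \code{lambda_hat} (mean ng/sheet), \code{dispersion}
#'   (sd of per-sheet yields, retained for the gamma/bootstrap families),
#'   \code{n} and \code{per_sheet} (the per-sheet yields).
#' @export
fit_per_sheet <- function(x) {
  ps <- if (is.data.frame(x)) {
    x <- yield_dataset(x)
    x$total_yield_ng / x$n_sheets
  } else as.numeric(x)
  ps <- ps[!is.na(ps)]
  if (length(ps) == 0) stop("empty input: no training sessions", call. = FALSE)
  list(lambda_hat = mean(ps),
       dispersion = if (length(ps) > 1) stats::sd(ps) else 0,
       n = length(ps), per_sheet = ps)
}

#' Simulate total yields for a given sheet count
#'
#' Draws \code{cfg$n_sim} total-yield values for \code{k_sheets} sheets.
#' When the training dispersion is exactly zero every family returns the
#' deterministic total \code{k_sheets * lambda_hat} (the simulator is
#' dispersion-faithful).  Families:
#' \describe{
#'   \item{scaled_poisson}{\code{rpois(n, scale * k * lambda) / scale} —
#'     continuous ng discretised at 1/scale resolution.}
#'   \item{gamma}{gamma with mean \code{k * lambda} and variance
#'     \code{k * dispersion^2} (sum of k per-sheet draws).}
#'   \item{bootstrap}{sum of k per-sheet yields resampled with replacement.}
#' }
#'
#' @param k_sheets integer >= 1.
#' @param lambda_hat per-sheet rate (ng/sheet), >= 0.
#' @param cfg an [effort_config()].
#' @param dispersion per-sheet sd from [fit_per_sheet()].
#' @param per_sheet per-sheet training yields (needed for bootstrap).
#' @return numeric vector of length \code{cfg$n_sim}.
#' @export
simulate_totals <- function(k_sheets, lambda_hat, cfg = effort_config(),
                            dispersion = 0, per_sheet = NULL) {
  if (k_sheets < 1) stop("k_sheets must be >= 1", call. = FALSE)
  if (!is.finite(lambda_hat) || lambda_hat < 0)
    stop("lambda_hat must be >= 0", call. = FALSE)
  n <- cfg$n_sim
  if (lambda_hat == 0) return(rep(0, n))
  if (dispersion == 0 && cfg$sim_family != "scaled_poisson")
    return(rep(k_sheets * lambda_hat, n))
  if (dispersion == 0) return(rep(k_sheets * lambda_hat, n))
  switch(cfg$sim_family,
    scaled_poisson = stats::rpois(n, cfg$poisson_scale * k_sheets *
                                    lambda_hat) / cfg$poisson_scale,
    gamma = {
      shape <- k_sheets * lambda_hat^2 / dispersion^2
      stats::rgamma(n, shape = shape, rate = lambda_hat / dispersion^2)
    },
    bootstrap = {
      if (is.null(per_sheet)) stop("bootstrap family needs 'per_sheet'",
                                   call. = FALSE)
      colSums(matrix(sample(per_sheet, n * k_sheets, replace = TRUE),
                     nrow = k_sheets))
    })
}

#' One-tailed lower confidence bound of simulated yields
#'
#' @param values numeric vector of simulated totals.
#' @param confidence one-tailed level in (0.5, 1).
#' @param ci_df degrees of freedom for the t-quantile.
#' @param bound_mode see [effort_config()].  \code{mean_sd}:
#'   mean - t * sd; \code{mean_se}: mean - t * sd / sqrt(n);
#'   \code{empirical_quantile}: the (1 - confidence) sample quantile
#'   (type 7).
#' @return the lower bound (ng).
#' @export
ci_lower_bound <- function(values, confidence = 0.90, ci_df = 40,
                           bound_mode = c("mean_sd", "mean_se",
                                          "empirical_quantile")) {
  bound_mode <- match.arg(bound_mode)
  if (!is.numeric(confidence) || confidence <= 0 || confidence >= 1)
    stop("confidence must be in (0, 1)", call. = FALSE)
  n <- length(values)
  if (bound_mode == "empirical_quantile") {
    if (n < 10) stop("empirical_quantile needs >= 10 values", call. = FALSE)
    return(unname(stats::quantile(values, probs = 1 - confidence, type = 7)))
  }
  if (n < 2) stop("need >= 2 values", call. = FALSE)
  m <- mean(values); s <- stats::sd(values)
  tq <- stats::qt(confidence, df = ci_df)
  if (bound_mode == "mean_se") m - tq * s / sqrt(n) else m - tq * s
}

#' Estimate the minimal number of filter sheets for a target yield
#'
#' For each sheet count k on the grid, simulates \code{n_sim} total yields
#' from the per-sheet rate, takes the one-tailed lower confidence bound,
#' regresses the bounds on k by OLS, and returns the smallest integer sheet
#' count at or above the crossing of the regression line with the target
#' yield (fractional sheets being physically meaningless).
#'
#' @param x training yield dataset or numeric per-sheet yields.
#' @param cfg an [effort_config()].  If \code{cfg$ci_df} is \code{NULL} it
#'   resolves to n_train - 1.
#' @return object of class \code{"effort_estimate"}: list with
#'   \code{min_sheets}, \code{crossing} (exact intersection abscissa),
#'   \code{slope}, \code{intercept}, \code{r_squared}, \code{lower_bounds}
#'   (data frame k, lower_bound), \code{lambda_hat}, \code{dispersion},
#'   \code{n_train}, \code{config}.
#' @examples
#' # deterministic 0.5 ng/sheet: exactly ceil(10 / 0.5) = 20 sheets
#' est <- estimate_min_sheets(rep(0.5, 10))
#' est$min_sheets
#' @export
estimate_min_sheets <- function(x, cfg = effort_config()) {
  stopifnot(inherits(cfg, "effort_config"))
  fit <- fit_per_sheet(x)
  if (fit$lambda_hat <= 0)
    stop("non-informative training data: per-sheet rate is 0", call. = FALSE)
  ci_df <- if (is.null(cfg$ci_df)) max(fit$n - 1, 1) else cfg$ci_df
  grid <- cfg$sheet_grid
  seed0 <- if (is.null(cfg$rng_seed)) NULL else as.integer(cfg$rng_seed)
  lb <- vapply(grid, function(k) {
    # per-k stream: fixed offset from the base seed, so results are
    # independent of grid order and subsets
    if (!is.null(seed0)) set.seed(seed0 + k)
    v <- simulate_totals(k, fit$lambda_hat, cfg, fit$dispersion,
                         fit$per_sheet)
    ci_lower_bound(v, cfg$confidence, ci_df, cfg$bound_mode)
  }, numeric(1))
  ols <- stats::lm(lb ~ grid)
  intercept <- unname(stats::coef(ols)[1])
  slope <- unname(stats::coef(ols)[2])
  if (!is.finite(slope) || slope <= 0)
    stop("non-informative regression: slope of lower bounds on sheet count ",
         "is not positive", call. = FALSE)
  crossing <- (cfg$target_yield_ng - intercept) / slope
  min_sheets <- max(1L, as.integer(ceiling(crossing - 1e-9)))
  if (crossing > max(grid))
    stop("target unreachable within sheet_grid: extrapolated crossing at k = ",
         ceiling(crossing), call. = FALSE)
  tss <- sum((lb - mean(lb))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(ols)^2) / tss else 1
  structure(list(min_sheets = min_sheets, crossing = crossing,
                 slope = slope, intercept = intercept, r_squared = r2,
                 lower_bounds = data.frame(k = grid, lower_bound = lb),
                 lambda_hat = fit$lambda_hat, dispersion = fit$dispersion,
                 n_train = fit$n, ci_df = ci_df, config = cfg),
            class = "effort_estimate")
}

#' @export
print.effort_estimate <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Minimal filter sheets for >= %g ng: %d\n",
              cfg$target_yield_ng, x$min_sheets))
  cat(sprintf("  regression of %s %.0f%% lower bounds on sheet count:\n",
              cfg$bound_mode, 100 * cfg$confidence))
  cat(sprintf("  bound = %.4g + %.4g * k  (R^2 = %.4f), crossing at k = %.2f\n",
              x$intercept, x$slope, x$r_squared, x$crossing))
  cat(sprintf("  per-sheet rate %.4g ng/sheet (sd %.4g, n = %d training sessions, df = %g)\n",
              x$lambda_hat, x$dispersion, x$n_train, x$ci_df))
  invisible(x)
}

#' @export
plot.effort_estimate <- function(x, ...) {
  with(x$lower_bounds,
       graphics::plot(k, lower_bound, pch = 16, cex = 0.5, col = "grey40",
                      xlab = "number of filter sheets",
                      ylab = sprintf("%.0f%% one-tailed lower yield bound (ng)",
                                     100 * x$config$confidence)))
  graphics::abline(a = x$intercept, b = x$slope, col = "steelblue", lwd = 2)
  graphics::abline(h = x$config$target_yield_ng, col = "firebrick", lty = 2)
  graphics::abline(v = x$min_sheets, col = "firebrick", lty = 3)
  invisible(x)
}
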