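# Yield-performance analysis: the moment-matched skew-t yield model,
# exceedance probabilities at a target yield, Gaussian-kernel densities and
# the two-sampler t-test.

#' Validate / construct a yield dataset
#'
#' A yield dataset is a data frame with one row per sampling session and
#' columns \code{sampler_label}, \code{session_id}, \code{duration_h},
#' \code{n_sheets}, \code{total_yield_ng} and optionally \code{location}
#' (\code{"indoor"}/\code{"outdoor"}) and \code{hour_index}
#' (\code{"H1"}/\code{"H2"}/\code{"H3"}).  Per-sheet yield is always derived
#' as \code{total_yield_ng / n_sheets}, never stored.
#'
#' @param df data frame to validate.
#' @return the validated data frame (invisibly classed
#'   \code{"yield_dataset"}).
#' @export
yield_dataset <- function(df) {
  req <- c("sampler_label", "duration_h", "n_sheets", "total_yield_ng")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0) stop("empty yield dataset", call. = FALSE)
  if (!"session_id" %in% names(df)) df$session_id <- seq_len(nrow(df))
  bad <- which(!is.finite(df$total_yield_ng) | df$total_yield_ng < 0)
  if (length(bad))
    stop("negative or non-finite total_yield_ng in row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(df$n_sheets) | df$n_sheets < 1)
  if (length(bad))
    stop("n_sheets must be >= 1; offending row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(df$duration_h) | df$duration_h <= 0)
  if (length(bad))
    stop("duration_h must be > 0; offending row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  if ("location" %in% names(df) &&
      !all(df$location %in% c("indoor", "outdoor")))
    stop("location must be 'indoor' or 'outdoor'", call. = FALSE)
  class(df) <- unique(c("yield_dataset", class(df)))
  df
}

.yields_of <- function(x) {
  if (is.data.frame(x)) {
    x <- yield_dataset(x)
    as.numeric(x$total_yield_ng)
  } else as.numeric(x)
}

#' Fit a skew-t yield model by moment matching
#'
#' Fits the four-parameter skew-t distribution to session DNA yields by
#' matching the first four sample moments: [sample_moments()] gives the
#' centred parameters, [cp2dp()] converts them to direct parameters.  This
#' is a method-of-moments fit, not maximum likelihood.
#'
#' @param x numeric vector of yields (ng), or a yield dataset
#'   (see [yield_dataset()]) whose \code{total_yield_ng} column is used.
#' @param adjusted logical, passed to [sample_moments()].
#' @param project logical, passed to [cp2dp()]: project infeasible sample
#'   shape moments onto the skew-t attainable boundary instead of erroring.
#' @return an object of class \code{"st_fit"} with components \code{dp}
#'   (direct parameters), \code{cp} (moment summary), \code{n}, \code{data}
#'   and \code{call}.  Methods: \code{print}, \code{summary}, \code{coef},
#'   \code{predict} (density / cdf / exceedance), \code{simulate},
#'   \code{plot}.
#' @examples
#' set.seed(1)
#' y <- rskewt(200, 10, 8, 4, 8)
#' fit <- st_moment_fit(y)
#' fit
#' predict(fit, newdata = 10, type = "exceedance")
#' @export
st_moment_fit <- function(x, adjusted = FALSE, project = FALSE) {
  y <- .yields_of(x)
  y <- y[!is.na(y)]
  if (length(y) < 4)
    stop("need at least 4 observations for a four-moment fit", call. = FALSE)
  cp <- sample_moments(y, adjusted = adjusted)
  dp <- cp2dp(cp, project = project)
  structure(list(dp = dp, cp = cp, n = length(y), data = y,
                 adjusted = adjusted, call = match.call()),
            class = "st_fit")
}

#' @export
print.st_fit <- function(x, digits = 4, ...) {
  cat("Moment-matched skew-t yield model (n =", x$n, "sessions)\n")
  cat("Direct parameters:\n")
  print(round(x$dp, digits))
  cat("Sample moments (mean, sd in ng; gamma2 = excess kurtosis):\n")
  print(round(x$cp, digits))
  invisible(x)
}

#' @export
coef.st_fit <- function(object, ...) object$dp

#' @export
summary.st_fit <- function(object, threshold_ng = 10, ...) {
  out <- list(fit = object, threshold_ng = threshold_ng,
              exceedance_parametric =
                unname(1 - pskewt(threshold_ng, object$dp[["xi"]],
                                  object$dp[["omega"]], object$dp[["alpha"]],
                                  object$dp[["nu"]])),
              exceedance_empirical = mean(object$data >= threshold_ng))
  class(out) <- "summary.st_fit"
  out
}

#' @export
print.summary.st_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat(sprintf("P(yield >= %g ng): parametric %.3f | empirical %.3f\n",
              x$threshold_ng, x$exceedance_parametric, x$exceedance_empirical))
  invisible(x)
}

#' @export
predict.st_fit <- function(object, newdata,
                           type = c("density", "cdf", "exceedance"), ...) {
  type <- match.arg(type)
  if (missing(newdata))
    newdata <- seq(min(object$data), max(object$data), length.out = 101)
  dp <- object$dp
  switch(type,
         density = dskewt(newdata, dp[["xi"]], dp[["omega"]], dp[["alpha"]],
                          dp[["nu"]]),
         cdf = pskewt(newdata, dp[["xi"]], dp[["omega"]], dp[["alpha"]],
                      dp[["nu"]]),
         exceedance = 1 - pskewt(newdata, dp[["xi"]], dp[["omega"]],
                                 dp[["alpha"]], dp[["nu"]]))
}

#' @export
simulate.st_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  dp <- object$dp
  rskewt(nsim, dp[["xi"]], dp[["omega"]], dp[["alpha"]], dp[["nu"]])
}

#' @export
plot.st_fit <- function(x, threshold_ng = 10, ...) {
  grid <- seq(min(0, min(x$data)), max(x$data) * 1.2, length.out = 200)
  graphics::hist(x$data, freq = FALSE, breaks = "FD",
                 main = "Session DNA yield with skew-t fit",
                 xlab = "total yield (ng)", border = "grey")
  graphics::lines(grid, predict(x, grid, type = "density"), col = "steelblue",
                  lwd = 2)
  graphics::abline(v = threshold_ng, col = "firebrick", lty = 2)
  invisible(x)
}

#' Probability of reaching a target DNA yield
#'
#' The yield-performance estimate: P(total yield >= threshold).  Three
#' methods are available; the threshold comparison is always inclusive.
#' \describe{
#'   \item{parametric_skew_t}{\code{1 - pskewt(threshold, cp2dp(sample
#'     moments))} — the moment-matched skew-t tail mass (default).}
#'   \item{empirical_ecdf}{fraction of sessions with yield >= threshold.}
#'   \item{kernel_density_auc}{tail mass of the Gaussian-kernel density
#'     estimate (computed exactly as a mean of normal tail probabilities).}
#' }
#'
#' @param x numeric yields (ng) or a yield dataset.
#' @param threshold_ng target yield in ng (default 10, the metabarcoding
#'   sufficiency threshold).
#' @param method one of \code{"parametric_skew_t"}, \code{"empirical_ecdf"},
#'   \code{"kernel_density_auc"}.
#' @param project logical (parametric method only): project infeasible
#'   sample shape moments onto the skew-t boundary instead of erroring.
#' @return an object of class \code{"exceedance_result"}: a list with
#'   \code{threshold_ng}, \code{probability}, \code{method}, \code{n_used}.
#' @examples
#' exceedance(c(2, 8, 12, 20, 31, 5), threshold_ng = 10,
#'            method = "empirical_ecdf")
#' @export
exceedance <- function(x, threshold_ng = 10,
                       method = c("parametric_skew_t", "empirical_ecdf",
                                  "kernel_density_auc"),
                       project = FALSE) {
  method <- match.arg(method)
  y <- .yields_of(x)
  y <- y[!is.na(y)]
  if (length(y) == 0) stop("empty input: no yields", call. = FALSE)
  p <- switch(method,
    empirical_ecdf = mean(y >= threshold_ng),
    parametric_skew_t = {
      if (length(y) < 4)
        stop("parametric method needs >= 4 observations", call. = FALSE)
      dp <- cp2dp(sample_moments(y), project = project)
      unname(1 - pskewt(threshold_ng, dp[["xi"]], dp[["omega"]],
                        dp[["alpha"]], dp[["nu"]]))
    },
    kernel_density_auc = {
      if (length(y) < 2)
        stop("kernel method needs >= 2 observations", call. = FALSE)
      h <- .kde_bw(y)
      mean(stats::pnorm(threshold_ng, mean = y, sd = h, lower.tail = FALSE))
    })
  structure(list(threshold_ng = threshold_ng, probability = p,
                 method = method, n_used = length(y)),
            class = "exceedance_result")
}

#' @export
print.exceedance_result <- function(x, ...) {
  cat(sprintf("P(yield >= %g ng) = %.4f  [%s, n = %d]\n",
              x$threshold_ng, x$probability, x$method, x$n_used))
  invisible(x)
}

# Silverman rule-of-thumb bandwidth (R's bw.nrd0), floored for degenerate
# spreads
.kde_bw <- function(x) {
  bw <- tryCatch(stats::bw.nrd0(x), error = function(e) 0)
  max(bw, 1e-6 * max(1, abs(mean(x))))
}

#' Gaussian kernel density on a grid
#'
#' Direct-sum Gaussian KDE with Silverman's rule-of-thumb bandwidth
#' (\code{stats::bw.nrd0}, floored at \code{1e-6 * max(1, |mean|)} for
#' degenerate spreads), evaluated at arbitrary grid points.
#'
#' @param values numeric sample (ng), length >= 2.
#' @param grid numeric evaluation points.
#' @param bw optional bandwidth override.
#' @return data frame with columns \code{x_ng} and \code{density}.
#' @export
kde_density <- function(values, grid, bw = NULL) {
  values <- as.numeric(values)
  values <- values[!is.na(values)]
  if (length(values) < 2)
    stop("need at least 2 values for a kernel density", call. = FALSE)
  h <- if (is.null(bw)) .kde_bw(values) else bw
  dens <- vapply(grid, function(g) mean(stats::dnorm(g, mean = values, sd = h)),
                 numeric(1))
  data.frame(x_ng = grid, density = dens)
}

#' Two-sample t-test between sampler yield groups
#'
#' Two-sided two-sample t-test, pooled-variance ("Student's") by default
#' with the Welch unequal-variance variant available.  Delegates to
#' \code{stats::t.test} and additionally reports the group summaries.
#'
#' @param group_a,group_b numeric yield vectors (ng), each length >= 2.
#' @param variant \code{"pooled"} (classical Student) or \code{"welch"}.
#' @return an object of class \code{"yield_ttest"}: list with
#'   \code{t_statistic}, \code{df}, \code{p_value}, \code{mean_a},
#'   \code{mean_b}, \code{sd_a}, \code{sd_b}, \code{n_a}, \code{n_b},
#'   \code{variant}.
#' @examples
#' compare_yields(c(1, 2, 3), c(4, 5, 6))  # t = -3.674, df = 4
#' @export
compare_yields <- function(group_a, group_b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  a <- as.numeric(group_a); a <- a[!is.na(a)]
  b <- as.numeric(group_b); b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 observations", call. = FALSE)
  tt <- stats::t.test(a, b, var.equal = (variant == "pooled"))
  structure(list(t_statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value,
                 mean_a = mean(a), mean_b = mean(b),
                 sd_a = stats::sd(a), sd_b = stats::sd(b),
                 n_a = length(a), n_b = length(b), variant = variant),
            class = "yield_ttest")
}

#' @export
print.yield_ttest <- function(x, ...) {
  cat(sprintf("Two-sample t-test (%s): t = %.4f, df = %.4g, p = %.4g\n",
              x$variant, x$t_statistic, x$df, x$p_value))
  cat(sprintf("group A: mean %.4g ng (sd %.4g, n %d); group B: mean %.4g ng (sd %.4g, n %d)\n",
              x$mean_a, x$sd_a, x$n_a, x$mean_b, x$sd_b, x$n_b))
  invisible(x)
}
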