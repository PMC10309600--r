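# Air-quality discrimination: Fisher's LDA on standardized covariates,
# Mann-Whitney ROC AUC, and the model-free per-variable ROC importance
# (folded to [0.5, 1], scaled 0-100 across variables).

.aq_vars <- c("pm_0_3", "pm_0_5", "pm_1_0", "pm_2_5", "pm_5_0", "pm_10",
              "at", "rh", "dp", "wb")

#' Label sessions as yield-sufficient or -insufficient
#'
#' A session is "sufficient" iff its yield is at or above the threshold
#' (inclusive, matching the 10 ng target convention used throughout).
#'
#' @param x numeric yields (ng) or a data frame with a \code{yield_ng}
#'   (or \code{total_yield_ng}) column.
#' @param threshold_ng sufficiency threshold (default 10 ng).
#' @return factor with levels \code{c("insufficient", "sufficient")}.
#'   Warns if only one class is present.
#' @export
label_sufficiency <- function(x, threshold_ng = 10) {
  y <- if (is.data.frame(x)) {
    col <- intersect(c("yield_ng", "total_yield_ng"), names(x))[1]
    if (is.na(col)) stop("missing yield column ('yield_ng' or 'total_yield_ng')",
                         call. = FALSE)
    x[[col]]
  } else as.numeric(x)
  if (anyNA(y)) stop("missing yield values", call. = FALSE)
  lab <- factor(ifelse(y >= threshold_ng, "sufficient", "insufficient"),
                levels = c("insufficient", "sufficient"))
  if (length(unique(lab)) < 2)
    warning("single-class label set: all sessions ",
            levels(droplevels(lab))[1])
  lab
}

.as_binary <- function(labels) {
  f <- as.factor(labels)
  if (nlevels(droplevels(f)) != 2)
    stop("labels must contain exactly two classes", call. = FALSE)
  droplevels(f)
}

#' Fisher's linear discriminant on standardized covariates
#'
#' Covariates are centred and scaled to unit sd; the discriminant direction
#' is \eqn{w \propto S_p^{-1} (\bar x_{pos} - \bar x_{neg})} with
#' \eqn{S_p} the pooled within-class covariance.  A tiny ridge
#' (\code{1e-8} on the diagonal) is applied with a warning if the pooled
#' covariance is singular.  The positive class is the second factor level.
#'
#' @param x numeric matrix or data frame of covariates (rows = sessions).
#' @param labels two-class factor (second level = positive class).
#' @param prior \code{"equal"} or \code{"proportional"} class priors
#'   (affects only the decision threshold, not the direction or AUC).
#' @return object of class \code{"aq_lda"}: \code{variable_names},
#'   \code{center}, \code{scale}, \code{class_means} (standardized space),
#'   \code{w}, \code{prior}, \code{decision_threshold}, \code{scores},
#'   \code{labels}, \code{training_auc}.
#' @export
fit_lda <- function(x, labels, prior = c("equal", "proportional")) {
  prior <- match.arg(prior)
  x <- as.matrix(as.data.frame(x))
  storage.mode(x) <- "double"
  labels <- .as_binary(labels)
  keep <- stats::complete.cases(x) & !is.na(labels)
  dropped <- sum(!keep)
  if (dropped) message(dropped, " row(s) with missing values dropped")
  x <- x[keep, , drop = FALSE]; labels <- labels[keep]
  if (min(table(labels)) < 2)
    stop("each class needs at least 2 members", call. = FALSE)
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  if (any(scl == 0))
    stop("constant column(s) after standardisation: ",
         paste(colnames(x)[scl == 0], collapse = ", "), call. = FALSE)
  xs <- scale(x, center = ctr, scale = scl)
  pos <- labels == levels(labels)[2]
  mu1 <- colMeans(xs[pos, , drop = FALSE])
  mu0 <- colMeans(xs[!pos, , drop = FALSE])
  n1 <- sum(pos); n0 <- sum(!pos)
  S <- ((n1 - 1) * stats::cov(xs[pos, , drop = FALSE]) +
          (n0 - 1) * stats::cov(xs[!pos, , drop = FALSE])) / (n1 + n0 - 2)
  w <- tryCatch(solve(S, mu1 - mu0), error = function(e) {
    warning("singular pooled covariance; ridge 1e-8 applied")
    solve(S + diag(1e-8, ncol(S)), mu1 - mu0)
  })
  scores <- drop(xs %*% w)
  pr <- if (prior == "equal") c(0.5, 0.5) else c(n0, n1) / (n0 + n1)
  thr <- (sum(mu1 * w) + sum(mu0 * w)) / 2 - log(pr[2] / pr[1])
  structure(list(variable_names = colnames(x), center = ctr, scale = scl,
                 class_means = rbind(negative = mu0, positive = mu1),
                 w = w, prior = pr, decision_threshold = thr,
                 scores = scores, labels = labels,
                 training_auc = roc_auc(scores, labels)),
            class = "aq_lda")
}

#' @export
print.aq_lda <- function(x, digits = 4, ...) {
  cat("Fisher LDA on standardized covariates (positive class: '",
      levels(x$labels)[2], "')\n", sep = "")
  cat("discriminant direction w:\n")
  print(round(x$w, digits))
  cat(sprintf("training (resubstitution) ROC AUC: %.4f\n", x$training_auc))
  invisible(x)
}

#' @export
predict.aq_lda <- function(object, newdata, type = c("score", "class"), ...) {
  type <- match.arg(type)
  x <- as.matrix(as.data.frame(newdata))[, object$variable_names, drop = FALSE]
  xs <- scale(x, center = object$center, scale = object$scale)
  s <- drop(xs %*% object$w)
  if (type == "score") s
  else factor(ifelse(s >= object$decision_threshold,
                     levels(object$labels)[2], levels(object$labels)[1]),
              levels = levels(object$labels))
}

#' ROC area under the curve (Mann-Whitney)
#'
#' \eqn{AUC = P(s_{pos} > s_{neg}) + \frac{1}{2} P(s_{pos} = s_{neg})},
#' computed by rank sums.  The positive class is the second factor level.
#'
#' @param scores numeric scores.
#' @param labels two-class factor.
#' @return AUC in [0, 1].
#' @examples
#' roc_auc(1:6, factor(c("n", "n", "p", "n", "p", "p"),
#'                     levels = c("n", "p")))  # 8/9
#' @export
roc_auc <- function(scores, labels) {
  labels <- .as_binary(labels)
  if (length(scores) != length(labels))
    stop("scores and labels differ in length", call. = FALSE)
  pos <- labels == levels(labels)[2]
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Per-variable ROC importance
#'
#' Model-free filter importance: each covariate is used directly as a score
#' against the class label, its ROC AUC is folded to
#' \eqn{\max(AUC, 1-AUC)} and the folded values are rescaled to 0-100
#' across variables (the most discriminative variable scores 100, the
#' least 0).  With an \code{hour_index} grouping the analysis runs
#' independently per stratum.
#'
#' @param x covariate matrix / data frame.
#' @param labels two-class factor.
#' @param hour_index optional stratification factor (e.g. H1/H2/H3).
#' @return object of class \code{"importance_report"}: a data frame with
#'   columns \code{variable}, \code{hour} (if stratified), \code{raw_auc},
#'   \code{folded_auc}, \code{importance}, with the per-stratum LDA model
#'   AUC in \code{attr(, "model_auc")}.
#' @export
variable_importance <- function(x, labels, hour_index = NULL) {
  x <- as.data.frame(x)
  labels <- .as_binary(labels)
  one_stratum <- function(xi, li, hour = NA_character_) {
    raw <- vapply(xi, function(col) roc_auc(col, li), numeric(1))
    folded <- pmax(raw, 1 - raw)
    rng <- range(folded)
    imp <- if (diff(rng) == 0) {
      warning("all variables equally discriminative; importance set to 100")
      rep(100, length(folded))
    } else (folded - rng[1]) / diff(rng) * 100
    out <- data.frame(variable = names(xi), raw_auc = unname(raw),
                      folded_auc = unname(folded), importance = unname(imp))
    if (!is.na(hour)) out <- cbind(hour = hour, out)
    attr(out, "model_auc") <- fit_lda(xi, li)$training_auc
    out
  }
  if (is.null(hour_index)) {
    rep_df <- one_stratum(x, labels)
    model_auc <- attr(rep_df, "model_auc")
  } else {
    hour_index <- as.factor(hour_index)
    parts <- lapply(levels(hour_index), function(h) {
      sel <- hour_index == h
      one_stratum(x[sel, , drop = FALSE], droplevels(labels[sel]), h)
    })
    model_auc <- vapply(parts, attr, numeric(1), "model_auc")
    names(model_auc) <- levels(hour_index)
    rep_df <- do.call(rbind, parts)
  }
  structure(rep_df, model_auc = model_auc,
            class = c("importance_report", "data.frame"))
}

#' @export
print.importance_report <- function(x, digits = 3, ...) {
  cat("Per-variable ROC importance (folded AUC scaled 0-100)\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits)
  print(df, row.names = FALSE)
  ma <- attr(x, "model_auc")
  cat("LDA model (resubstitution) AUC:",
      paste(sprintf("%s%.3f", if (is.null(names(ma))) "" else
        paste0(names(ma), " = "), ma), collapse = ", "), "\n")
  invisible(x)
}

#' LDA model AUC under different evaluation schemes
#'
#' @param x covariates; \code{labels} two-class factor.
#' @param labels class labels.
#' @param method \code{"resubstitution"} (training AUC), \code{"cv"}
#'   (k-fold cross-validated scores), or \code{"loo"} (leave-one-out).
#' @param folds number of CV folds.
#' @param seed RNG seed for the fold assignment.
#' @return AUC in [0, 1].
#' @export
model_auc <- function(x, labels, method = c("resubstitution", "cv", "loo"),
                      folds = 5, seed = NULL) {
  method <- match.arg(method)
  x <- as.data.frame(x)
  labels <- .as_binary(labels)
  n <- nrow(x)
  if (method == "resubstitution") return(fit_lda(x, labels)$training_auc)
  idx <- if (method == "loo") seq_len(n) else {
    if (!is.null(seed)) set.seed(seed)
    sample(rep(seq_len(folds), length.out = n))
  }
  scores <- numeric(n)
  for (f in unique(idx)) {
    test <- idx == f
    fit <- fit_lda(x[!test, , drop = FALSE], labels[!test])
    scores[test] <- predict(fit, x[test, , drop = FALSE])
  }
  roc_auc(scores, labels)
}
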