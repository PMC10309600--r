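# Fisher LDA, Mann-Whitney AUC and ROC-filter variable importance.

two_class <- function(n, sep, seed) {
  set.seed(seed)
  data.frame(x = c(stats::rnorm(n, 0), stats::rnorm(n, sep)),
             lab = factor(rep(c("insufficient", "sufficient"), each = n)))
}

test_that("sufficiency labelling is inclusive at the threshold", {
  lab <- label_sufficiency(c(9.9, 10.0, 10.1), 10)
  expect_equal(as.character(lab),
               c("insufficient", "sufficient", "sufficient"))
  expect_warning(label_sufficiency(c(1, 2, 3), 10), "single-class")
  df <- data.frame(yield_ng = c(5, 15))
  expect_equal(as.character(label_sufficiency(df)),
               c("insufficient", "sufficient"))
  expect_error(label_sufficiency(data.frame(a = 1)), "yield")
})

test_that("roc_auc matches brute-force pair enumeration, with ties", {
  labs <- factor(c("n", "n", "p", "n", "p", "p"), levels = c("n", "p"))
  expect_equal(roc_auc(1:6, labs), 8 / 9)
  expect_equal(roc_auc(1:6, labs), pairwise_auc(1:6, labs))
  set.seed(412)
  for (i in 1:25) {
    s <- sample(1:5, 12, replace = TRUE)   # plenty of ties
    l <- factor(sample(c("n", "p"), 12, replace = TRUE, prob = c(0.5, 0.5)))
    if (nlevels(droplevels(l)) < 2) next
    expect_equal(roc_auc(s, l), pairwise_auc(s, l))
    expect_equal(roc_auc(s, l) + roc_auc(-s, l), 1)
  }
  expect_equal(roc_auc(c(1, 1, 1, 1), factor(c("n", "p", "n", "p"))), 0.5)
  expect_equal(roc_auc(c(0, 0, 9, 9), factor(c("n", "n", "p", "p"))), 1)
  expect_error(roc_auc(1:3, factor(rep("p", 3))), "two classes")
})

test_that("roc_auc agrees with pROC on a randomized score set", {
  set.seed(413)
  s <- stats::rnorm(60)
  l <- factor(sample(c("n", "p"), 60, replace = TRUE))
  expect_equal(roc_auc(s, l),
               as.numeric(pROC::auc(pROC::roc(l, s, levels = c("n", "p"),
                                              direction = "<", quiet = TRUE))))
})

test_that("discriminant direction is the pooled-covariance solve", {
  set.seed(414)
  n <- 200
  x <- data.frame(a = stats::rnorm(2 * n), b = 2 * stats::rnorm(2 * n))
  x$b <- x$b + 0.3 * x$a
  lab <- factor(rep(c("neg", "pos"), each = n))
  x$a[lab == "pos"] <- x$a[lab == "pos"] + 1
  x$b[lab == "pos"] <- x$b[lab == "pos"] + 1
  fit <- fit_lda(x, lab)
  # independent recomputation in standardized space
  xs <- scale(as.matrix(x))
  pos <- lab == "pos"
  S <- ((sum(pos) - 1) * stats::cov(xs[pos, ]) +
          (sum(!pos) - 1) * stats::cov(xs[!pos, ])) / (2 * n - 2)
  w_ref <- solve(S, colMeans(xs[pos, ]) - colMeans(xs[!pos, ]))
  expect_equal(fit$w / fit$w[1], w_ref / w_ref[1], tolerance = 1e-10)
  # hand case: diagonal pooled covariance diag(1, 4), delta mu = (1, 1)
  w_hand <- solve(diag(c(1, 4)), c(1, 1))
  expect_equal(unname(w_hand / w_hand[1]), c(1, 0.25))
})

test_that("LDA direction agrees with MASS::lda on standardized data", {
  set.seed(415)
  n <- 150
  x <- matrix(stats::rnorm(2 * n * 3), ncol = 3,
              dimnames = list(NULL, c("v1", "v2", "v3")))
  lab <- factor(rep(c("neg", "pos"), each = n))
  x[lab == "pos", 1] <- x[lab == "pos", 1] + 1.5
  fit <- fit_lda(x, lab)
  m <- MASS::lda(scale(x), grouping = lab)
  ratio <- fit$w / drop(m$scaling)
  expect_equal(max(ratio) / min(ratio), 1, tolerance = 1e-6)
})

test_that("well-separated classes score near-perfect training AUC", {
  d <- two_class(50, 6, seed = 416)
  fit <- fit_lda(d["x"], d$lab)
  expect_gte(fit$training_auc, 0.99)
  d0 <- two_class(100, 0, seed = 417)
  expect_equal(fit_lda(d0["x"], d0$lab)$training_auc, 0.5, tolerance = 0.1)
  expect_error(fit_lda(d["x"], factor(rep("a", 100))), "two classes")
  dd <- d; dd$const <- 1
  expect_error(fit_lda(dd[c("x", "const")], dd$lab), "constant column")
})

test_that("scores are invariant to affine rescaling of input columns", {
  set.seed(418)
  x <- data.frame(u = stats::rnorm(80), v = stats::rnorm(80))
  lab <- factor(rep(c("neg", "pos"), 40))
  x$u[lab == "pos"] <- x$u[lab == "pos"] + 1
  f1 <- fit_lda(x, lab)
  x2 <- x; x2$u <- 1000 * x2$u + 5; x2$v <- -0.01 * x2$v + 2
  f2 <- fit_lda(x2, lab)
  expect_equal(abs(f1$scores), abs(f2$scores), tolerance = 1e-10)
  expect_equal(f1$training_auc, f2$training_auc, tolerance = 1e-12)
})

test_that("variable importance folds, scales 0-100 and ranks planted signal", {
  set.seed(419)
  n <- 500
  lab <- factor(rep(c("neg", "pos"), each = n / 2))
  x <- data.frame(signal = stats::rnorm(n) + 2 * (lab == "pos"),
                  null = sample(stats::rnorm(n)))
  imp <- variable_importance(x, lab)
  expect_equal(imp$importance[imp$variable == "signal"], 100)
  expect_equal(imp$importance[imp$variable == "null"], 0)
  # null AUC sd is ~0.026 at n = 500; 0.1 is a ~4-sigma band
  expect_lt(abs(imp$folded_auc[imp$variable == "null"] - 0.5), 0.1)
  # importance is invariant to strictly increasing transforms
  x2 <- x; x2$signal <- exp(x2$signal)
  imp2 <- variable_importance(x2, lab)
  expect_equal(imp$raw_auc, imp2$raw_auc, tolerance = 1e-12)
  # anti-correlated variables are folded above one half
  x3 <- data.frame(neg_signal = -x$signal, null = x$null)
  imp3 <- variable_importance(x3, lab)
  expect_lt(imp3$raw_auc[1], 0.5)
  expect_equal(imp3$importance[1], 100)
})

test_that("planted air-quality signal is recovered at n = 2000", {
  g <- gen_air_quality(2000, effects = c(pm_0_3 = 2), noise_sd = 0.3,
                       seed = 420)
  labels <- label_sufficiency(g$records)
  imp <- variable_importance(g$records[, 1:10], labels)
  expect_equal(imp$importance[imp$variable == "pm_0_3"], 100)
  # meteorological covariates carry no planted signal
  null_auc <- imp$folded_auc[imp$variable %in% c("at", "rh")]
  expect_true(all(abs(null_auc - 0.5) < 0.05))
})

test_that("per-hour stratification reports one importance set per stratum", {
  g <- gen_air_quality(600, seed = 421)
  labels <- label_sufficiency(g$records)
  imp <- variable_importance(g$records[, 1:10], labels,
                             hour_index = g$records$hour_index)
  expect_setequal(unique(imp$hour), c("H1", "H2", "H3"))
  ma <- attr(imp, "model_auc")
  expect_named(ma, c("H1", "H2", "H3"))
  expect_true(all(ma >= 0 & ma <= 1))
  for (h in c("H1", "H2", "H3")) {
    sub <- imp[imp$hour == h, ]
    expect_equal(max(sub$importance), 100)
    expect_equal(min(sub$importance), 0)
  }
})

test_that("leave-one-out model AUC does not beat resubstitution on average", {
  set.seed(422)
  diffs <- replicate(50, {
    n <- 60
    lab <- factor(rep(c("neg", "pos"), each = n / 2))
    x <- data.frame(a = stats::rnorm(n) + 0.6 * (lab == "pos"),
                    b = stats::rnorm(n), c = stats::rnorm(n))
    model_auc(x, lab, "resubstitution") - model_auc(x, lab, "loo")
  })
  expect_gt(mean(diffs), 0)
  # cv with a fixed seed is reproducible
  n <- 80
  lab <- factor(rep(c("neg", "pos"), each = n / 2))
  x <- data.frame(a = stats::rnorm(n) + (lab == "pos"), b = stats::rnorm(n))
  expect_equal(model_auc(x, lab, "cv", seed = 3),
               model_auc(x, lab, "cv", seed = 3))
})
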