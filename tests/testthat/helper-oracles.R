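# Independent oracles used across test files.

# numerical moments of a skew-t via adaptive quadrature of the density
# (independent of dp2cp's closed forms)
quadrature_cp <- function(xi, omega, alpha, nu) {
  raw <- vapply(1:4, function(k) {
    stats::integrate(function(x) x^k * dskewt(x, xi, omega, alpha, nu),
                     -Inf, Inf, rel.tol = 1e-11)$value
  }, numeric(1))
  mu <- raw[1]
  v <- raw[2] - mu^2
  g1 <- (raw[3] - 3 * mu * v - mu^3) / v^1.5
  g2 <- (raw[4] - 4 * mu * raw[3] + 6 * mu^2 * raw[2] - 3 * mu^4) / v^2 - 3
  c(mean = mu, sd = sqrt(v), gamma1 = g1, gamma2 = g2)
}

# brute-force Mann-Whitney AUC by enumerating every positive-negative pair
pairwise_auc <- function(scores, labels) {
  labels <- droplevels(as.factor(labels))
  pos <- scores[labels == levels(labels)[2]]
  neg <- scores[labels == levels(labels)[1]]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

# brute-force rectangle mean by an explicit double loop (0-based half-open)
loop_rect_mean <- function(image, r0, c0, h, w) {
  acc <- 0
  for (i in seq_len(h)) for (j in seq_len(w))
    acc <- acc + image[r0 + i, c0 + j]
  acc / (h * w)
}
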