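## Compact exact t-SNE (no Barnes-Hut approximation), sufficient for the
## small validation cohorts this pipeline targets (tens of samples embedded
## from a handful of pathway-activity dimensions).

## per-point precision search so each conditional distribution has the
## requested perplexity (entropy = log(perplexity))
tsne_affinities <- function(X, perplexity, tol = 1e-5) {
  n <- nrow(X)
  D2 <- as.matrix(stats::dist(X))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; bmin <- -Inf; bmax <- Inf
    d <- D2[i, -i]
    for (iter in 1:50) {
      p <- exp(-d * beta)
      sump <- sum(p)
      if (sump == 0) p <- rep(1e-12, length(d)) else p <- p / sump
      H <- -sum(p * log(pmax(p, 1e-12)))
      diff <- H - logU
      if (abs(diff) < tol) break
      if (diff > 0) { bmin <- beta; beta <- if (is.finite(bmax)) (beta + bmax) / 2 else beta * 2 }
      else { bmax <- beta; beta <- if (is.finite(bmin)) (beta + bmin) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

## gradient-descent embedding with momentum, gains and early exaggeration
tsne_embed <- function(X, dims = 2, perplexity = 10, max_iter = 500,
                       eta = 100, seed = 1) {
  n <- nrow(X)
  P <- tsne_affinities(X, perplexity)
  set.seed(seed)
  Y <- matrix(stats::rnorm(n * dims, sd = 1e-4), n, dims)
  dY <- matrix(0, n, dims)
  gains <- matrix(1, n, dims)
  momentum <- 0.5
  P_run <- P * 4                       # early exaggeration
  for (iter in seq_len(max_iter)) {
    if (iter == 101) P_run <- P
    if (iter == 251) momentum <- 0.8
    num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    W <- (P_run - Q) * num
    grad <- 4 * (diag(rowSums(W)) - W) %*% Y
    gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    dY <- momentum * dY - eta * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}
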