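# Compact exact t-SNE for small point sets (the 72-row basin maps).
# Symmetric SNE affinities with per-point perplexity calibration by binary
# search, then momentum gradient descent with early exaggeration. Exact
# (no tree approximation): fine for n of order 100.

tsne_embed <- function(X, dims = 2L, perplexity = 15, max_iter = 500L,
                       eta = 100, seed = 1L) {
  n <- nrow(X)
  perplexity <- min(perplexity, (n - 1) / 3)
  D2 <- as.matrix(stats::dist(X))^2

  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1
    lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (iter in seq_len(64L)) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) { p <- rep(1 / length(di), length(di)); sp <- 1 }
      H <- log(sp) + beta * sum(di * p) / sp
      diff <- H - logU
      if (abs(diff) < 1e-5) break
      if (diff > 0) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p / sum(p)
  }
  P <- (P + t(P)) / (2 * n)
  P[P < 1e-12] <- 1e-12

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  Y <- matrix(stats::rnorm(n * dims, sd = 1e-4), n, dims)
  gains <- matrix(1, n, dims)
  inc <- matrix(0, n, dims)
  exag_until <- 100L
  Pe <- P * 4
  for (it in seq_len(max_iter)) {
    if (it == exag_until + 1L) Pe <- P
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- num / sum(num)
    Q[Q < 1e-12] <- 1e-12
    W <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(W)) - W) %*% Y
    momentum <- if (it <= 20L) 0.5 else 0.8
    gains <- ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    inc <- momentum * inc - eta * gains * grad
    Y <- Y + inc
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}
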