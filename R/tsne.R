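# Exact t-SNE (O(n^2)) for embedding latent sample scores. Latent score
# matrices are small (one row per sample), so the exact gradient is
# affordable and avoids approximation parameters. Standard recipe:
# perplexity-calibrated Gaussian input affinities (binary search on the
# bandwidth), Student-t output kernel, early exaggeration, momentum
# gradient descent with per-parameter gains.

.tsnePerplexityRow <- function(d2, perplexity, tol = 1e-5, maxTries = 50L) {
  target <- log(perplexity)
  beta <- 1
  betaMin <- -Inf; betaMax <- Inf
  for (i in seq_len(maxTries)) {
    w <- exp(-d2 * beta)
    sw <- sum(w)
    if (sw == 0) { h <- 0; p <- w }
    else {
      h <- log(sw) + beta * sum(d2 * w) / sw
      p <- w / sw
    }
    diff <- h - target
    if (abs(diff) < tol) break
    if (diff > 0) { betaMin <- beta; beta <- if (is.finite(betaMax)) (beta + betaMax) / 2 else beta * 2 }
    else { betaMax <- beta; beta <- if (is.finite(betaMin)) (beta + betaMin) / 2 else beta / 2 }
  }
  p
}

.tsne <- function(X, perplexity = 30, seed = 1L, maxIter = 500L,
                  eta = 100, exaggeration = 12, exaggerateIter = 100L) {
  n <- nrow(X)
  if (perplexity >= n) perplexity <- (n - 1) / 3
  D2 <- as.matrix(stats::dist(X))^2
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- setdiff(seq_len(n), i)
    P[i, idx] <- .tsnePerplexityRow(D2[i, idx], perplexity)
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  Y <- .withSeed(seed, matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2))
  inc <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  momentum <- 0.5
  Pe <- P * exaggeration
  for (iter in seq_len(maxIter)) {
    Puse <- if (iter <= exaggerateIter) Pe else P
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Puse - Q) * num
    grad <- 4 * (diag(rowSums(L)) %*% Y - L %*% Y)
    gains <- ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    inc <- momentum * inc - eta * gains * grad
    Y <- Y + inc
    Y <- sweep(Y, 2, colMeans(Y), "-")
    if (iter == 250L) momentum <- 0.8
  }
  Y
}
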