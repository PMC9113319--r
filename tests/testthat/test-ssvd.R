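test_that("dense truncated SVD matches a full-SVD oracle", {
  # trivial diagonal case
  f <- denseSVD(diag(c(3, 1)), K = 1)
  expect_equal(singularValues(f), 3)
  expect_equal(abs(featureLoadings(f)[, 1]), c(1, 0), tolerance = 1e-10)

  X <- randMatrix(20, 30, seed = 31)
  ref <- svd(X)
  f <- denseSVD(X, K = 5)
  expect_equal(singularValues(f), ref$d[1:5], tolerance = 1e-10)
  expect_lt(max(principalAngles(featureLoadings(f), ref$v[, 1:5])), 1e-6)
  expect_lt(max(principalAngles(sampleScores(f), ref$u[, 1:5])), 1e-6)

  # exact rank deficiency: K beyond the rank pads a zero singular value
  X2 <- tcrossprod(randMatrix(15, 2, 32), randMatrix(10, 2, 33))
  f2 <- denseSVD(X2, K = 3)
  expect_lt(singularValues(f2)[3], 1e-10)
  expect_error(denseSVD(X2, K = 11), "K")
})

test_that("sign convention puts the largest loading positive", {
  X <- randMatrix(25, 12, seed = 34)
  f <- denseSVD(X, K = 4)
  V <- featureLoadings(f)
  for (k in 1:4) expect_gt(V[which.max(abs(V[, k])), k], 0)
})

test_that("unpenalized rank-1 iteration reproduces the dense triplet", {
  X <- randMatrix(40, 25, seed = 35)
  ref <- svd(X)
  fit <- rank1SSVD(X, PenaltySpec(alpha = 1, lam = 0))
  expect_equal(fit$d, ref$d[1], tolerance = 1e-8)
  expect_equal(abs(sum(fit$v * ref$v[, 1])), 1, tolerance = 1e-8)
  expect_equal(sum(fit$u^2), 1, tolerance = 1e-12)
})

test_that("rank-1 iteration recovers a planted noiseless support", {
  set.seed(36)
  u0 <- rnorm(30); u0 <- u0 / sqrt(sum(u0^2))
  v0 <- numeric(50); v0[c(3, 10, 22, 41, 47)] <- c(2, -1, 3, 1, -2)
  v0 <- v0 / sqrt(sum(v0^2))
  X <- 7 * tcrossprod(u0, v0)
  fit <- rank1SSVD(X, PenaltySpec(alpha = 1, degree = 5))
  expect_setequal(which(fit$v != 0), which(v0 != 0))
  expect_equal(fit$d, 7, tolerance = 1e-6)

  # exact rank-1 positive matrix: fixed point from the dense start
  Y <- tcrossprod(runif(10) + 1, runif(8) + 1)
  fit2 <- rank1SSVD(Y, PenaltySpec(alpha = 1, degree = 8))
  expect_lte(fit2$iter, 2)
  expect_true(fit2$converged)
})

test_that("penalized objective is non-increasing across iterations", {
  # alternating prox/least-squares updates descend the fixed-lam criterion
  # ||X - u vtilde'||^2 + 2 lam (alpha |vtilde|_1 + (1-alpha)/2 |vtilde|^2)
  set.seed(37)
  for (r in 1:10) {
    X <- matrix(rnorm(60 * 40), 60, 40) +
      3 * tcrossprod(rnorm(60), rnorm(40) * rbinom(40, 1, 0.3))
    lam <- runif(1, 0.5, 3)
    alpha <- runif(1, 0.3, 1)
    fit <- suppressWarnings(
      rank1SSVD(X, PenaltySpec(alpha = alpha, lam = lam), trace = TRUE))
    obj <- vapply(fit$history, function(h) {
      sum((X - tcrossprod(h$u, h$vtilde))^2) +
        2 * lam * (alpha * sum(abs(h$vtilde)) +
                     (1 - alpha) * sum(h$vtilde^2) / 2)
    }, numeric(1))
    expect_true(all(diff(obj) <= 1e-8 * abs(obj[1])))
  }
})

test_that("deflation subtracts exactly one rank-1 component", {
  set.seed(38)
  u <- rnorm(12); u <- u / sqrt(sum(u^2))
  v <- rnorm(9); v <- v / sqrt(sum(v^2))
  X <- 4.2 * tcrossprod(u, v)
  expect_lt(max(abs(deflate(X, u, 4.2, v))), 1e-10)
  # zero-d deflation is the identity
  expect_identical(deflate(X, u, 0, v), X)
  # spectral-norm oracle: after deflating k dense factors, the residual's
  # leading singular value is the (k+1)-th of the original
  Y <- randMatrix(30, 20, seed = 39)
  ref <- svd(Y)
  R <- Y
  for (k in 1:3) {
    R <- deflate(R, ref$u[, k], ref$d[k], ref$v[, k])
    expect_equal(svd(R)$d[1], ref$d[k + 1], tolerance = 1e-10)
  }
  expect_error(deflate(Y, 2 * ref$u[, 1], 1, ref$v[, 1]), "unit")
})

test_that("multi-factor decomposition recovers disjoint planted supports", {
  set.seed(40)
  n <- 80; p <- 60
  u1 <- rnorm(n); u1 <- u1 / sqrt(sum(u1^2))
  u2 <- rnorm(n); u2 <- u2 - u1 * sum(u1 * u2); u2 <- u2 / sqrt(sum(u2^2))
  v1 <- numeric(p); v1[1:6] <- sample(c(-1, 1), 6, TRUE) / sqrt(6)
  v2 <- numeric(p); v2[31:38] <- sample(c(-1, 1), 8, TRUE) / sqrt(8)
  X <- 50 * tcrossprod(u1, v1) + 35 * tcrossprod(u2, v2) +
    matrix(rnorm(n * p), n, p)
  fit <- omicSSVD(X, K = 2, penalty = "auto", candidateDegrees = c(4, 6, 8, 12))
  V <- featureLoadings(fit)
  expect_setequal(which(V[, 1] != 0), 1:6)
  expect_setequal(which(V[, 2] != 0), 31:38)
  expect_equal(selectedDegree(fit), c(6L, 8L))
})

test_that("zero-penalty decomposition equals the dense SVD up to sign", {
  X <- randMatrix(50, 35, seed = 41)
  fit <- omicSSVD(X, K = 4, penalty = PenaltySpec(alpha = 0.5, lam = 0))
  ref <- denseSVD(X, K = 4)
  expect_equal(singularValues(fit), singularValues(ref), tolerance = 1e-8)
  expect_lt(max(abs(abs(featureLoadings(fit)) - abs(featureLoadings(ref)))),
            1e-6)
  # the dense initializations are reported alongside
  expect_equal(denseFactors(fit)$d, singularValues(ref), tolerance = 1e-8)
})

test_that("leading factor of a positive matrix is nonnegative", {
  set.seed(42)
  X <- matrix(runif(20 * 15) + 0.5, 20, 15)
  fit <- omicSSVD(X, K = 1)
  expect_true(all(featureLoadings(fit) >= -1e-12))
  expect_true(all(sampleScores(fit) >= -1e-12))
})

test_that("decomposition is scale equivariant", {
  X <- randMatrix(30, 40, seed = 43)
  f1 <- omicSSVD(X, K = 3, penalty = PenaltySpec(alpha = 1, degree = 10))
  f2 <- omicSSVD(2.5 * X, K = 3, penalty = PenaltySpec(alpha = 1, degree = 10))
  expect_equal(singularValues(f2), 2.5 * singularValues(f1),
               tolerance = 1e-6)
  expect_equal(featureLoadings(f2), featureLoadings(f1), tolerance = 1e-5)
  expect_equal(sampleScores(f2), sampleScores(f1), tolerance = 1e-5)
})

test_that("degenerate inputs are rejected with clear errors", {
  X <- randMatrix(10, 8, seed = 44)
  expect_error(omicSSVD(X, K = 0), "K")
  expect_error(omicSSVD(X, K = 9), "K")
  expect_error(omicSSVD(X, K = 2,
                        penalty = PenaltySpec(alpha = 1, degree = 9)),
               "exceeds")
  expect_error(rank1SSVD(matrix(0, 5, 5), PenaltySpec(alpha = 1, lam = 0)),
               "zero")
  expect_warning(
    fit <- rank1SSVD(X, PenaltySpec(alpha = 1, lam = 1e3)),
    "zeroed")
  expect_equal(fit$d, 0)
})
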