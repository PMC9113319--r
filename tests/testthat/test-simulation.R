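test_that("correlated base generator has the advertised correlation level", {
  # rank 0: mean |off-diagonal r| matches the independence baseline
  # E|r| ~ sqrt(2/(pi*n)) for large n
  n <- 200
  X0 <- makeCorrelatedBase(n, 80, latentRank = 0, seed = 81)
  r0 <- abs(cor(X0)[upper.tri(diag(80))])
  expect_equal(mean(r0), sqrt(2 / (pi * n)), tolerance = 0.1)
  # rank 3 lifts correlation far above the baseline (>> 5 sigma)
  X3 <- makeCorrelatedBase(n, 80, latentRank = 3, seed = 81)
  r3 <- abs(cor(X3)[upper.tri(diag(80))])
  sdBase <- sd(r0) / sqrt(length(r0))
  expect_gt(mean(r3), mean(r0) + 5 * sdBase)
  # fixed seed: bit-identical
  expect_identical(X0, makeCorrelatedBase(n, 80, latentRank = 0, seed = 81))
  expect_error(makeCorrelatedBase(10, 5, latentRank = 5), "latentRank")
})

test_that("shuffling preserves each column's value multiset exactly", {
  X <- makeCorrelatedBase(60, 30, latentRank = 2, seed = 82)
  inf <- c(3, 7, 20)
  Y <- shuffleDecorrelate(X, inf, seed = 4)
  expect_identical(Y[, inf], X[, inf])  # informative columns untouched
  for (j in setdiff(seq_len(30), inf)) {
    expect_identical(sort(Y[, j]), sort(X[, j]))
    expect_equal(mean(Y[, j]), mean(X[, j]))
    expect_equal(var(Y[, j]), var(X[, j]))
  }
  # informative = all columns is the identity
  expect_identical(shuffleDecorrelate(X, seq_len(30), seed = 4), X)
  expect_error(shuffleDecorrelate(X, c(1, 31)), "1, 30")
})

test_that("full shuffling drives correlation to the independence baseline", {
  n <- 200
  X <- makeCorrelatedBase(n, 60, latentRank = 3, seed = 83)
  Y <- shuffleDecorrelate(X, integer(0), seed = 5)
  rY <- abs(cor(Y)[upper.tri(diag(60))])
  expect_equal(mean(rY), sqrt(2 / (pi * n)), tolerance = 0.1)
})

test_that("confusion statistics follow their closed forms", {
  expect_equal(confusionStats(1:10, 1:10, 50),
               c(sensitivity = 1, specificity = 1))
  expect_equal(confusionStats(integer(0), 1:10, 50),
               c(sensitivity = 0, specificity = 1))
  # TP=8, FN=2, FP=5, TN=85
  out <- confusionStats(c(1:8, 11:15), 1:10, 100)
  expect_equal(unname(out), c(0.8, 85 / 90))
  expect_error(confusionStats(1:3, integer(0), 10), "undefined")
  expect_error(confusionStats(11, 1:2, 10), "1, 10")
})

test_that("benchmark endpoints are forced by the definitions", {
  b <- runFeatureBenchmark(n = 30, p = 40, latentRank = 2,
                           signalFraction = 0.1, nReplicates = 2,
                           degreeGrid = c(0, 40), K = 1, seed = 9)
  s <- benchmarkSummary(b)
  expect_equal(s$meanSensitivity[s$degree == 0], 0)
  expect_equal(s$meanSpecificity[s$degree == 0], 1)
  expect_equal(s$meanSensitivity[s$degree == 40], 1)
  expect_equal(s$meanSpecificity[s$degree == 40], 0)
  # confusion identities per replicate
  m <- length(b@informative[[1]])
  expect_true(all(b@replicates$TP + b@replicates$FN == m))
  expect_true(all(b@replicates$TN + b@replicates$FP == 40 - m))
  expect_error(runFeatureBenchmark(n = 10, p = 20, degreeGrid = 30,
                                   nReplicates = 1), "degreeGrid")
  expect_error(runFeatureBenchmark(n = 10, p = 20, signalFraction = 1.5,
                                   nReplicates = 1), "signalFraction")
})

test_that("a strong planted spike is detected with high sensitivity", {
  # rank-1 spike on the informative set at d0 = 5*sqrt(n); selection at the
  # true degree recovers the support in nearly every replicate
  n <- 100; p <- 50; m <- 5
  sens <- vapply(1:20, function(r) {
    inst <- makePlantedRank1(n, p, support = m, seed = 900 + r)
    Xs <- scale(inst$X)
    fit <- omicSSVD(Xs, K = 1, penalty = PenaltySpec(alpha = 1, degree = m))
    sel <- which(featureLoadings(fit)[, 1] != 0)
    confusionStats(sel, inst$support, p)[["sensitivity"]]
  }, numeric(1))
  expect_gte(mean(sens), 0.95)
})

test_that("benchmark is deterministic given the master seed", {
  b1 <- runFeatureBenchmark(n = 25, p = 30, latentRank = 2,
                            signalFraction = 0.2, nReplicates = 2,
                            degreeGrid = c(5, 15), K = 1, seed = 77)
  b2 <- runFeatureBenchmark(n = 25, p = 30, latentRank = 2,
                            signalFraction = 0.2, nReplicates = 2,
                            degreeGrid = c(5, 15), K = 1, seed = 77)
  expect_identical(b1@replicates, b2@replicates)
  expect_identical(b1@informative, b2@informative)
  # replicate seeds are recorded as seed + replicate index
  expect_identical(unique(b1@replicates$seed), c(78, 79))
})

test_that("sensitivity rises and specificity falls along the degree grid", {
  b <- runFeatureBenchmark(n = 50, p = 120, latentRank = 3,
                           signalFraction = 0.1, nReplicates = 8,
                           degreeGrid = c(4, 12, 30, 60, 120), K = 3,
                           seed = 31)
  s <- benchmarkSummary(b)
  expect_true(all(diff(s$meanSensitivity) >= -0.02))
  expect_true(all(diff(s$meanSpecificity) <= 0.02))
})
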