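test_that("well-separated blobs cluster perfectly with chosen k = 2", {
  set.seed(71)
  S <- rbind(matrix(rnorm(60, 0, 1), 30, 2),
             matrix(rnorm(60, 10, 1), 30, 2))  # ~10 sigma separation
  truth <- rep(1:2, each = 30)
  res <- clusterScores(S, kRange = 2:5, seed = 3)
  expect_identical(chosenK(res), 2L)
  lab <- clusterLabels(res)
  agree <- max(mean(lab == truth), mean(lab == 3 - truth))
  expect_equal(agree, 1)
  expect_true(all(res@quality >= -1 & res@quality <= 1))
})

test_that("identical points fall back to a single cluster with a warning", {
  S <- matrix(1, 20, 3)
  expect_warning(res <- clusterScores(S, kRange = 2:4), "single cluster")
  expect_identical(chosenK(res), 1L)
  expect_true(all(clusterLabels(res) == 1L))
})

test_that("clustering is invariant to sign flips and isotropic rotation", {
  set.seed(72)
  U <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 6), 20, 2))
  U <- sweep(U, 2, sqrt(colSums(U^2)), "/")
  d <- c(3, 3)  # isotropic weights
  base <- clusterScores(U, d, kRange = 2:3, seed = 5)
  flip <- clusterScores(U %*% diag(c(-1, 1)), d, kRange = 2:3, seed = 5)
  theta <- 0.7
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  rot <- clusterScores(U %*% R, d, kRange = 2:3, seed = 5)
  match12 <- function(a, b) max(mean(a == b), mean(a == 3 - b))
  expect_equal(match12(clusterLabels(base), clusterLabels(flip)), 1)
  expect_equal(match12(clusterLabels(base), clusterLabels(rot)), 1)
})

test_that("kRange outside [2, n-1] is rejected", {
  S <- matrix(rnorm(20), 10, 2)
  expect_error(clusterScores(S, kRange = 1:3), "kRange")
  expect_error(clusterScores(S, kRange = 2:10), "kRange")
})

test_that("embedding contracts hold for both methods", {
  set.seed(73)
  U <- matrix(rnorm(60), 20, 3)
  d <- c(5, 3, 1)
  # "none" = first two variance-weighted score columns
  out <- embedScores(U, d, method = "none")
  expect_equal(unname(out), sweep(U, 2, d, "*")[, 1:2])
  # t-SNE: shape and seed-determinism
  t1 <- embedScores(U, d, method = "tsne", seed = 9)
  t2 <- embedScores(U, d, method = "tsne", seed = 9)
  expect_identical(dim(t1), c(20L, 2L))
  expect_identical(t1, t2)
  expect_false(identical(t1, embedScores(U, d, method = "tsne", seed = 10)))
  expect_error(embedScores(U, d, method = "umap"), "arg")
  expect_error(embedScores(U[1:3, ], d, method = "tsne"), "at least 5")
})

test_that("t-SNE keeps well-separated groups separated", {
  set.seed(74)
  S <- rbind(matrix(rnorm(40, 0, 0.3), 20, 2),
             matrix(rnorm(40, 8, 0.3), 20, 2))
  Y <- embedScores(S, d = c(1, 1), method = "tsne", seed = 1)
  within <- c(dist(Y[1:20, ]), dist(Y[21:40, ]))
  between <- as.matrix(dist(Y))[1:20, 21:40]
  expect_gt(min(between), max(within) * 0.5)
})
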