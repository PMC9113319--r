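test_that("blocks align to the first block's sample order", {
  blocks <- toyBlocks()
  expect_identical(alignBlocks(blocks)[[2]]@values, blocks[[2]]@values)
  # reversed rows come back in reference order with values permuted along
  rev2 <- OmicBlock(blocks[[2]]@values[rev(seq_len(12)), ], "protein")
  aligned <- alignBlocks(list(blocks[[1]], rev2))
  expect_identical(aligned[[2]]@values, blocks[[2]]@values)
  # a missing sample is an alignment error naming the difference
  short <- OmicBlock(blocks[[2]]@values[-3, ], "protein")
  expect_error(alignBlocks(list(blocks[[1]], short)), "s03")
})

test_that("mean imputation fills by column means and keeps the mask", {
  m <- matrix(c(1, NA, 3, 4, 5, 6), 3, 2,
              dimnames = list(paste0("s", 1:3), c("f1", "f2")))
  b <- imputeMeans(OmicBlock(m, "x"))
  expect_equal(as.matrix(b)[, "f1"], c(s1 = 1, s2 = 2, s3 = 3))
  expect_true(b@missingMask[2, 1])
  # no missing values: identity
  full <- toyBlocks()[[1]]
  expect_identical(as.matrix(imputeMeans(full)), as.matrix(full))
  # fully missing column: error naming the feature
  m[, 2] <- NA
  expect_error(imputeMeans(OmicBlock(m, "x")), "f2")
})

test_that("covariate residualization is an exact projection", {
  set.seed(21)
  X <- matrix(rnorm(30 * 5), 30, 5)
  # intercept only = column centering
  expect_equal(adjustCovariates(X, data.frame(row.names = 1:30)),
               scale(X, scale = FALSE), ignore_attr = TRUE)
  # residuals orthogonal to every covariate column
  cov <- data.frame(age = rnorm(30), sex = factor(rep(c("a", "b"), 15)))
  res <- adjustCovariates(X, cov)
  D <- model.matrix(~ ., cov)
  expect_lt(max(abs(crossprod(D, res))), 1e-10)
  # regressing a column on itself zeroes it exactly (projection oracle)
  res2 <- adjustCovariates(X, data.frame(z = X[, 3]))
  expect_lt(max(abs(res2[, 3])), 1e-10)
  # rank-deficient design is rejected
  expect_error(adjustCovariates(X, data.frame(a = 1:30, b = 2 * (1:30))),
               "rank deficient")
  expect_error(adjustCovariates(X, data.frame(a = c(NA, rnorm(29)))),
               "missing")
})

test_that("standardization centers, scales, and equalizes block norms", {
  sids <- paste0("s", 1:3)
  b <- OmicBlock(matrix(c(1, 2, 3), 3, 1, dimnames = list(sids, "f")), "x")
  em <- standardizeBlocks(list(b))
  # (1,2,3) -> (-1,0,1) before block rescaling (sample sd divisor n-1)
  expect_equal(as.numeric(as.matrix(em)) * blockNorms(em), c(-1, 0, 1))

  blocks <- toyBlocks()  # block 2 has ~5x the scale of block 1
  em <- buildExtendedMatrix(blocks)
  v <- as.matrix(em)
  expect_lt(max(abs(colMeans(v))), 1e-12)
  for (lab in c("rna", "protein"))
    expect_equal(sum(v[, columnMap(em)$block == lab]^2), 1)
})

test_that("standardization round-trips through the inverse transform", {
  blocks <- toyBlocks(seed = 5)
  em <- standardizeBlocks(blocks)
  back <- inverseTransform(em)
  for (i in 1:2) {
    orig <- as.matrix(blocks[[i]])
    expect_lt(max(abs(back[[blockLabel(blocks[[i]])]] - orig)) /
                max(abs(orig)), 1e-10)
  }
})

test_that("constant columns are zeroed with a warning, not dropped", {
  sids <- paste0("s", 1:5)
  m <- cbind(const = rep(2, 5), ok = rnorm(5))
  rownames(m) <- sids
  expect_warning(em <- standardizeBlocks(list(OmicBlock(m, "x"))),
                 "constant")
  expect_equal(ncol(as.matrix(em)), 2L)
  expect_true(all(as.matrix(em)[, 1] == 0))
  expect_identical(columnMap(em)$feature, c("const", "ok"))
})

test_that("preprocessing is idempotent up to block rescaling", {
  blocks <- toyBlocks(seed = 9)
  em1 <- buildExtendedMatrix(blocks)
  # feed the standardized output back through the chain
  v <- as.matrix(em1)
  again <- list()
  for (lab in unique(columnMap(em1)$block))
    again[[lab]] <- v[, columnMap(em1)$block == lab, drop = FALSE]
  em2 <- buildExtendedMatrix(again)
  # identical up to each block's Frobenius rescaling (already unit here)
  expect_equal(as.matrix(em2), v, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("delimited and MatrixMarket readers round-trip a block", {
  b <- toyBlocks()[[1]]
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeToyBlockTSV(b, tsv)
  back <- readOmicBlock(tsv, label = "rna")
  expect_equal(as.matrix(back), as.matrix(b))
  expect_identical(blockLabel(back), "rna")

  # missing cells come back as NA
  m <- as.matrix(b)
  m[2, 2] <- NA
  writeToyBlockTSV(OmicBlock(m, "rna"), tsv)
  expect_true(is.na(as.matrix(readOmicBlock(tsv))[2, 2]))

  mtx <- withr::local_tempfile(fileext = ".mtx")
  sp <- as.matrix(b)
  sp[abs(sp) < 0.5] <- 0
  Matrix::writeMM(Matrix::Matrix(sp, sparse = TRUE), mtx)
  writeLines(rownames(sp), paste0(mtx, ".rows"))
  writeLines(colnames(sp), paste0(mtx, ".cols"))
  back <- readOmicBlock(mtx, label = "rna")
  expect_equal(as.matrix(back), sp, ignore_attr = TRUE)
  expect_identical(featureIds(back), colnames(sp))
})

test_that("extended matrices serialize to TSV + JSON and back", {
  em <- buildExtendedMatrix(toyBlocks())
  path <- withr::local_tempfile(fileext = ".tsv")
  writeExtendedMatrix(em, path)
  back <- readExtendedMatrix(path)
  expect_equal(as.matrix(back), as.matrix(em), tolerance = 1e-12)
  expect_identical(columnMap(back)$feature, columnMap(em)$feature)
  expect_equal(blockNorms(back), blockNorms(em))
})
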