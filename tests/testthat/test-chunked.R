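test_that("chunked storage round-trips bit for bit", {
  X <- randMatrix(23, 11, seed = 61)
  for (cr in c(1, 5, 23, 40)) {  # includes 1 row/chunk and chunks > n
    path <- withr::local_tempfile(fileext = ".bin")
    cm <- writeChunkedMatrix(X, path, chunkRows = cr)
    expect_identical(as.matrix(cm), X)
  }
  # reopening from the header reproduces the handle
  path <- withr::local_tempfile(fileext = ".bin")
  writeChunkedMatrix(X, path, chunkRows = 7)
  cm2 <- readChunkedMatrix(path)
  expect_identical(dim(cm2), c(23L, 11L))
  expect_identical(as.matrix(cm2), X)
})

test_that("extended-matrix metadata survives the chunked round trip", {
  em <- buildExtendedMatrix(toyBlocks())
  path <- withr::local_tempfile(fileext = ".bin")
  cm <- writeChunkedMatrix(em, path, chunkRows = 5)
  expect_identical(sampleIds(cm), sampleIds(em))
  expect_identical(columnMap(cm)$feature, columnMap(em)$feature)
  expect_identical(unname(as.matrix(cm)), unname(as.matrix(em)))
})

test_that("streaming products agree with in-memory products", {
  # identity: product returns the vector unchanged
  I5 <- diag(5)
  path <- withr::local_tempfile(fileext = ".bin")
  cm <- writeChunkedMatrix(I5, path, chunkRows = 2)
  expect_equal(chunkedMatvec(cm, 1:5), as.numeric(1:5))
  expect_equal(chunkedCrossprodVec(cm, 1:5), as.numeric(1:5))

  X <- randMatrix(500, 200, seed = 62)
  path <- withr::local_tempfile(fileext = ".bin")
  cm <- writeChunkedMatrix(X, path, chunkRows = 37)
  v <- rnorm(200); u <- rnorm(500)
  expect_equal(chunkedMatvec(cm, v), as.numeric(X %*% v),
               tolerance = 1e-10)
  expect_equal(chunkedCrossprodVec(cm, u), as.numeric(crossprod(X, u)),
               tolerance = 1e-10)
  expect_equal(chunkedMatvec(cm, numeric(200)), numeric(500))
  expect_error(chunkedMatvec(cm, rnorm(7)), "length")
  expect_error(chunkedCrossprodVec(cm, rnorm(7)), "length")
})

test_that("decomposition is independent of the chunk size", {
  X <- randMatrix(120, 300, seed = 63) +
    5 * tcrossprod(rnorm(120), rnorm(300) * rbinom(300, 1, 0.1))
  fmem <- omicSSVD(X, K = 3, penalty = PenaltySpec(alpha = 1, degree = 25))
  for (cr in c(1, 7, 64, 120)) {
    path <- withr::local_tempfile(fileext = ".bin")
    cm <- writeChunkedMatrix(X, path, chunkRows = cr)
    fchk <- omicSSVD(cm, K = 3, penalty = PenaltySpec(alpha = 1, degree = 25))
    expect_equal(singularValues(fchk), singularValues(fmem),
                 tolerance = 1e-8)
    expect_lt(max(abs(featureLoadings(fchk) - featureLoadings(fmem))), 1e-8)
    expect_lt(max(abs(sampleScores(fchk) - sampleScores(fmem))), 1e-8)
  }
})
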