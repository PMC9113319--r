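test_that("elastic-net proximal map matches closed forms", {
  expect_equal(enThreshold(3, 1, 1), 2)
  expect_equal(enThreshold(0.5, 1, 1), 0)
  expect_equal(enThreshold(3, 1, 0), 1.5)
  expect_equal(enThreshold(-3, 2, 0.5), -1)
  # vectorized, zero penalty is the identity
  z <- c(-2.5, 0, 0.3, 4)
  expect_identical(enThreshold(z, 0, 0.7), z)
})

test_that("elastic-net operator is a sign-preserving contraction", {
  set.seed(11)
  for (r in 1:20) {
    z <- rnorm(50, sd = 3)
    lam <- runif(1, 0, 5)
    alpha <- runif(1)
    out <- enThreshold(z, lam, alpha)
    expect_true(all(abs(out) <= abs(z) + 1e-12))
    expect_true(all(out == 0 | sign(out) == sign(z)))
    expect_lte(sum(out^2), sum(z^2) + 1e-12)
  }
  # ridge never zeroes a nonzero entry
  expect_true(all(enThreshold(c(1e-8, -2), 10, 0) != 0))
})

test_that("nonzero count under soft-thresholding is non-increasing in lam", {
  set.seed(12)
  z <- rnorm(100)
  lams <- seq(0, 3, length.out = 40)
  counts <- vapply(lams, function(l) sum(enThreshold(z, l, 1) != 0), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("degree targeting yields exactly the requested nonzero count", {
  expect_equal(degreeThreshold(c(5, 3, 1), 3, 1), c(5, 3, 1))
  expect_equal(degreeThreshold(c(5, 3, 1), 2, 1), c(4, 2, 0))
  set.seed(13)
  for (r in 1:25) {
    z <- rnorm(80)  # distinct |z| almost surely
    k <- sample(79, 1)
    alpha <- runif(1, 0.2, 1)
    out <- degreeThreshold(z, k, alpha)
    expect_equal(sum(out != 0), k)
    # kept entries are the k largest in magnitude
    expect_setequal(which(out != 0), order(-abs(z))[seq_len(k)])
  }
})

test_that("ties at the degree cutoff resolve deterministically", {
  # achievable nonzero counts for z = (5,3,3,1) by any soft-threshold cutoff
  # are {0,1,3,4}; a degree of 2 falls in the gap and the data-driven
  # cutoff |z|_(3) = 3 zeroes both tied entries, leaving 1 nonzero.
  z <- c(5, 3, 3, 1)
  counts <- vapply(c(abs(z), 0),
                   function(l) sum(enThreshold(z, l, 1) != 0), 0L)
  expect_false(2L %in% counts)
  out <- degreeThreshold(z, 2, 1)
  expect_equal(out, c(2, 0, 0, 0))
  expect_identical(out, degreeThreshold(z, 2, 1))  # deterministic
})

test_that("zero vectors pass through any penalty unchanged", {
  z <- numeric(6)
  expect_identical(enThreshold(z, 2, 0.5), z)
  expect_identical(degreeThreshold(z, 3, 1), z)
})

test_that("invalid penalty parameters are rejected", {
  expect_error(enThreshold(1:3, -1, 1), "nonnegative")
  expect_error(enThreshold(1:3, 1, 1.5), "0, 1")
  expect_error(degreeThreshold(1:3, 0, 1), "integer in")
  expect_error(degreeThreshold(1:3, 4, 1), "integer in")
  expect_error(degreeThreshold(1:3, 2, 0), "alpha > 0")
  expect_error(PenaltySpec(alpha = 0, degree = 2), "ridge")
  expect_error(PenaltySpec(alpha = 1, lam = 1, degree = 2), "exactly one")
  expect_error(PenaltySpec(alpha = 1), "exactly one")
})
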