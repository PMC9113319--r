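# Automatic tuning of the degree of sparsity (number of nonzero loadings)
# by a rank-1 residual BIC:
#   BIC(k) = log(RSS_k / (n P)) + k log(n P) / (n P),
#   RSS_k  = || R - d u v' ||_F^2 = ||R||_F^2 - d^2,
# the identity holding exactly at the fixed point since u = Rv/||Rv|| and
# d = u'Rv. ||R||^2 is tracked recursively across deflations, so no
# residual is ever materialized (chunked backends included).

.defaultDegreeGrid <- function(P, length = 20L) {
  g <- unique(as.integer(round(exp(seq(log(1), log(P), length.out = length)))))
  sort(g)
}

.checkDegreeGrid <- function(grid, P) {
  if (length(grid) < 1L) stop("candidate degree grid is empty")
  grid <- as.integer(grid)
  if (anyNA(grid) || any(grid < 1L) || any(grid > P))
    stop(sprintf("candidate degrees must lie in [1, %d]", P))
  sort(unique(grid))
}

# Tune one factor on the current residual; returns the criterion curve, the
# selected degree (smallest minimizer), its fitted triplet, and a flatness
# flag. A curve is "flat" when the best candidate improves on the null fit
# (d = 0) by no more than the leading singular value of an equally sized
# pure-noise matrix would, i.e. log(RSS) drops by less than
# (sqrt(n) + sqrt(P))^2 / (nP).
.tuneFactor <- function(A, defl, alpha, grid, R2, nP, tol, maxIter,
                        startV = NULL) {
  fits <- vector("list", length(grid))
  crit <- numeric(length(grid))
  pen <- log(nP) / nP
  # dense initialization, shared across all candidate degrees
  init <- .lanczosSVD(A, k = 1L, defl = defl, v0 = startV)
  dims <- dim(A)
  for (i in seq_along(grid)) {
    fits[[i]] <- .rank1(A, defl, PenaltySpec(alpha = alpha, degree = grid[i]),
                        tol, maxIter, init = init)
    rss <- max(R2 - fits[[i]]$d^2, .Machine$double.xmin)
    crit[i] <- log(rss / nP) + grid[i] * pen
  }
  best <- which.min(crit)  # which.min takes the first = smallest degree on ties
  bic0 <- log(max(R2, .Machine$double.xmin) / nP)
  noiseGain <- (sqrt(dims[1]) + sqrt(dims[2]))^2 / nP
  flat <- (bic0 - crit[best]) < noiseGain
  list(criterion = crit, degree = grid[best], fit = fits[[best]], flat = flat)
}

#' Tune the degree of sparsity by BIC
#'
#' For each of \code{K} sequentially deflated factors, fits a sparse rank-1
#' triplet at every candidate degree and scores it with the rank-1 residual
#' BIC \eqn{\log(RSS/(nP)) + k \log(nP)/(nP)}; the selected degree is the
#' smallest minimizer. A factor whose best candidate does not improve
#' materially on the unpenalized null fit is flagged (and warned about) as
#' having a flat criterion curve — typical for pure-noise data.
#'
#' @param X numeric matrix, \code{ExtendedMatrix}, or \code{ChunkedMatrix}.
#' @param alpha elastic-net mixing weight in (0, 1].
#' @param candidateDegrees integer grid of nonzero counts; default 20
#'   log-spaced values from 1 to P.
#' @param K number of factors to tune sequentially.
#' @param tol,maxIter convergence controls for the inner iteration.
#' @return A \code{\link{TuningResult-class}}.
#' @examples
#' u <- rnorm(60); v <- c(rep(2, 4), rep(0, 26))
#' X <- tcrossprod(u, v) + matrix(rnorm(60 * 30), 60, 30)
#' selectedDegree(tuneDegree(X, candidateDegrees = 2:10))
#' @export
tuneDegree <- function(X, alpha = 1, candidateDegrees = NULL, K = 1L,
                       tol = 1e-6, maxIter = 1000L) {
  X <- .coerceOperand(X)
  dims <- dim(X)
  P <- dims[2]
  if (is.null(candidateDegrees)) candidateDegrees <- .defaultDegreeGrid(P)
  grid <- .checkDegreeGrid(candidateDegrees, P)
  if (alpha <= 0 || alpha > 1)
    stop("'alpha' must lie in (0, 1] for degree tuning")
  K <- as.integer(K)
  defl <- list(U = matrix(0, dims[1], 0), d = numeric(0),
               V = matrix(0, P, 0))
  R2 <- .opFnorm2(X)
  nP <- as.numeric(dims[1]) * as.numeric(P)
  crit <- matrix(NA_real_, K, length(grid))
  selDeg <- integer(K); flat <- logical(K)
  for (k in seq_len(K)) {
    tuned <- .tuneFactor(X, defl, alpha, grid, R2, nP, tol, maxIter)
    crit[k, ] <- tuned$criterion
    selDeg[k] <- tuned$degree
    flat[k] <- tuned$flat
    defl$U <- cbind(defl$U, tuned$fit$u)
    defl$d <- c(defl$d, tuned$fit$d)
    defl$V <- cbind(defl$V, tuned$fit$v)
    R2 <- max(R2 - tuned$fit$d^2, 0)
  }
  out <- new("TuningResult", candidateDegrees = grid, criterionValues = crit,
             selectedDegree = selDeg, criterionName = "BIC",
             flatCurve = flat)
  if (any(flat))
    warning(sprintf(
      "flat criterion curve for factor(s) %s: no degree improves materially on the null fit",
      paste(which(flat), collapse = ", ")))
  out
}
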