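# Core sparse-SVD machinery: alternating elastic-net-thresholded power
# iteration for one factor, implicit deflation for K factors.

# One sparse factor of the residual operator (A minus the deflation set).
# Initialization is the leading dense singular pair of that residual; the
# dense pair is returned alongside the sparse one.
.rank1 <- function(A, defl, penalty, tol, maxIter, trace = FALSE,
                   init = NULL, startV = NULL) {
  if (is.null(init)) init <- .lanczosSVD(A, k = 1L, defl = defl, v0 = startV)
  u <- init$u[, 1]
  v <- init$v[, 1]
  p <- length(v)
  degree <- if (!is.na(penalty@degree)) as.integer(penalty@degree) else NULL
  if (!is.null(degree) && degree > p)
    stop(sprintf("'degree' (%d) exceeds the number of features (%d)", degree, p))
  alpha <- penalty@alpha
  lam <- penalty@lam
  iter <- 0L
  converged <- FALSE
  zeroed <- FALSE
  history <- if (trace) list() else NULL
  while (iter < maxIter) {
    iter <- iter + 1L
    w <- .resRmatvec(A, u, defl)
    vn <- if (!is.null(degree)) degreeThreshold(w, degree, alpha)
          else enThreshold(w, lam, alpha)
    nv <- sqrt(sum(vn^2))
    if (trace)  # iterate pair (u, unnormalized thresholded loadings)
      history[[iter]] <- list(u = u, vtilde = vn)
    if (nv == 0) {  # penalty removed every loading
      v <- vn
      zeroed <- TRUE
      converged <- TRUE
      break
    }
    vn <- vn / nv
    rel <- sqrt(sum((vn - v)^2))
    v <- vn
    z <- .resMatvec(A, v, defl)
    u <- z / sqrt(sum(z^2))
    if (rel < tol) {
      converged <- TRUE
      break
    }
  }
  d <- if (zeroed) 0 else sum(u * .resMatvec(A, v, defl))
  if (zeroed)
    warning("penalty zeroed out every loading; factor returned with d = 0")
  if (!converged)
    warning(sprintf("sparse factor did not converge in %d iterations", maxIter))
  list(u = u, d = d, v = v, converged = converged, iter = iter,
       dense = list(u = init$u[, 1], d = init$d[1], v = init$v[, 1]),
       history = history)
}

#' Rank-1 sparse singular triplet
#'
#' Extracts the leading sparse singular triplet of a matrix by alternating
#' iteration: the feature side is repeatedly formed as \eqn{X'u}, passed
#' through the elastic-net threshold (at fixed magnitude \code{lam} or at a
#' magnitude chosen to keep \code{degree} loadings nonzero), and
#' renormalized, while the sample side is the normalized image \eqn{Xv}.
#' Iteration starts from the leading dense singular pair and stops when the
#' relative change in \eqn{v} falls below \code{tol}. With \code{lam = 0}
#' the fixed point is the dense leading triplet itself.
#'
#' @param X numeric matrix, \code{ExtendedMatrix}, or \code{ChunkedMatrix}.
#' @param penalty a \code{\link{PenaltySpec}}.
#' @param tol relative L2 change in \eqn{v} declaring convergence.
#' @param maxIter iteration cap; non-convergence returns the current triplet
#'   with \code{converged = FALSE} and a warning.
#' @param trace when \code{TRUE}, record the iterates in \code{history}: per
#'   iteration, the sample vector \code{u} entering the loading update and
#'   the unnormalized thresholded loadings \code{vtilde}. For a fixed
#'   penalty magnitude the alternating updates are exact coordinate
#'   minimizers, so the penalized criterion
#'   \eqn{\|X - u\tilde v'\|_F^2 + 2\lambda(\alpha\|\tilde v\|_1 +
#'   (1-\alpha)\|\tilde v\|_2^2/2)} is non-increasing along this sequence.
#'   (Degree-targeted runs re-estimate \eqn{\lambda} each iteration and
#'   carry no single objective.)
#' @return A list with \code{u} (unit sample vector), \code{d} (singular
#'   value), \code{v} (unit, possibly sparse feature vector),
#'   \code{converged}, \code{iter}, \code{dense} (the initializing dense
#'   triplet), and optionally \code{history}.
#' @examples
#' u0 <- rnorm(30); v0 <- c(rep(1, 5), rep(0, 45))
#' X <- 10 * tcrossprod(u0 / sqrt(sum(u0^2)), v0 / sqrt(5))
#' fit <- rank1SSVD(X, PenaltySpec(alpha = 1, degree = 5))
#' which(fit$v != 0)
#' @export
rank1SSVD <- function(X, penalty, tol = 1e-6, maxIter = 1000L,
                      trace = FALSE) {
  X <- .coerceOperand(X)
  stopifnot(is(penalty, "PenaltySpec"))
  validObject(penalty)
  fit <- .rank1(X, defl = NULL, penalty = penalty, tol = tol,
                maxIter = maxIter, trace = trace)
  sf <- .signFix(cbind(fit$u), cbind(fit$v))
  fit$u <- sf$u[, 1]
  fit$v <- sf$v[, 1]
  fit
}

#' Remove a rank-1 component
#'
#' Returns \eqn{X - d\,u v'}. Sequential factor extraction deflates the
#' matrix by each extracted triplet before computing the next. (Inside
#' \code{\link{omicSSVD}} deflation is applied implicitly so chunked
#' matrices are never materialized; this function is the explicit in-memory
#' form.)
#'
#' @param X numeric matrix (or \code{ExtendedMatrix}, returned as a plain
#'   matrix).
#' @param u,v unit-norm singular vectors.
#' @param d singular value.
#' @return The deflated matrix.
#' @export
deflate <- function(X, u, d, v) {
  X <- .coerceOperand(X)
  if (is(X, "ChunkedMatrix"))
    stop("deflate() materializes its result; chunked matrices are deflated implicitly inside omicSSVD()")
  if (is(X, "ExtendedMatrix")) X <- X@values
  if (abs(sum(u^2) - 1) > 1e-6 || abs(sum(v^2) - 1) > 1e-6)
    stop("'u' and 'v' must have unit Euclidean norm")
  X - d * tcrossprod(u, v)
}

#' Sparse singular value decomposition of an integrated matrix
#'
#' The package's main decomposition. K factors are extracted sequentially:
#' each factor is initialized at the leading dense singular pair of the
#' running residual, sparsified by elastic-net thresholding of the feature
#' loadings (\code{\link{rank1SSVD}}), and deflated before the next factor
#' is extracted. With \code{penalty = "auto"} the number of nonzero
#' loadings of every factor is tuned by BIC over a candidate degree grid
#' (see \code{\link{tuneDegree}}). Both the sparse factors and the dense
#' initializing factors are returned; with \code{lam = 0} the two coincide
#' with the ordinary truncated SVD.
#'
#' @param X numeric matrix, \code{\link{ExtendedMatrix-class}}, or
#'   \code{\link{ChunkedMatrix-class}}.
#' @param K number of latent factors.
#' @param penalty a \code{\link{PenaltySpec}}, or \code{"auto"} for
#'   per-factor degree tuning.
#' @param alpha elastic-net mixing weight used when \code{penalty = "auto"}.
#' @param candidateDegrees integer grid for tuning; default 20 log-spaced
#'   values from 1 to P.
#' @param tol convergence tolerance (relative L2 change in loadings).
#' @param maxIter per-factor iteration cap.
#' @return An \code{\link{SvdFactors-class}}; when tuned, its
#'   \code{tuning} slot holds the \code{\link{TuningResult-class}}.
#' @examples
#' X <- matrix(rnorm(50 * 40), 50, 40)
#' fit <- omicSSVD(X, K = 2, penalty = PenaltySpec(alpha = 1, degree = 5))
#' nnzLoadings(fit)
#' @export
omicSSVD <- function(X, K = 2L, penalty = PenaltySpec(alpha = 1, lam = 0),
                     alpha = 1, candidateDegrees = NULL,
                     tol = 1e-6, maxIter = 1000L) {
  X <- .coerceOperand(X)
  dims <- dim(X)
  n <- dims[1]; P <- dims[2]
  if (!is.numeric(K) || length(K) != 1L || K < 1 || K > min(dims) ||
      K != round(K))
    stop(sprintf("'K' must be an integer in [1, %d]", min(dims)))
  K <- as.integer(K)
  auto <- identical(penalty, "auto")
  if (!auto) {
    stopifnot(is(penalty, "PenaltySpec"))
    validObject(penalty)
    if (!is.na(penalty@degree) && penalty@degree > P)
      stop(sprintf("'degree' (%d) exceeds the number of features (%d)",
                   as.integer(penalty@degree), P))
  } else {
    if (is.null(candidateDegrees)) candidateDegrees <- .defaultDegreeGrid(P)
    candidateDegrees <- .checkDegreeGrid(candidateDegrees, P)
    if (alpha <= 0 || alpha > 1)
      stop("'alpha' must lie in (0, 1] for degree tuning")
  }
  defl <- list(U = matrix(0, n, 0), d = numeric(0), V = matrix(0, P, 0))
  # one upfront dense run; its k-th vector warm-starts the Lanczos
  # initialization of factor k on the deflated residual
  dense0 <- .lanczosSVD(X, k = K)
  U <- matrix(0, n, K); V <- matrix(0, P, K); d <- numeric(K)
  dU <- matrix(0, n, K); dV <- matrix(0, P, K); dd <- numeric(K)
  converged <- logical(K); nIter <- integer(K)
  R2 <- .opFnorm2(X)
  nP <- as.numeric(n) * as.numeric(P)
  crit <- if (auto) matrix(NA_real_, K, length(candidateDegrees)) else NULL
  selDeg <- integer(K); flat <- logical(K)
  for (k in seq_len(K)) {
    if (auto) {
      tuned <- .tuneFactor(X, defl, alpha, candidateDegrees, R2, nP,
                           tol, maxIter, startV = dense0$v[, k])
      crit[k, ] <- tuned$criterion
      selDeg[k] <- tuned$degree
      flat[k] <- tuned$flat
      fit <- tuned$fit
    } else {
      fit <- .rank1(X, defl, penalty, tol, maxIter,
                    startV = dense0$v[, k])
    }
    U[, k] <- fit$u; d[k] <- fit$d; V[, k] <- fit$v
    dU[, k] <- fit$dense$u; dd[k] <- fit$dense$d; dV[, k] <- fit$dense$v
    converged[k] <- fit$converged; nIter[k] <- fit$iter
    defl$U <- cbind(defl$U, fit$u)
    defl$d <- c(defl$d, fit$d)
    defl$V <- cbind(defl$V, fit$v)
    R2 <- max(R2 - fit$d^2, 0)
  }
  ord <- order(-d, seq_len(K))  # descending; sequential extraction can invert
  U <- U[, ord, drop = FALSE]; d <- d[ord]; V <- V[, ord, drop = FALSE]
  dU <- dU[, ord, drop = FALSE]; dd <- dd[ord]; dV <- dV[, ord, drop = FALSE]
  converged <- converged[ord]; nIter <- nIter[ord]
  tuning <- NULL
  if (auto) {
    crit <- crit[ord, , drop = FALSE]
    selDeg <- selDeg[ord]; flat <- flat[ord]
    tuning <- new("TuningResult", candidateDegrees = candidateDegrees,
                  criterionValues = crit, selectedDegree = selDeg,
                  criterionName = "BIC", flatCurve = flat)
    if (any(flat))
      warning(sprintf(
        "flat criterion curve for factor(s) %s: no degree improves materially on the null fit",
        paste(which(flat), collapse = ", ")))
  }
  sf <- .signFix(U, V)
  sd_ <- .signFix(dU, dV)
  .newFactors(U = sf$u, d = d, V = sf$v,
              penalty = if (auto) PenaltySpec(alpha = alpha, degree = max(selDeg)) else penalty,
              converged = converged, nIter = nIter,
              denseU = sd_$u, denseD = dd, denseV = sd_$v,
              tuning = tuning, X = X)
}
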