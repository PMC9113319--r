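# Golub-Kahan-Lanczos bidiagonalization with full reorthogonalization.
# Matrix-free: needs only products with A and A'. Used both for the dense
# truncated SVD and to initialize each sparse factor from the leading dense
# triplet of the running residual. The start vector is a fixed pseudo-random
# sequence, so results are deterministic and backend-independent.

.lanczosStart <- function(p) {
  j <- seq_len(p)
  v0 <- sin(j) + 0.5 * cos(2 * j) + 1e-3
  v0 / sqrt(sum(v0^2))
}

# Returns the top-k singular triplets of the (possibly deflated) operator.
# On early Krylov breakdown (numerical rank < k) missing triplets are padded
# with zero singular values and deterministic orthonormal filler vectors.
.lanczosSVD <- function(A, k = 1L, defl = NULL, tol = 1e-11,
                        maxSteps = NULL, v0 = NULL) {
  dims <- dim(A)
  n <- dims[1]; p <- dims[2]
  m <- min(n, p)
  if (is.null(maxSteps)) maxSteps <- as.integer(min(m, max(250L, 8L * k)))
  maxSteps <- max(maxSteps, k)
  V <- matrix(0, p, maxSteps)
  U <- matrix(0, n, maxSteps)
  alph <- numeric(maxSteps)
  bet <- numeric(maxSteps)
  V[, 1] <- if (is.null(v0)) .lanczosStart(p) else v0 / sqrt(sum(v0^2))
  w <- .resMatvec(A, V[, 1], defl)
  alph[1] <- sqrt(sum(w^2))
  if (alph[1] < 1e-290 && !is.null(v0)) {
    # supplied start lies in the (numerical) null space; fall back
    V[, 1] <- .lanczosStart(p)
    w <- .resMatvec(A, V[, 1], defl)
    alph[1] <- sqrt(sum(w^2))
  }
  if (alph[1] < 1e-290) stop("matrix is numerically zero")
  U[, 1] <- w / alph[1]
  j <- 1L
  hitTol <- FALSE
  repeat {
    w <- .resRmatvec(A, U[, j], defl) - alph[j] * V[, j]
    Vj <- V[, seq_len(j), drop = FALSE]
    w <- w - Vj %*% crossprod(Vj, w)
    w <- w - Vj %*% crossprod(Vj, w)  # second pass: full reorthogonalization
    bet[j] <- sqrt(sum(w^2))
    if (j >= k) {
      B <- diag(alph[seq_len(j)], j, j)
      if (j > 1) B[cbind(seq_len(j - 1), 2:j)] <- bet[seq_len(j - 1)]
      sv <- svd(B)
      resid <- bet[j] * abs(sv$u[j, seq_len(min(k, j))])
      if (all(resid <= tol * max(sv$d[1], 1e-290)) ||
          bet[j] < 1e-13 * sv$d[1]) {
        hitTol <- TRUE
        break
      }
      if (j == maxSteps) break
    } else if (j == maxSteps || bet[j] < 1e-290) break
    V[, j + 1] <- w / bet[j]
    w <- .resMatvec(A, V[, j + 1], defl) - bet[j] * U[, j]
    Uj <- U[, seq_len(j), drop = FALSE]
    w <- w - Uj %*% crossprod(Uj, w)
    w <- w - Uj %*% crossprod(Uj, w)
    alph[j + 1] <- sqrt(sum(w^2))
    if (alph[j + 1] < 1e-290) break
    U[, j + 1] <- w / alph[j + 1]
    j <- j + 1L
  }
  # Exact Rayleigh-Ritz over the full Krylov basis: recurrence drift in the
  # bidiagonal model limits Ritz-vector accuracy near exhaustion, so the
  # final triplets are recomputed from one true block product A Qv.
  Qv <- qr.Q(qr(V[, seq_len(j), drop = FALSE]))
  W <- .resMatMult(A, Qv, defl)
  sw <- svd(W)
  kk <- min(k, j)
  Uo <- sw$u[, seq_len(kk), drop = FALSE]
  Vo <- Qv %*% sw$v[, seq_len(kk), drop = FALSE]
  do <- sw$d[seq_len(kk)]
  if (!hitTol) {
    # Krylov exhaustion/step cap: recurrence drift caps Ritz accuracy, so
    # polish the leading subspace by plain subspace iteration.
    pol <- .polishTriplets(A, defl, Vo)
    Uo <- pol$u; do <- pol$d; Vo <- pol$v
  }
  if (kk < k) {  # rank-deficient: pad zero triplets with orthonormal fillers
    Uo <- cbind(Uo, .orthoFill(Uo, k - kk))
    Vo <- cbind(Vo, .orthoFill(Vo, k - kk))
    do <- c(do, rep(0, k - kk))
  }
  list(u = Uo, d = do, v = Vo, steps = j)
}

# Subspace-iteration polish: refine a near-converged leading right subspace
# to vector-level accuracy, then Rayleigh-Ritz the result.
.polishTriplets <- function(A, defl, V0, tol = 1e-10, maxIter = 500L) {
  Vk <- qr.Q(qr(V0))
  for (t in seq_len(maxIter)) {
    Z <- .resRmatMult(A, .resMatMult(A, Vk, defl), defl)
    Vn <- qr.Q(qr(Z))
    ch <- sqrt(max(0, 1 - min(svd(crossprod(Vn, Vk))$d)^2))
    Vk <- Vn
    if (ch < tol) break
  }
  W <- .resMatMult(A, Vk, defl)
  sw <- svd(W)
  list(u = sw$u, d = sw$d, v = Vk %*% sw$v)
}

# deterministic orthonormal vectors orthogonal to the columns of M
.orthoFill <- function(M, k) {
  n <- nrow(M)
  out <- matrix(0, n, k)
  got <- 0L
  j <- 0L
  while (got < k) {
    j <- j + 1L
    if (j > n + k) stop("cannot construct orthonormal complement")
    cand <- cos(seq_len(n) * j) + 1e-3 * j
    cand <- cand - M %*% crossprod(M, cand)
    if (got > 0) {
      O <- out[, seq_len(got), drop = FALSE]
      cand <- cand - O %*% crossprod(O, cand)
    }
    nc <- sqrt(sum(cand^2))
    if (nc > 1e-8) {
      out[, got + 1L] <- cand / nc
      got <- got + 1L
    }
  }
  out
}

#' Dense truncated singular value decomposition
#'
#' Computes the top-K singular triplets of an extended (or plain, or
#' chunked) matrix by Lanczos bidiagonalization with full
#' reorthogonalization. The routine is matrix-free, so chunked on-disk
#' matrices are decomposed by streaming; results agree with a full SVD
#' truncated to K up to sign.
#'
#' @param X a numeric matrix, \code{ExtendedMatrix}, or
#'   \code{ChunkedMatrix}.
#' @param K number of factors, at most \code{min(n, P)}.
#' @param tol convergence tolerance on the Lanczos residual, relative to
#'   the leading singular value.
#' @param maxSteps maximum bidiagonalization steps (default
#'   \code{min(n, P, max(250, 8 K))}).
#' @return An \code{\link{SvdFactors-class}} object with dense factors (the
#'   sparse slots simply repeat them, with \code{penalty = NULL}).
#' @examples
#' X <- matrix(rnorm(200), 10, 20)
#' f <- denseSVD(X, K = 3)
#' singularValues(f)
#' @export
denseSVD <- function(X, K, tol = 1e-11, maxSteps = NULL) {
  X <- .coerceOperand(X)
  dims <- dim(X)
  if (!is.numeric(K) || length(K) != 1L || K < 1 || K > min(dims) ||
      K != round(K))
    stop(sprintf("'K' must be an integer in [1, %d]", min(dims)))
  K <- as.integer(K)
  sv <- .lanczosSVD(X, k = K, tol = tol, maxSteps = maxSteps)
  fac <- .signFix(sv$u, sv$v)
  .newFactors(U = fac$u, d = sv$d, V = fac$v, penalty = NULL,
              converged = rep(TRUE, K), nIter = rep(sv$steps, K),
              denseU = fac$u, denseD = sv$d, denseV = fac$v, tuning = NULL,
              X = X)
}

# flip each factor so its largest-magnitude loading is positive
.signFix <- function(u, v) {
  for (k in seq_len(ncol(v))) {
    i <- which.max(abs(v[, k]))
    if (v[i, k] < 0) {
      v[, k] <- -v[, k]
      u[, k] <- -u[, k]
    }
  }
  list(u = u, v = v)
}

.newFactors <- function(U, d, V, penalty, converged, nIter,
                        denseU, denseD, denseV, tuning, X = NULL) {
  if (!is.null(X)) {
    sid <- if (is(X, "ExtendedMatrix")) rownames(X@values)
           else if (is(X, "ChunkedMatrix") && length(X@sampleIds)) X@sampleIds
           else rownames(X)
    cm <- if (is(X, "ExtendedMatrix")) X@columnMap
          else if (is(X, "ChunkedMatrix") && nrow(X@columnMap)) X@columnMap
          else NULL
    if (!is.null(sid)) rownames(U) <- rownames(denseU) <- sid
    if (!is.null(cm)) {
      rn <- paste(cm$block, cm$feature, sep = ".")
      rownames(V) <- rownames(denseV) <- rn
    } else if (is.matrix(X) && !is.null(colnames(X))) {
      rownames(V) <- rownames(denseV) <- colnames(X)
    }
  }
  colnames(U) <- colnames(V) <- colnames(denseU) <- colnames(denseV) <-
    paste0("factor", seq_along(d))
  new("SvdFactors", U = U, d = d, V = V,
      nnz = as.integer(colSums(V != 0)), penalty = penalty,
      converged = converged, nIter = as.integer(nIter),
      denseU = denseU, denseD = denseD, denseV = denseV, tuning = tuning)
}
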