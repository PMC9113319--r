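# Internal matrix-free operator layer. Every linear-algebra routine in the
# package touches the data only through these generics, so in-memory and
# chunked backends share one code path.

setGeneric(".opMatvec", function(A, v) standardGeneric(".opMatvec"))
setGeneric(".opRmatvec", function(A, u) standardGeneric(".opRmatvec"))
setGeneric(".opMatMult", function(A, V) standardGeneric(".opMatMult"))
setGeneric(".opRmatMult", function(A, U) standardGeneric(".opRmatMult"))
setGeneric(".opFnorm2", function(A) standardGeneric(".opFnorm2"))

setMethod(".opMatvec", "matrix", function(A, v) as.numeric(A %*% v))
setMethod(".opRmatvec", "matrix", function(A, u) as.numeric(crossprod(A, u)))
setMethod(".opMatMult", "matrix", function(A, V) A %*% V)
setMethod(".opRmatMult", "matrix", function(A, U) crossprod(A, U))
setMethod(".opFnorm2", "matrix", function(A) sum(A * A))

setMethod(".opMatvec", "ExtendedMatrix", function(A, v) as.numeric(A@values %*% v))
setMethod(".opRmatvec", "ExtendedMatrix", function(A, u) as.numeric(crossprod(A@values, u)))
setMethod(".opMatMult", "ExtendedMatrix", function(A, V) A@values %*% V)
setMethod(".opRmatMult", "ExtendedMatrix", function(A, U) crossprod(A@values, U))
setMethod(".opFnorm2", "ExtendedMatrix", function(A) sum(A@values^2))

# Residual products against an implicit deflation set {U, d, V}:
# R = A - U diag(d) V', applied without materializing R.
.resMatvec <- function(A, v, defl = NULL) {
  out <- .opMatvec(A, v)
  if (!is.null(defl) && length(defl$d))
    out <- out - as.numeric(defl$U %*% (defl$d * as.numeric(crossprod(defl$V, v))))
  out
}

.resRmatvec <- function(A, u, defl = NULL) {
  out <- .opRmatvec(A, u)
  if (!is.null(defl) && length(defl$d))
    out <- out - as.numeric(defl$V %*% (defl$d * as.numeric(crossprod(defl$U, u))))
  out
}

.resMatMult <- function(A, V, defl = NULL) {
  out <- .opMatMult(A, V)
  if (!is.null(defl) && length(defl$d))
    out <- out - defl$U %*% (defl$d * crossprod(defl$V, V))
  out
}

.resRmatMult <- function(A, U, defl = NULL) {
  out <- .opRmatMult(A, U)
  if (!is.null(defl) && length(defl$d))
    out <- out - defl$V %*% (defl$d * crossprod(defl$U, U))
  out
}

# run code under a fixed seed without disturbing the caller's RNG stream
.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.coerceOperand <- function(X) {
  if (is(X, "ExtendedMatrix") || is(X, "ChunkedMatrix")) return(X)
  if (is(X, "OmicBlock")) return(X@values)
  if (is.matrix(X)) {
    storage.mode(X) <- "double"
    return(X)
  }
  if (is.data.frame(X)) return(as.matrix(X))
  stop("expected a matrix, ExtendedMatrix, or ChunkedMatrix")
}
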