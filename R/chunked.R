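# File-backed chunked matrix backend. The payload is flat little-endian
# float64, written as consecutive row-chunks (each chunk column-major), with
# a JSON header <path>.json. Row chunking is used because both X v and X'u
# stream naturally over row blocks; all accumulation is in float64.

.chunkedHeaderPath <- function(path) paste0(path, ".json")

#' Write a matrix to chunked on-disk storage
#'
#' @param X numeric matrix or \code{\link{ExtendedMatrix-class}} (whose
#'   sample ids and column map are carried into the header).
#' @param path payload path; the header is written to \code{<path>.json}.
#' @param chunkRows rows per chunk (>= 1).
#' @return A \code{\link{ChunkedMatrix-class}} handle.
#' @examples
#' X <- matrix(rnorm(200), 20, 10)
#' cm <- writeChunkedMatrix(X, tempfile(fileext = ".bin"), chunkRows = 7)
#' all.equal(as.matrix(cm), X, check.attributes = FALSE)
#' @export
writeChunkedMatrix <- function(X, path, chunkRows = 256L) {
  em <- NULL
  if (is(X, "ExtendedMatrix")) {
    em <- X
    X <- X@values
  }
  if (!is.matrix(X)) stop("'X' must be a matrix or ExtendedMatrix")
  storage.mode(X) <- "double"
  chunkRows <- as.integer(chunkRows)
  if (is.na(chunkRows) || chunkRows < 1L) stop("'chunkRows' must be >= 1")
  n <- nrow(X); P <- ncol(X)
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop(sprintf("cannot open '%s' for writing: %s",
                                                   path, conditionMessage(e))))
  on.exit(close(con))
  start <- 1L
  while (start <= n) {
    end <- min(start + chunkRows - 1L, n)
    writeBin(as.vector(X[start:end, , drop = FALSE]), con, size = 8L,
             endian = "little")
    start <- end + 1L
  }
  sid <- if (!is.null(em)) rownames(em@values) else rownames(X)
  cmap <- if (!is.null(em)) em@columnMap else
    data.frame(block = character(0), feature = character(0))
  header <- list(shape = c(n, P), dtype = "float64",
                 chunk_rows = chunkRows, byte_order = "little",
                 sample_ids = if (is.null(sid)) character(0) else sid,
                 column_map = cmap)
  jsonlite::write_json(header, .chunkedHeaderPath(path), auto_unbox = TRUE,
                       digits = NA)
  new("ChunkedMatrix", path = path, dim = c(n, P), chunkRows = chunkRows,
      sampleIds = if (is.null(sid)) character(0) else sid,
      columnMap = cmap)
}

#' Open an existing chunked matrix
#'
#' @param path payload path written by \code{\link{writeChunkedMatrix}}.
#' @return A \code{\link{ChunkedMatrix-class}} handle.
#' @export
readChunkedMatrix <- function(path) {
  hp <- .chunkedHeaderPath(path)
  if (!file.exists(path) || !file.exists(hp))
    stop(sprintf("chunked matrix payload '%s' or header '%s' is missing",
                 path, hp))
  h <- jsonlite::read_json(hp, simplifyVector = TRUE)
  if (!identical(h$dtype, "float64"))
    stop(sprintf("unsupported dtype '%s'", h$dtype))
  cmap <- if (length(h$column_map)) as.data.frame(h$column_map) else
    data.frame(block = character(0), feature = character(0))
  new("ChunkedMatrix", path = path, dim = as.integer(h$shape),
      chunkRows = as.integer(h$chunk_rows),
      sampleIds = as.character(h$sample_ids), columnMap = cmap)
}

# Stream chunks through fun(chunkMatrix, rowStart). One chunk is resident at
# a time; the connection is opened once and read sequentially.
.streamChunks <- function(A, fun) {
  n <- A@dim[1]; P <- A@dim[2]; cr <- A@chunkRows
  con <- file(A@path, "rb")
  on.exit(close(con))
  start <- 1L
  while (start <= n) {
    r <- min(cr, n - start + 1L)
    vals <- readBin(con, "double", n = as.numeric(r) * P, size = 8L,
                    endian = "little")
    if (length(vals) != r * P)
      stop(sprintf("truncated chunk payload in '%s'", A@path))
    fun(matrix(vals, r, P), start)
    start <- start + r
  }
  invisible(NULL)
}

#' Streaming matrix-vector products for chunked matrices
#'
#' \code{chunkedMatvec} computes \eqn{Av}; \code{chunkedCrossprodVec}
#' computes \eqn{A'u}. Both stream the payload one chunk at a time, so peak
#' resident data is one chunk plus the result, and both agree with the
#' in-memory product up to float64 summation order.
#'
#' @param A a \code{\link{ChunkedMatrix-class}}.
#' @param v length-P vector.
#' @param u length-n vector.
#' @return A numeric vector (\eqn{Av} of length n, or \eqn{A'u} of length
#'   P).
#' @export
chunkedMatvec <- function(A, v) {
  stopifnot(is(A, "ChunkedMatrix"))
  v <- as.numeric(v)
  if (length(v) != A@dim[2])
    stop(sprintf("length of 'v' (%d) must equal ncol (%d)",
                 length(v), A@dim[2]))
  out <- numeric(A@dim[1])
  .streamChunks(A, function(chunk, start) {
    out[start:(start + nrow(chunk) - 1L)] <<- chunk %*% v
  })
  out
}

#' @rdname chunkedMatvec
#' @export
chunkedCrossprodVec <- function(A, u) {
  stopifnot(is(A, "ChunkedMatrix"))
  u <- as.numeric(u)
  if (length(u) != A@dim[1])
    stop(sprintf("length of 'u' (%d) must equal nrow (%d)",
                 length(u), A@dim[1]))
  out <- numeric(A@dim[2])
  .streamChunks(A, function(chunk, start) {
    out <<- out + as.numeric(crossprod(chunk, u[start:(start + nrow(chunk) - 1L)]))
  })
  out
}

setMethod(".opMatvec", "ChunkedMatrix", function(A, v) chunkedMatvec(A, v))
setMethod(".opMatMult", "ChunkedMatrix", function(A, V) {
  stopifnot(nrow(V) == A@dim[2])
  out <- matrix(0, A@dim[1], ncol(V))
  .streamChunks(A, function(chunk, start) {
    out[start:(start + nrow(chunk) - 1L), ] <<- chunk %*% V
  })
  out
})
setMethod(".opRmatMult", "ChunkedMatrix", function(A, U) {
  stopifnot(nrow(U) == A@dim[1])
  out <- matrix(0, A@dim[2], ncol(U))
  .streamChunks(A, function(chunk, start) {
    out <<- out + crossprod(chunk, U[start:(start + nrow(chunk) - 1L), ,
                                     drop = FALSE])
  })
  out
})
setMethod(".opRmatvec", "ChunkedMatrix", function(A, u) chunkedCrossprodVec(A, u))
setMethod(".opFnorm2", "ChunkedMatrix", function(A) {
  tot <- 0
  .streamChunks(A, function(chunk, start) tot <<- tot + sum(chunk^2))
  tot
})

#' @describeIn ChunkedMatrix-class Read the full matrix back into memory;
#'   the reassembly reproduces the written matrix bit for bit.
#' @param x a \code{ChunkedMatrix}.
#' @param ... ignored.
#' @export
setMethod("as.matrix", "ChunkedMatrix", function(x, ...) {
  out <- matrix(0, x@dim[1], x@dim[2])
  .streamChunks(x, function(chunk, start) {
    out[start:(start + nrow(chunk) - 1L), ] <<- chunk
  })
  if (length(x@sampleIds)) rownames(out) <- x@sampleIds
  if (nrow(x@columnMap))
    colnames(out) <- paste(x@columnMap$block, x@columnMap$feature, sep = ".")
  out
})
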