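#' Read one omic block from disk
#'
#' Delimited input (TSV/CSV) must carry feature ids in the header row and
#' sample ids in the first column; empty cells and \code{NA} are treated as
#' missing. MatrixMarket input (\code{.mtx}) is read with
#' \code{Matrix::readMM} and needs sidecar id files (one id per line) for
#' rows and columns.
#'
#' @param path path to the matrix file.
#' @param label block label; defaults to the file name without extension.
#' @param format \code{"auto"} (from the extension), \code{"tsv"},
#'   \code{"csv"}, or \code{"mtx"}.
#' @param rowIds,colIds paths of the sidecar id files (MatrixMarket only;
#'   default \code{<path>.rows} / \code{<path>.cols}).
#' @return An \code{\link{OmicBlock-class}}.
#' @export
readOmicBlock <- function(path, label = NULL,
                          format = c("auto", "tsv", "csv", "mtx"),
                          rowIds = NULL, colIds = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("block file not found: %s", path))
  if (is.null(label))
    label <- sub("\\.[^.]*$", "", basename(path))
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", path))
    format <- switch(ext, mtx = "mtx", csv = "csv", "tsv")
  }
  if (format == "mtx") {
    if (is.null(rowIds)) rowIds <- paste0(path, ".rows")
    if (is.null(colIds)) colIds <- paste0(path, ".cols")
    if (!file.exists(rowIds) || !file.exists(colIds))
      stop(sprintf("MatrixMarket block needs id sidecars '%s' and '%s'",
                   rowIds, colIds))
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- readLines(rowIds)
    colnames(m) <- readLines(colIds)
    return(OmicBlock(m, label))
  }
  sep <- if (format == "csv") "," else "\t"
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          na.strings = c("NA", ""), data.table = FALSE)
  ids <- as.character(dt[[1]])
  m <- as.matrix(dt[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  OmicBlock(m, label)
}

#' Read a covariate table
#'
#' First column = sample ids (checked against blocks by the caller),
#' remaining columns = covariates; character columns become factors during
#' adjustment.
#'
#' @param path TSV/CSV path.
#' @return A data.frame with sample ids as row names.
#' @export
readCovariates <- function(path) {
  if (!file.exists(path)) stop(sprintf("covariate file not found: %s", path))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          na.strings = c("NA", ""), data.table = FALSE)
  rownames(dt) <- as.character(dt[[1]])
  dt[, -1, drop = FALSE]
}

#' Serialize an extended matrix
#'
#' Writes the values as one TSV (sample ids in the first column) and the
#' provenance — column map, standardization constants, block norms — as a
#' JSON sidecar \code{<path>.json}.
#'
#' @param x an \code{\link{ExtendedMatrix-class}}.
#' @param path output TSV path.
#' @return Invisibly, the two paths written.
#' @export
writeExtendedMatrix <- function(x, path) {
  stopifnot(is(x, "ExtendedMatrix"))
  df <- data.frame(sample_id = rownames(x@values), x@values,
                   check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  side <- paste0(path, ".json")
  jsonlite::write_json(
    list(column_map = x@columnMap,
         standardization = list(center = x@centerValues,
                                scale = x@scaleValues),
         block_norms = as.list(x@blockNorms)),
    side, auto_unbox = TRUE, digits = NA)
  invisible(c(path, side))
}

#' Read back a serialized extended matrix
#'
#' @param path TSV path previously written by
#'   \code{\link{writeExtendedMatrix}} (expects \code{<path>.json} next to
#'   it).
#' @return An \code{\link{ExtendedMatrix-class}}.
#' @export
readExtendedMatrix <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(side))
    stop("extended matrix TSV or its JSON sidecar is missing")
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  v <- as.matrix(dt[, -1, drop = FALSE])
  rownames(v) <- as.character(dt[[1]])
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  norms <- unlist(meta$block_norms)
  new("ExtendedMatrix", values = v,
      columnMap = as.data.frame(meta$column_map),
      centerValues = as.numeric(meta$standardization$center),
      scaleValues = as.numeric(meta$standardization$scale),
      blockNorms = norms)
}

#' Write decomposition factors as TSV files
#'
#' Emits \code{scores.tsv} (U with sample ids), \code{loadings.tsv} (V with
#' block and feature ids), \code{factors.tsv} (singular values, nonzero
#' counts, convergence), and — when tuning was performed —
#' \code{tuning.tsv} with the criterion grid.
#'
#' @param fit an \code{\link{SvdFactors-class}}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeFactors <- function(fit, dir) {
  stopifnot(is(fit, "SvdFactors"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  p <- file.path(dir, "scores.tsv")
  data.table::fwrite(data.frame(sample_id = rownames(fit@U) %||%
                                  seq_len(nrow(fit@U)), fit@U,
                                check.names = FALSE), p, sep = "\t")
  paths <- c(paths, p)
  p <- file.path(dir, "loadings.tsv")
  data.table::fwrite(data.frame(feature_id = rownames(fit@V) %||%
                                  seq_len(nrow(fit@V)), fit@V,
                                check.names = FALSE), p, sep = "\t")
  paths <- c(paths, p)
  p <- file.path(dir, "factors.tsv")
  data.table::fwrite(data.frame(factor = seq_along(fit@d), d = fit@d,
                                nnz = fit@nnz, converged = fit@converged,
                                n_iter = fit@nIter), p, sep = "\t")
  paths <- c(paths, p)
  if (!is.null(fit@tuning)) {
    tr <- fit@tuning
    grid <- data.frame(factor = rep(seq_len(nrow(tr@criterionValues)),
                                    each = length(tr@candidateDegrees)),
                       degree = rep(tr@candidateDegrees,
                                    nrow(tr@criterionValues)),
                       criterion = as.vector(t(tr@criterionValues)))
    p <- file.path(dir, "tuning.tsv")
    data.table::fwrite(grid, p, sep = "\t")
    paths <- c(paths, p)
  }
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
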