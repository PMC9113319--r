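#' Align omic blocks to a common sample order
#'
#' All blocks must cover the same set of samples; every block is reordered
#' to the sample order of the first. A mismatch in sample sets is an error
#' that reports the offending ids.
#'
#' @param blocks list of \code{\link{OmicBlock-class}} objects (or named
#'   matrices with sample row names, which are wrapped).
#' @return A list of \code{OmicBlock}s sharing one row order.
#' @export
alignBlocks <- function(blocks) {
  blocks <- .asBlockList(blocks)
  ref <- sampleIds(blocks[[1]])
  lapply(blocks, function(b) {
    ids <- sampleIds(b)
    extra <- setdiff(ids, ref)
    missing <- setdiff(ref, ids)
    if (length(extra) || length(missing))
      stop(sprintf(
        "sample ids of block '%s' do not match block '%s': missing {%s}, unexpected {%s}",
        blockLabel(b), blockLabel(blocks[[1]]),
        paste(missing, collapse = ", "), paste(extra, collapse = ", ")))
    idx <- match(ref, ids)
    new("OmicBlock", values = b@values[idx, , drop = FALSE],
        label = b@label,
        missingMask = b@missingMask[idx, , drop = FALSE])
  })
}

.asBlockList <- function(blocks) {
  if (is(blocks, "OmicBlock")) return(list(blocks))
  if (!is.list(blocks) || length(blocks) < 1L)
    stop("'blocks' must be a nonempty list")
  labs <- names(blocks)
  out <- lapply(seq_along(blocks), function(i) {
    b <- blocks[[i]]
    if (is(b, "OmicBlock")) return(b)
    lab <- if (!is.null(labs) && nzchar(labs[i])) labs[i] else paste0("block", i)
    OmicBlock(b, lab)
  })
  if (anyDuplicated(vapply(out, blockLabel, character(1))))
    stop("block labels must be unique")
  out
}

#' Mean imputation of missing entries
#'
#' Replaces every missing entry by the mean of its column over the observed
#' entries. The missing mask is retained on the result for provenance. A
#' column with no observed value cannot be imputed and raises an error
#' naming the feature.
#'
#' @param block an \code{\link{OmicBlock-class}}.
#' @return An \code{OmicBlock} with no missing values.
#' @examples
#' m <- matrix(c(1, NA, 3, 4, 5, 6), 3, 2,
#'             dimnames = list(paste0("s", 1:3), c("f1", "f2")))
#' as.matrix(imputeMeans(OmicBlock(m, "x")))
#' @export
imputeMeans <- function(block) {
  stopifnot(is(block, "OmicBlock"))
  v <- block@values
  allMissing <- colSums(!is.na(v)) == 0L
  if (any(allMissing))
    stop(sprintf("block '%s': column(s) entirely missing, cannot impute: %s",
                 block@label,
                 paste(colnames(v)[allMissing], collapse = ", ")))
  if (anyNA(v)) {
    mu <- colMeans(v, na.rm = TRUE)
    idx <- which(is.na(v), arr.ind = TRUE)
    v[idx] <- mu[idx[, 2]]
  }
  new("OmicBlock", values = v, label = block@label,
      missingMask = block@missingMask)
}

#' Residualize features on covariates
#'
#' Removes confounder main effects by regressing every feature column on an
#' intercept plus the supplied covariates and returning the least-squares
#' residuals, which are exactly orthogonal to every covariate column.
#' Categorical covariates are expanded to treatment-coded indicators with
#' the first level dropped.
#'
#' @param values n x p numeric matrix (an \code{OmicBlock} is accepted and
#'   returned as one).
#' @param covariates data.frame, matrix, or vector of covariates in the same
#'   sample order as \code{values}. Missing covariate values are an error.
#' @return Residual matrix (or \code{OmicBlock}) of the same shape.
#' @export
adjustCovariates <- function(values, covariates) {
  isBlock <- is(values, "OmicBlock")
  v <- if (isBlock) values@values else .coerceOperand(values)
  D <- .covariateDesign(covariates, nrow(v))
  qrD <- qr(D)
  if (qrD$rank < ncol(D))
    stop("covariate design is rank deficient after adding an intercept; remove collinear covariates")
  res <- qr.resid(qrD, v)
  dimnames(res) <- dimnames(v)
  if (isBlock)
    new("OmicBlock", values = res, label = values@label,
        missingMask = values@missingMask)
  else res
}

# intercept + treatment-coded covariate design (internal)
.covariateDesign <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(1, n, 1))
  if (is.vector(covariates) && !is.list(covariates))
    covariates <- data.frame(covariate = covariates)
  if (is.matrix(covariates)) covariates <- as.data.frame(covariates)
  if (!is.data.frame(covariates)) stop("'covariates' must be a data frame, matrix, or vector")
  if (ncol(covariates) == 0L) return(matrix(1, n, 1))
  if (nrow(covariates) != n)
    stop(sprintf("covariates have %d rows but the data have %d samples",
                 nrow(covariates), n))
  if (anyNA(covariates))
    stop("covariates contain missing values; impute or drop them explicitly before adjustment")
  covariates[] <- lapply(covariates, function(x) if (is.character(x)) factor(x) else x)
  stats::model.matrix(~ ., data = covariates)
}

#' Standardize blocks and assemble the extended matrix
#'
#' Centers every column to mean 0, scales it to unit sample standard
#' deviation (divisor n - 1), divides each standardized block by its
#' Frobenius norm so every block contributes equal total variance, and
#' concatenates the blocks column-wise. Constant columns are set to zero
#' (with a warning) rather than dropped, so the column map stays aligned to
#' the input feature ids. All constants are stored for
#' \code{\link{inverseTransform}}.
#'
#' @param blocks list of aligned, fully observed \code{OmicBlock}s.
#' @return An \code{\link{ExtendedMatrix-class}}.
#' @export
standardizeBlocks <- function(blocks) {
  blocks <- .asBlockList(blocks)
  ref <- sampleIds(blocks[[1]])
  pieces <- vector("list", length(blocks))
  centers <- scales <- numeric(0)
  norms <- numeric(length(blocks))
  names(norms) <- vapply(blocks, blockLabel, character(1))
  maps <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    if (!identical(sampleIds(b), ref))
      stop("blocks are not aligned; call alignBlocks() first")
    v <- b@values
    if (anyNA(v))
      stop(sprintf("block '%s' still contains missing values; call imputeMeans() first",
                   blockLabel(b)))
    mu <- colMeans(v)
    sdv <- apply(v, 2, stats::sd)
    const <- sdv == 0 | is.na(sdv)
    if (any(const)) {
      warning(sprintf("block '%s': %d constant column(s) set to zero: %s",
                      blockLabel(b), sum(const),
                      paste(utils::head(colnames(v)[const], 5), collapse = ", ")))
      sdv[const] <- 1
    }
    z <- sweep(sweep(v, 2, mu, "-"), 2, sdv, "/")
    fn <- sqrt(sum(z^2))
    if (fn == 0) {
      warning(sprintf("block '%s' is entirely constant; kept as zeros", blockLabel(b)))
      fn <- 1
    }
    pieces[[i]] <- z / fn
    centers <- c(centers, mu)
    scales <- c(scales, sdv)
    norms[i] <- fn
    maps[[i]] <- data.frame(block = blockLabel(b), feature = colnames(v),
                            stringsAsFactors = FALSE)
  }
  values <- do.call(cbind, pieces)
  cm <- do.call(rbind, maps)
  rownames(cm) <- NULL
  colnames(values) <- paste(cm$block, cm$feature, sep = ".")
  rownames(values) <- ref
  new("ExtendedMatrix", values = values, columnMap = cm,
      centerValues = unname(centers), scaleValues = unname(scales),
      blockNorms = norms)
}

#' Build an extended matrix from raw blocks
#'
#' Full preprocessing chain: align the blocks to a common sample order,
#' mean-impute missing entries, optionally residualize each feature on the
#' covariates, then standardize per column and normalize per block into one
#' extended matrix. Covariate adjustment happens on the original scale,
#' before standardization.
#'
#' @param blocks list of \code{OmicBlock}s or named numeric matrices.
#' @param covariates optional covariate table (same samples, any order is
#'   NOT resolved — rows must follow the first block's order after
#'   alignment).
#' @return An \code{\link{ExtendedMatrix-class}}.
#' @examples
#' rna <- matrix(rnorm(40), 8, 5,
#'               dimnames = list(paste0("s", 1:8), paste0("g", 1:5)))
#' prot <- matrix(rnorm(24), 8, 3,
#'                dimnames = list(paste0("s", 1:8), paste0("p", 1:3)))
#' em <- buildExtendedMatrix(list(rna = rna, protein = prot))
#' blockNorms(em)
#' @export
buildExtendedMatrix <- function(blocks, covariates = NULL) {
  blocks <- alignBlocks(blocks)
  blocks <- lapply(blocks, imputeMeans)
  if (!is.null(covariates))
    blocks <- lapply(blocks, adjustCovariates, covariates = covariates)
  standardizeBlocks(blocks)
}

#' Invert standardization and block normalization
#'
#' Maps an extended matrix back to the per-block matrices on their original
#' scale (multiplying out the block norm and column scale, adding back the
#' column mean). Imputation and covariate adjustment are not inverted.
#'
#' @param x an \code{\link{ExtendedMatrix-class}}.
#' @return A named list of numeric matrices, one per block.
#' @export
inverseTransform <- function(x) {
  stopifnot(is(x, "ExtendedMatrix"))
  cm <- x@columnMap
  out <- list()
  for (lab in unique(cm$block)) {
    idx <- which(cm$block == lab)
    v <- x@values[, idx, drop = FALSE] * x@blockNorms[[lab]]
    v <- sweep(sweep(v, 2, x@scaleValues[idx], "*"), 2, x@centerValues[idx], "+")
    colnames(v) <- cm$feature[idx]
    out[[lab]] <- v
  }
  out
}
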