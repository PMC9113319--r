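#' Elastic-net penalty specification
#'
#' Describes how feature loadings are penalized: the mixing weight
#' \code{alpha} interpolates between the lasso (\code{alpha = 1}, exact
#' zeros) and the ridge (\code{alpha = 0}, shrinkage only), while the
#' penalty strength is given either as a magnitude \code{lam} or as a
#' target \code{degree} of sparsity (number of loadings kept nonzero).
#' Exactly one of \code{lam} and \code{degree} must be set.
#'
#' @slot alpha numeric mixing weight in [0, 1].
#' @slot lam nonnegative penalty magnitude, or \code{NA} when
#'   degree-parametrized.
#' @slot degree target count of nonzero loadings, or \code{NA} when
#'   lam-parametrized.
#' @export
setClass("PenaltySpec",
  representation(alpha = "numeric", lam = "numeric", degree = "numeric"),
  prototype(alpha = 1, lam = NA_real_, degree = NA_real_))

setValidity("PenaltySpec", function(object) {
  msg <- character()
  a <- object@alpha
  if (length(a) != 1L || is.na(a) || a < 0 || a > 1)
    msg <- c(msg, "'alpha' must be a single value in [0, 1]")
  hasLam <- !is.na(object@lam)
  hasDeg <- !is.na(object@degree)
  if (hasLam == hasDeg)
    msg <- c(msg, "exactly one of 'lam' and 'degree' must be set")
  if (hasLam && object@lam < 0)
    msg <- c(msg, "'lam' must be nonnegative")
  if (hasDeg) {
    if (object@degree < 1 || object@degree != round(object@degree))
      msg <- c(msg, "'degree' must be a positive integer")
    if (length(a) == 1L && !is.na(a) && a == 0)
      msg <- c(msg, "degree-parametrized penalty requires alpha > 0 (ridge cannot produce exact zeros)")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn PenaltySpec-class Constructor. Supply either \code{lam} or
#'   \code{degree} (not both).
#' @param alpha elastic-net mixing weight in [0, 1]; 1 = lasso, 0 = ridge.
#' @param lam nonnegative penalty magnitude.
#' @param degree integer count of loadings to keep nonzero.
#' @return A \code{PenaltySpec} object.
#' @examples
#' PenaltySpec(alpha = 1, lam = 0.5)
#' PenaltySpec(alpha = 0.5, degree = 10)
#' @export
PenaltySpec <- function(alpha = 1, lam = NULL, degree = NULL) {
  new("PenaltySpec", alpha = as.numeric(alpha),
      lam = if (is.null(lam)) NA_real_ else as.numeric(lam),
      degree = if (is.null(degree)) NA_real_ else as.numeric(degree))
}

setMethod("show", "PenaltySpec", function(object) {
  mode <- if (!is.na(object@degree)) sprintf("degree = %d", as.integer(object@degree))
          else sprintf("lam = %g", object@lam)
  cat(sprintf("PenaltySpec(alpha = %g, %s)\n", object@alpha, mode))
})

#' One omic data block
#'
#' A samples-by-features numeric matrix from a single omic layer (e.g. gene
#' expression, methylation, copy number), with sample ids as row names,
#' feature ids as column names, a block label, and a mask recording which
#' entries were missing on input. The mask is retained through mean
#' imputation for provenance.
#'
#' @slot values numeric matrix, samples in rows, features in columns.
#' @slot label character block label.
#' @slot missingMask logical matrix, \code{TRUE} where the input was missing.
#' @export
setClass("OmicBlock",
  representation(values = "matrix", label = "character",
                 missingMask = "matrix"))

setValidity("OmicBlock", function(object) {
  msg <- character()
  v <- object@values
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "'values' must have sample ids as rownames and feature ids as colnames")
  if (!is.null(rownames(v)) && anyDuplicated(rownames(v)))
    msg <- c(msg, "sample ids must be unique")
  if (!is.null(colnames(v)) && anyDuplicated(colnames(v)))
    msg <- c(msg, "feature ids must be unique within a block")
  if (!identical(dim(object@missingMask), dim(v)))
    msg <- c(msg, "'missingMask' must have the same shape as 'values'")
  if (length(object@label) != 1L || is.na(object@label) || !nzchar(object@label))
    msg <- c(msg, "'label' must be a nonempty string")
  if (length(msg)) msg else TRUE
})

#' @describeIn OmicBlock-class Constructor. The missing mask is derived from
#'   \code{NA} entries of \code{values}.
#' @param values numeric matrix with row and column names.
#' @param label block label (e.g. \code{"rna"}, \code{"methylation"}).
#' @return An \code{OmicBlock}.
#' @examples
#' m <- matrix(rnorm(20), 4, 5,
#'             dimnames = list(paste0("s", 1:4), paste0("g", 1:5)))
#' OmicBlock(m, "rna")
#' @export
OmicBlock <- function(values, label) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  new("OmicBlock", values = values, label = as.character(label),
      missingMask = is.na(values))
}

setMethod("show", "OmicBlock", function(object) {
  cat(sprintf("OmicBlock '%s': %d samples x %d features (%d missing entries)\n",
              object@label, nrow(object@values), ncol(object@values),
              sum(object@missingMask)))
})

#' @rdname blockLabel
#' @export
setMethod("blockLabel", "OmicBlock", function(x) x@label)
#' @rdname sampleIds
#' @export
setMethod("sampleIds", "OmicBlock", function(x) rownames(x@values))
#' @rdname featureIds
#' @export
setMethod("featureIds", "OmicBlock", function(x) colnames(x@values))

#' @describeIn OmicBlock-class Numeric values of the block.
#' @param x an \code{OmicBlock}.
#' @param ... ignored.
#' @export
setMethod("as.matrix", "OmicBlock", function(x, ...) x@values)

setMethod("dim", "OmicBlock", function(x) dim(x@values))

#' Standardized extended matrix
#'
#' Column-wise concatenation of preprocessed omic blocks sharing one sample
#' order. Every column is centered and scaled, every block divided by its
#' Frobenius norm so each block contributes equal total variance, and the
#' provenance of each column — which block, which feature — is kept in
#' \code{columnMap}. Centering/scaling constants and block norms are stored
#' so the transform can be inverted.
#'
#' @slot values n x P numeric matrix.
#' @slot columnMap data.frame with columns \code{block}, \code{feature}.
#' @slot centerValues per-column means removed.
#' @slot scaleValues per-column standard deviations divided out (1 where a
#'   column was constant).
#' @slot blockNorms named per-block Frobenius norms divided out.
#' @export
setClass("ExtendedMatrix",
  representation(values = "matrix", columnMap = "data.frame",
                 centerValues = "numeric", scaleValues = "numeric",
                 blockNorms = "numeric"))

setValidity("ExtendedMatrix", function(object) {
  msg <- character()
  P <- ncol(object@values)
  if (nrow(object@columnMap) != P)
    msg <- c(msg, "'columnMap' must have one row per column")
  if (!all(c("block", "feature") %in% names(object@columnMap)))
    msg <- c(msg, "'columnMap' needs columns 'block' and 'feature'")
  if (length(object@centerValues) != P || length(object@scaleValues) != P)
    msg <- c(msg, "standardization parameters must have one entry per column")
  if (is.null(rownames(object@values)))
    msg <- c(msg, "'values' must carry sample ids as rownames")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ExtendedMatrix", function(object) {
  tab <- table(object@columnMap$block)
  cat(sprintf("ExtendedMatrix: %d samples x %d features from %d block(s)\n",
              nrow(object@values), ncol(object@values), length(tab)))
  cat("  ", paste(sprintf("%s(%d)", names(tab), as.integer(tab)),
                  collapse = ", "), "\n")
})

#' @rdname columnMap
#' @export
setMethod("columnMap", "ExtendedMatrix", function(x) x@columnMap)
#' @rdname blockNorms
#' @export
setMethod("blockNorms", "ExtendedMatrix", function(x) x@blockNorms)
#' @rdname sampleIds
#' @export
setMethod("sampleIds", "ExtendedMatrix", function(x) rownames(x@values))

#' @describeIn ExtendedMatrix-class The underlying numeric matrix.
#' @param x an \code{ExtendedMatrix}.
#' @param ... ignored.
#' @export
setMethod("as.matrix", "ExtendedMatrix", function(x, ...) x@values)

setMethod("dim", "ExtendedMatrix", function(x) dim(x@values))

#' Result of automatic sparsity-degree tuning
#'
#' Stores, per factor, the information-criterion value at every candidate
#' degree of sparsity and the degree that minimized it (smallest minimizer
#' on ties). A factor whose criterion curve shows no material improvement
#' over the unpenalized null fit is flagged in \code{flatCurve}.
#'
#' @slot candidateDegrees integer grid of candidate nonzero counts.
#' @slot criterionValues factors x candidates matrix of criterion values.
#' @slot selectedDegree integer, selected degree per factor.
#' @slot criterionName name of the criterion ("BIC").
#' @slot flatCurve logical per factor.
#' @export
setClass("TuningResult",
  representation(candidateDegrees = "integer", criterionValues = "matrix",
                 selectedDegree = "integer", criterionName = "character",
                 flatCurve = "logical"))

setValidity("TuningResult", function(object) {
  msg <- character()
  if (ncol(object@criterionValues) != length(object@candidateDegrees))
    msg <- c(msg, "'criterionValues' must have one column per candidate degree")
  if (length(object@selectedDegree) != nrow(object@criterionValues))
    msg <- c(msg, "'selectedDegree' must have one entry per factor")
  if (!all(object@selectedDegree %in% object@candidateDegrees))
    msg <- c(msg, "every selected degree must come from the candidate grid")
  for (f in seq_along(object@selectedDegree)) {
    vals <- object@criterionValues[f, ]
    sel <- object@selectedDegree[f]
    if (is.finite(min(vals)) &&
        vals[match(sel, object@candidateDegrees)] > min(vals) + 1e-12)
      msg <- c(msg, sprintf("selected degree of factor %d does not minimize its criterion", f))
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "TuningResult", function(object) {
  cat(sprintf("TuningResult (%s): %d factor(s), %d candidate degrees\n",
              object@criterionName, nrow(object@criterionValues),
              length(object@candidateDegrees)))
  cat("  selected:", paste(object@selectedDegree, collapse = ", "), "\n")
  if (any(object@flatCurve))
    cat("  flat criterion curve for factor(s):",
        paste(which(object@flatCurve), collapse = ", "), "\n")
})

#' @rdname selectedDegree
#' @export
setMethod("selectedDegree", "TuningResult", function(x) x@selectedDegree)

#' Rank-K decomposition of an extended matrix
#'
#' Holds the sparse factors — sample scores \code{U}, singular values
#' \code{d}, feature loadings \code{V} with \code{nnz} nonzeros per factor —
#' together with the dense factors from which each sparse factor was
#' initialized, per-factor convergence flags and iteration counts, the
#' penalty used, and (when the degree was tuned automatically) the
#' \code{TuningResult}.
#'
#' @slot U n x K matrix of sample scores (unit-norm columns).
#' @slot d length-K singular values, descending.
#' @slot V P x K matrix of feature loadings, sparse when penalized.
#' @slot nnz integer nonzero count per factor.
#' @slot penalty the \code{PenaltySpec} applied (\code{NULL} for dense).
#' @slot converged logical per factor.
#' @slot nIter iteration count per factor.
#' @slot denseU,denseD,denseV dense factors used as initializations.
#' @slot tuning a \code{TuningResult} or \code{NULL}.
#' @export
setClass("SvdFactors",
  representation(U = "matrix", d = "numeric", V = "matrix", nnz = "integer",
                 penalty = "ANY", converged = "logical", nIter = "integer",
                 denseU = "matrix", denseD = "numeric", denseV = "matrix",
                 tuning = "ANY"))

setValidity("SvdFactors", function(object) {
  msg <- character()
  K <- length(object@d)
  if (ncol(object@U) != K || ncol(object@V) != K)
    msg <- c(msg, "'U' and 'V' must have one column per singular value")
  if (K > 1 && any(diff(object@d) > 1e-8 * max(object@d, 1)))
    msg <- c(msg, "'d' must be sorted in descending order")
  if (any(object@d < -1e-12))
    msg <- c(msg, "singular values must be nonnegative")
  if (!identical(object@nnz, as.integer(colSums(object@V != 0))))
    msg <- c(msg, "'nnz' must equal the per-factor count of nonzero loadings")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SvdFactors", function(object) {
  cat(sprintf("SvdFactors: %d factor(s), %d samples x %d features\n",
              length(object@d), nrow(object@U), nrow(object@V)))
  cat("  d  :", paste(signif(object@d, 5), collapse = ", "), "\n")
  cat("  nnz:", paste(object@nnz, collapse = ", "),
      sprintf(" (of %d)\n", nrow(object@V)))
  if (!is.null(object@penalty)) {
    cat("  penalty: "); show(object@penalty)
  }
  if (!all(object@converged))
    cat("  WARNING: factor(s)", paste(which(!object@converged), collapse = ", "),
        "did not converge\n")
})

#' @rdname sampleScores
#' @export
setMethod("sampleScores", "SvdFactors", function(x, ...) x@U)
#' @rdname featureLoadings
#' @export
setMethod("featureLoadings", "SvdFactors", function(x, ...) x@V)
#' @rdname singularValues
#' @export
setMethod("singularValues", "SvdFactors", function(x, ...) x@d)
#' @rdname nnzLoadings
#' @export
setMethod("nnzLoadings", "SvdFactors", function(x) x@nnz)
#' @rdname selectedDegree
#' @export
setMethod("selectedDegree", "SvdFactors", function(x) {
  if (is.null(x@tuning)) stop("no tuning was performed for this decomposition")
  x@tuning@selectedDegree
})

#' Dense factors underlying a sparse decomposition
#'
#' Each sparse factor is initialized from the leading dense singular triplet
#' of the running residual; those dense triplets are returned alongside the
#' sparse ones, matching the convention that a decomposition reports both
#' the standard and the sparse solution.
#'
#' @param x an \code{SvdFactors}.
#' @return A list with elements \code{U}, \code{d}, \code{V}.
#' @export
denseFactors <- function(x) {
  stopifnot(is(x, "SvdFactors"))
  list(U = x@denseU, d = x@denseD, V = x@denseV)
}

#' On-disk chunked matrix
#'
#' A samples-by-features numeric matrix stored on disk as row chunks (flat
#' little-endian float64 binary plus a JSON header), so decompositions can
#' stream it one chunk at a time instead of holding it in memory.
#'
#' @slot path path of the binary payload (header is \code{<path>.json}).
#' @slot dim integer (n, P).
#' @slot chunkRows rows per chunk.
#' @slot sampleIds character row ids (may be empty).
#' @slot columnMap data.frame column provenance (may be empty).
#' @export
setClass("ChunkedMatrix",
  representation(path = "character", dim = "integer", chunkRows = "integer",
                 sampleIds = "character", columnMap = "data.frame"))

setValidity("ChunkedMatrix", function(object) {
  msg <- character()
  if (length(object@dim) != 2L || any(object@dim < 1L))
    msg <- c(msg, "'dim' must be two positive integers")
  if (length(object@chunkRows) != 1L || object@chunkRows < 1L)
    msg <- c(msg, "'chunkRows' must be >= 1")
  if (!file.exists(object@path))
    msg <- c(msg, sprintf("payload '%s' does not exist", object@path))
  if (length(msg)) msg else TRUE
})

setMethod("show", "ChunkedMatrix", function(object) {
  cat(sprintf("ChunkedMatrix: %d x %d, %d rows/chunk (%d chunks)\n  %s\n",
              object@dim[1], object@dim[2], object@chunkRows,
              ceiling(object@dim[1] / object@chunkRows), object@path))
})

setMethod("dim", "ChunkedMatrix", function(x) as.integer(x@dim))
#' @rdname columnMap
#' @export
setMethod("columnMap", "ChunkedMatrix", function(x) x@columnMap)
#' @rdname sampleIds
#' @export
setMethod("sampleIds", "ChunkedMatrix", function(x) x@sampleIds)

#' Cluster analysis of latent sample scores
#'
#' @slot labels named integer cluster assignment per sample.
#' @slot k number of clusters used.
#' @slot quality named mean silhouette width per candidate k.
#' @slot chosenK the k maximizing mean silhouette (smallest on ties).
#' @export
setClass("ClusterResult",
  representation(labels = "integer", k = "integer", quality = "numeric",
                 chosenK = "integer"))

setValidity("ClusterResult", function(object) {
  msg <- character()
  if (any(object@labels < 1L) || any(object@labels > object@k))
    msg <- c(msg, "labels must lie in [1, k]")
  if (length(object@quality) && any(stats::na.omit(object@quality) < -1 - 1e-12 |
                                    stats::na.omit(object@quality) > 1 + 1e-12))
    msg <- c(msg, "silhouette values must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ClusterResult", function(object) {
  cat(sprintf("ClusterResult: %d samples in %d cluster(s)\n",
              length(object@labels), object@k))
  if (length(object@quality))
    cat("  mean silhouette by k:",
        paste(sprintf("%s=%.3f", names(object@quality), object@quality),
              collapse = ", "), "\n")
})

#' @rdname clusterLabels
#' @export
setMethod("clusterLabels", "ClusterResult", function(x) x@labels)
#' @rdname chosenK
#' @export
setMethod("chosenK", "ClusterResult", function(x) x@chosenK)

#' Feature-selection benchmark result
#'
#' Per replicate and sparsity degree: confusion counts of selected versus
#' informative features, plus sensitivity and specificity; aggregated per
#' degree in \code{summary}.
#'
#' @slot replicates data.frame with columns replicate, degree, TP, FP, TN,
#'   FN, sensitivity, specificity, seed.
#' @slot summary data.frame with per-degree means and standard deviations.
#' @slot informative list of informative-feature index sets per replicate.
#' @slot config list echoing the benchmark configuration.
#' @export
setClass("BenchmarkResult",
  representation(replicates = "data.frame", summary = "data.frame",
                 informative = "list", config = "list"))

setValidity("BenchmarkResult", function(object) {
  r <- object@replicates
  need <- c("replicate", "degree", "TP", "FP", "TN", "FN",
            "sensitivity", "specificity")
  if (!all(need %in% names(r)))
    return("replicate table is missing required columns")
  bad <- with(r, sensitivity < -1e-12 | sensitivity > 1 + 1e-12 |
                 specificity < -1e-12 | specificity > 1 + 1e-12)
  if (any(bad)) return("sensitivity and specificity must lie in [0, 1]")
  TRUE
})

setMethod("show", "BenchmarkResult", function(object) {
  cat(sprintf("BenchmarkResult: %d replicate(s) x %d degree(s), p = %d, signal fraction %.2f\n",
              length(unique(object@replicates$replicate)),
              length(unique(object@replicates$degree)),
              object@config$p, object@config$signalFraction))
  print(object@summary, digits = 3)
})

#' @rdname benchmarkSummary
#' @export
setMethod("benchmarkSummary", "BenchmarkResult", function(x) x@summary)
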