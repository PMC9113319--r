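#' @import methods
NULL

#' Sample-side latent scores
#'
#' Accessor for the left singular vectors (one column per latent factor,
#' one row per sample) of a fitted decomposition.
#'
#' @param x an object holding decomposition results.
#' @param ... further arguments for methods.
#' @return A numeric matrix of sample scores.
#' @export
setGeneric("sampleScores", function(x, ...) standardGeneric("sampleScores"))

#' Feature-side loadings
#'
#' Accessor for the right singular vectors (feature loadings, sparse when a
#' penalty was applied).
#'
#' @param x an object holding decomposition results.
#' @param ... further arguments for methods.
#' @return A numeric matrix of feature loadings.
#' @export
setGeneric("featureLoadings", function(x, ...) standardGeneric("featureLoadings"))

#' Singular values
#'
#' @param x an object holding decomposition results.
#' @param ... further arguments for methods.
#' @return A numeric vector of singular values, descending.
#' @export
setGeneric("singularValues", function(x, ...) standardGeneric("singularValues"))

#' Per-factor count of nonzero loadings
#'
#' @param x an object holding decomposition results.
#' @return An integer vector, one count per factor.
#' @export
setGeneric("nnzLoadings", function(x) standardGeneric("nnzLoadings"))

#' Column provenance of an extended matrix
#'
#' Maps every column of the extended matrix back to its originating
#' (block label, feature id) pair.
#'
#' @param x an \code{ExtendedMatrix} or \code{ChunkedMatrix}.
#' @return A \code{data.frame} with columns \code{block} and \code{feature}.
#' @export
setGeneric("columnMap", function(x) standardGeneric("columnMap"))

#' Per-block normalization constants
#'
#' @param x an \code{ExtendedMatrix}.
#' @return A named numeric vector of Frobenius norms, one per block.
#' @export
setGeneric("blockNorms", function(x) standardGeneric("blockNorms"))

#' Block label of an omic block
#'
#' @param x an \code{OmicBlock}.
#' @return A character scalar.
#' @export
setGeneric("blockLabel", function(x) standardGeneric("blockLabel"))

#' Sample identifiers
#'
#' @param x an object carrying per-sample data.
#' @return A character vector of sample ids.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' Feature identifiers
#'
#' @param x an object carrying per-feature data.
#' @return A character vector of feature ids.
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' Cluster labels
#'
#' @param x a \code{ClusterResult}.
#' @return A named integer vector of cluster assignments.
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' Selected number of clusters
#'
#' @param x a \code{ClusterResult}.
#' @return An integer scalar.
#' @export
setGeneric("chosenK", function(x) standardGeneric("chosenK"))

#' Degree selected by automatic tuning
#'
#' @param x a \code{TuningResult} or an \code{SvdFactors} carrying one.
#' @return An integer vector with the selected nonzero count per factor.
#' @export
setGeneric("selectedDegree", function(x) standardGeneric("selectedDegree"))

#' Per-degree benchmark summary
#'
#' @param x a \code{BenchmarkResult}.
#' @return A \code{data.frame} with mean and sd of sensitivity and
#'   specificity per sparsity degree.
#' @export
setGeneric("benchmarkSummary", function(x) standardGeneric("benchmarkSummary"))
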