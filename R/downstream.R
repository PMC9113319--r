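# Downstream analysis of latent sample scores: k-means clustering with
# silhouette model selection, and 2-D embedding for plotting.

.weightedScores <- function(x, d = NULL) {
  if (is(x, "SvdFactors")) {
    U <- x@U
    d <- x@d
  } else {
    U <- as.matrix(x)
    if (is.null(d)) d <- rep(1, ncol(U))
  }
  if (length(d) != ncol(U)) stop("'d' must have one entry per score column")
  sweep(U, 2, d, "*")  # variance-weighted scores U diag(d)
}

#' Cluster samples in latent score space
#'
#' Partitions the variance-weighted sample scores \eqn{U\,diag(d)} with
#' k-means (multiple seeded restarts) for every candidate number of
#' clusters, and selects the k with the largest mean silhouette width
#' (smallest k on ties). Results are deterministic given \code{seed};
#' weighting by \eqn{d} makes the partition invariant to sign flips of the
#' factors. Identical points (zero spread) yield a single-cluster result
#' with a warning rather than an error.
#'
#' @param x an \code{\link{SvdFactors-class}} or an n x K score matrix.
#' @param d singular values used as column weights (taken from \code{x}
#'   when it is an \code{SvdFactors}).
#' @param kRange candidate numbers of clusters, within [2, n - 1].
#' @param seed integer seed for the k-means restarts.
#' @param nstart random restarts per candidate k.
#' @return A \code{\link{ClusterResult-class}}.
#' @examples
#' S <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 8), 20, 2))
#' chosenK(clusterScores(S, kRange = 2:4, seed = 1))
#' @export
clusterScores <- function(x, d = NULL, kRange = 2:6, seed = 1L,
                          nstart = 20L) {
  S <- .weightedScores(x, d)
  n <- nrow(S)
  ids <- rownames(S) %||% as.character(seq_len(n))
  if (max(stats::dist(S)) == 0) {
    warning("all samples are identical in score space; reporting a single cluster")
    labels <- stats::setNames(rep(1L, n), ids)
    return(new("ClusterResult", labels = labels, k = 1L,
               quality = numeric(0), chosenK = 1L))
  }
  kRange <- sort(unique(as.integer(kRange)))
  if (any(kRange < 2L) || any(kRange > n - 1L))
    stop(sprintf("'kRange' must lie within [2, %d]", n - 1L))
  D <- stats::dist(S)
  quality <- stats::setNames(numeric(length(kRange)), kRange)
  fits <- vector("list", length(kRange))
  .withSeed(seed, {
    for (i in seq_along(kRange)) {
      fits[[i]] <- stats::kmeans(S, centers = kRange[i], nstart = nstart,
                                 iter.max = 100L)
      sil <- cluster::silhouette(fits[[i]]$cluster, D)
      quality[i] <- mean(sil[, "sil_width"])
    }
  })
  best <- which.max(quality)  # first maximum = smallest k on ties
  labels <- stats::setNames(as.integer(fits[[best]]$cluster), ids)
  new("ClusterResult", labels = labels, k = kRange[best], quality = quality,
      chosenK = kRange[best])
}

#' Two-dimensional embedding of latent scores
#'
#' \code{method = "none"} returns the first two variance-weighted score
#' columns (zero-padded if only one factor is present); \code{method =
#' "tsne"} runs the package's exact t-SNE on the weighted scores.
#' Deterministic given \code{seed}.
#'
#' @param x an \code{\link{SvdFactors-class}} or score matrix.
#' @param d column weights, as in \code{\link{clusterScores}}.
#' @param method \code{"none"} or \code{"tsne"}.
#' @param seed integer seed (t-SNE initialization).
#' @param perplexity t-SNE perplexity; default \code{min(30, (n - 1) / 3)}.
#' @return An n x 2 coordinate matrix with sample ids as row names.
#' @export
embedScores <- function(x, d = NULL, method = c("none", "tsne"), seed = 1L,
                        perplexity = NULL) {
  method <- match.arg(method)
  S <- .weightedScores(x, d)
  n <- nrow(S)
  ids <- rownames(S) %||% as.character(seq_len(n))
  if (method == "none") {
    out <- if (ncol(S) >= 2L) S[, 1:2, drop = FALSE] else cbind(S[, 1], 0)
  } else {
    if (n < 5L) stop("t-SNE embedding needs at least 5 samples")
    if (is.null(perplexity)) perplexity <- min(30, (n - 1) / 3)
    out <- .tsne(S, perplexity = perplexity, seed = seed)
  }
  dimnames(out) <- list(ids, c("dim1", "dim2"))
  out
}

#' Write cluster labels and embedding coordinates
#'
#' @param clusters a \code{\link{ClusterResult-class}}.
#' @param coords optional n x 2 coordinates from \code{\link{embedScores}}.
#' @param path output TSV path.
#' @return Invisibly, \code{path}.
#' @export
writeClusters <- function(clusters, path, coords = NULL) {
  stopifnot(is(clusters, "ClusterResult"))
  df <- data.frame(sample_id = names(clusters@labels),
                   cluster = as.integer(clusters@labels))
  if (!is.null(coords)) {
    stopifnot(nrow(coords) == nrow(df))
    df$dim1 <- coords[, 1]
    df$dim2 <- coords[, 2]
  }
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Scatter plot of samples in latent or embedded space
#'
#' Base-graphics scatter of 2-D coordinates colored by cluster; written to
#' \code{png} when \code{file} is given.
#'
#' @param coords n x 2 matrix from \code{\link{embedScores}}.
#' @param clusters optional \code{\link{ClusterResult-class}} for colors.
#' @param file optional PNG path.
#' @param ... passed to \code{plot}.
#' @return Invisibly, \code{NULL}.
#' @export
plotScores <- function(coords, clusters = NULL, file = NULL, ...) {
  col <- if (!is.null(clusters)) clusterLabels(clusters) + 1L else "grey30"
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 760, res = 130)
    on.exit(grDevices::dev.off())
  }
  plot(coords[, 1], coords[, 2], col = col, pch = 19,
       xlab = colnames(coords)[1] %||% "dim1",
       ylab = colnames(coords)[2] %||% "dim2", ...)
  invisible(NULL)
}
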