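#' Elastic-net proximal operator
#'
#' Applies the elastic-net shrinkage/selection map elementwise:
#' \deqn{out_i = sign(z_i) \max(|z_i| - \alpha \lambda, 0) / (1 + (1 - \alpha)\lambda).}
#' With \code{alpha = 1} this is plain soft-thresholding (lasso); with
#' \code{alpha = 0} it is pure ridge shrinkage, which never produces exact
#' zeros. The operator is a contraction: no entry grows in magnitude and
#' signs are preserved or zeroed.
#'
#' @param z numeric vector.
#' @param lam nonnegative penalty magnitude.
#' @param alpha mixing weight in [0, 1].
#' @return A numeric vector the same length as \code{z}.
#' @examples
#' enThreshold(3, 1, 1)    # 2: soft-threshold
#' enThreshold(3, 1, 0)    # 1.5: ridge shrinkage
#' enThreshold(-3, 2, 0.5) # -1
#' @export
enThreshold <- function(z, lam, alpha) {
  if (!is.numeric(lam) || length(lam) != 1L || is.na(lam) || lam < 0)
    stop("'lam' must be a single nonnegative value")
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0 || alpha > 1)
    stop("'alpha' must be a single value in [0, 1]")
  sign(z) * pmax(abs(z) - alpha * lam, 0) / (1 + (1 - alpha) * lam)
}

#' Degree-targeted elastic-net thresholding
#'
#' Chooses the penalty magnitude from the data so that the requested number
#' of entries survives thresholding: \code{lam* = |z|_(degree+1) / alpha},
#' the (degree+1)-th largest absolute value scaled by the mixing weight
#' (and 0 when \code{degree = length(z)}), then applies
#' \code{\link{enThreshold}} with that magnitude. Order statistics break
#' ties by smallest index, so the result is deterministic; entries exactly
#' tied with the cutoff shrink to zero, in which case fewer than
#' \code{degree} nonzeros can remain.
#'
#' @param z numeric vector.
#' @param degree integer in [1, length(z)], the target nonzero count.
#' @param alpha mixing weight in (0, 1]; \code{alpha = 0} is rejected since
#'   ridge shrinkage cannot produce exact zeros.
#' @return A numeric vector the same length as \code{z}.
#' @examples
#' degreeThreshold(c(5, 3, 1), 2, 1) # c(4, 2, 0)
#' @export
degreeThreshold <- function(z, degree, alpha) {
  p <- length(z)
  if (!is.numeric(degree) || length(degree) != 1L || is.na(degree) ||
      degree < 1 || degree > p || degree != round(degree))
    stop(sprintf("'degree' must be an integer in [1, %d]", p))
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0 || alpha > 1)
    stop("'alpha' must be a single value in [0, 1]")
  if (degree >= p) return(enThreshold(z, 0, alpha))
  if (alpha == 0)
    stop("degree-targeted thresholding requires alpha > 0 (ridge cannot zero entries)")
  ord <- order(-abs(z), seq_along(z))
  # lam* = |z|_(degree+1) / alpha; threshold at alpha * lam* = |z|_(degree+1)
  # directly so the cutoff entry is zeroed exactly
  cut <- abs(z[ord[degree + 1L]])
  sign(z) * pmax(abs(z) - cut, 0) / (1 + (1 - alpha) * cut / alpha)
}

# strength needed to keep `degree` entries of z nonzero (internal)
.degreeLambda <- function(z, degree, alpha) {
  p <- length(z)
  if (degree >= p) return(0)
  ord <- order(-abs(z), seq_along(z))
  abs(z[ord[degree + 1L]]) / alpha
}
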