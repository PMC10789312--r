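#' Gaussian similarity kernel from a distance matrix
#'
#' `K(i,j) = exp(-d(i,j)^2 / (2 sigma^2))`.  When `sigma` is not supplied it
#' is set to the mean of all pairwise training distances (the strict upper
#' triangle, excluding the zero self-distances which would bias the
#' bandwidth downward).  The chosen bandwidth is stored on the result so it
#' can be reused verbatim for test samples.
#'
#' @param D square symmetric distance matrix.
#' @param sigma positive bandwidth, or `NULL` to use the training mean.
#' @return kernel matrix with attributes `sigma` and `metric`.
#' @export
gaussian_kernel <- function(D, sigma = NULL) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  if (is.null(sigma)) sigma <- mean(D[upper.tri(D)])
  if (!is.finite(sigma) || sigma <= 0)
    stop("bandwidth sigma is ", sigma,
         ": all pairwise distances are zero (degenerate input)")
  K <- exp(-D^2 / (2 * sigma^2))
  dimnames(K) <- dimnames(D)
  attr(K, "sigma") <- sigma
  attr(K, "metric") <- attr(D, "metric")
  K
}

#' Rectangular kernel for test samples with a training bandwidth
#'
#' Applies the Gaussian transform to a test x training distance matrix
#' using the bandwidth learned on the training set, so nothing about the
#' test samples leaks into the kernel geometry.
#'
#' @param D_test_train rectangular distance matrix (test rows, training
#'   columns).
#' @param sigma positive bandwidth from the training kernel (required).
#' @return rectangular kernel matrix with attribute `sigma`.
#' @export
cross_kernel <- function(D_test_train, sigma) {
  if (missing(sigma) || is.null(sigma))
    stop("sigma from the training kernel is required")
  stopifnot(is.finite(sigma), sigma > 0)
  K <- exp(-D_test_train^2 / (2 * sigma^2))
  dimnames(K) <- dimnames(D_test_train)
  attr(K, "sigma") <- sigma
  attr(K, "metric") <- attr(D_test_train, "metric")
  K
}

#' Gaussian kernel for a single numeric covariate
#'
#' The covariate is z-scored with the training mean and standard deviation
#' (so the kernel is invariant to affine rescalings of the covariate and
#' Euclidean distances are comparable across covariates), the distance is
#' `|x_i - x_j|` on the standardized scale, and the bandwidth defaults to
#' the mean pairwise training distance.  Test values reuse the training
#' center, scale and bandwidth.
#'
#' @param x numeric covariate vector for the training samples.
#' @param newdata optional numeric covariate vector for test samples; when
#'   given the result is the test x training kernel.
#' @param standardize logical; z-score using training statistics.
#' @param name covariate name used in error messages.
#' @return kernel matrix with attributes `sigma`, `center`, `scale`.
#' @export
covariate_kernel <- function(x, newdata = NULL, standardize = TRUE,
                             name = deparse(substitute(x))) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  ctr <- 0; scl <- 1
  if (standardize) {
    ctr <- mean(x); scl <- sd(x)
    if (!is.finite(scl) || scl == 0)
      stop("covariate '", name, "' has zero variance")
    x <- (x - ctr) / scl
  }
  D <- abs(outer(x, x, "-"))
  sigma <- mean(D[upper.tri(D)])
  if (!is.finite(sigma) || sigma <= 0)
    stop("covariate '", name, "' has zero variance")
  if (is.null(newdata)) {
    K <- exp(-D^2 / (2 * sigma^2))
  } else {
    stopifnot(is.numeric(newdata), all(is.finite(newdata)))
    xt <- (newdata - ctr) / scl
    Dc <- abs(outer(xt, x, "-"))
    K <- exp(-Dc^2 / (2 * sigma^2))
  }
  attr(K, "sigma") <- sigma
  attr(K, "center") <- ctr
  attr(K, "scale") <- scl
  attr(K, "metric") <- paste0("covariate:", name)
  K
}
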