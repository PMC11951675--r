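#' ARD squared-exponential kernel parameters
#'
#' @param variance Signal variance sigma^2 (> 0): the kernel value at zero
#'   distance, i.e. the prior variance of the latent function.
#' @param lengthscales Vector of per-dimension length scales l_1..l_d
#'   (all > 0). A small length scale makes the corresponding input dimension
#'   highly influential; a large one effectively switches it off -- this is
#'   the automatic-relevance-determination (ARD) mechanism.
#' @return An `ard_params` object.
#' @export
#' @examples
#' ard_params(1, c(0.5, 5))
ard_params <- function(variance = 1, lengthscales) {
  if (!is_scalar_number(variance) || variance <= 0) stop_moegpr("variance must be a positive number")
  lengthscales <- as.numeric(lengthscales)
  if (length(lengthscales) < 1L || any(!is.finite(lengthscales)) || any(lengthscales <= 0)) {
    stop_moegpr("lengthscales must all be positive and finite")
  }
  structure(list(variance = variance, lengthscales = lengthscales),
            class = "ard_params")
}

#' @export
print.ard_params <- function(x, ...) {
  cat("<ard_params> variance =", signif(x$variance, 4),
      "| lengthscales =", paste(signif(x$lengthscales, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate the SE-ARD kernel for a pair of points
#'
#' k(x, x') = sigma^2 exp(-1/2 sum_i (x_i - x'_i)^2 / l_i^2). With all length
#' scales equal this reduces to the isotropic squared-exponential kernel.
#'
#' @param x,x2 Numeric vectors of length d.
#' @param params An [ard_params] object with d length scales.
#' @return A single kernel value in (0, sigma^2].
#' @export
ard_kernel <- function(x, x2, params) {
  d <- length(params$lengthscales)
  if (length(x) != d || length(x2) != d) {
    stop_moegpr("ard_kernel: inputs must have length ", d, " to match the kernel parameters")
  }
  params$variance * exp(-0.5 * sum(((x - x2) / params$lengthscales)^2))
}

# scaled squared distances: ||(x - x') / l||^2 for all row pairs
scaled_sqdist <- function(X, X2, lengthscales) {
  Xs <- sweep(X, 2L, lengthscales, `/`)
  X2s <- sweep(X2, 2L, lengthscales, `/`)
  d2 <- outer(rowSums(Xs^2), rowSums(X2s^2), `+`) - 2 * tcrossprod(Xs, X2s)
  pmax(d2, 0)
}

#' Kernel (Gram) matrix of the SE-ARD kernel
#'
#' @param X n x d matrix of inputs (rows are points).
#' @param X2 Optional p x d matrix; defaults to `X`, giving the symmetric
#'   Gram matrix K(X, X).
#' @param params An [ard_params] object.
#' @param jitter Non-negative value added to the diagonal when `X2` is
#'   missing, to keep the matrix numerically positive definite.
#' @return An n x p matrix with entries `ard_kernel(X[i, ], X2[j, ], params)`.
#' @export
kernel_matrix <- function(X, X2 = NULL, params, jitter = 0) {
  X <- as_num_matrix(X, "X")
  symmetric <- is.null(X2)
  X2 <- if (symmetric) X else as_num_matrix(X2, "X2")
  d <- length(params$lengthscales)
  if (ncol(X) != d || ncol(X2) != d) {
    stop_moegpr("kernel_matrix: inputs have ", ncol(X), "/", ncol(X2),
                " columns but the kernel expects ", d)
  }
  K <- params$variance * exp(-0.5 * scaled_sqdist(X, X2, params$lengthscales))
  if (!all(is.finite(K))) stop_moegpr("non-finite kernel entries (check inputs and lengthscales)")
  if (symmetric) {
    K <- (K + t(K)) / 2
    if (jitter > 0) K <- K + diag(jitter, nrow(K))
  }
  K
}
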