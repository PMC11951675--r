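#' @importFrom rlang %||%
#' @importFrom stats median optim rnorm runif rbinom sd setNames kmeans cor dnorm quantile
#' @importFrom utils head modifyList
NULL

# numerically safe log-sum-exp over rows of a matrix
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

# row-wise softmax with max subtraction; never overflows for finite logits
row_softmax <- function(m) {
  e <- exp(m - apply(m, 1L, max))
  e / rowSums(e)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stop_moegpr <- function(...) stop(..., call. = FALSE)

as_num_matrix <- function(x, what = "matrix") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  if (!is.numeric(x)) stop_moegpr(what, " must be numeric")
  x
}
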