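#' @title Gaussian-process expert regression
#' @description Exact GP regression with a zero mean function and the SE-ARD
#'   kernel: hyperparameters (signal variance, per-dimension length scales,
#'   observation-noise variance) are fitted by minimizing the negative log
#'   marginal likelihood (NLML), summed over output columns so that all
#'   metabolites share one ARD length-scale vector per expert.
#' @name gp_expert
NULL

# Cholesky of K + noise*I with jitter escalation: start at 1e-6*variance,
# multiply by 10 up to 1e-2*variance before giving up.
chol_noisy <- function(K, noise, variance) {
  n <- nrow(K)
  jitter <- 0
  repeat {
    R <- tryCatch(chol(K + diag(noise + jitter, n)), error = function(e) NULL)
    if (!is.null(R)) return(list(R = R, jitter = jitter))
    if (jitter >= 1e-2 * variance) {
      stop_moegpr("covariance factorization failed even at maximum jitter ",
                  signif(jitter, 3))
    }
    jitter <- if (jitter == 0) 1e-6 * variance else jitter * 10
  }
}

# per-dimension squared-difference matrices (x_i - x'_i)^2, reused by the
# NLML gradient
sqdiff_per_dim <- function(X) {
  lapply(seq_len(ncol(X)), function(j) outer(X[, j], X[, j], `-`)^2)
}

# theta = c(log variance, log lengthscales (d), log noise)
theta_pack <- function(variance, lengthscales, noise) log(c(variance, lengthscales, noise))
theta_unpack <- function(theta, d) {
  list(variance = exp(theta[1L]),
       lengthscales = exp(theta[1L + seq_len(d)]),
       noise = exp(theta[d + 2L]))
}

# Summed-over-outputs NLML and its gradient in log-parameter space.
nlml_objective <- function(theta, X, Y, D2, grad = TRUE) {
  d <- ncol(X); n <- nrow(X); m <- ncol(Y)
  p <- theta_unpack(theta, d)
  params <- ard_params(p$variance, p$lengthscales)
  K <- kernel_matrix(X, params = params)
  fac <- chol_noisy(K, p$noise, p$variance)
  R <- fac$R
  alpha <- backsolve(R, forwardsolve(t(R), Y))       # (K + noise I)^{-1} Y
  val <- 0.5 * sum(Y * alpha) + m * sum(log(diag(R))) + 0.5 * n * m * log(2 * pi)
  if (!grad) return(list(value = val))
  Ainv <- chol2inv(R)
  G <- m * Ainv - tcrossprod(alpha)                  # d(NLML)/dA = G/2
  g <- numeric(d + 2L)
  g[1L] <- 0.5 * sum(G * K)                          # dA/dlog sigma^2 = K
  for (j in seq_len(d)) {
    g[1L + j] <- 0.5 * sum(G * (K * D2[[j]])) / p$lengthscales[j]^2
  }
  g[d + 2L] <- 0.5 * p$noise * sum(diag(G))          # dA/dlog noise = noise I
  list(value = val, gradient = g, chol = R, jitter = fac$jitter, alpha = alpha)
}

#' Construct a GP expert from given hyperparameters
#'
#' Builds the cached factorization for fixed hyperparameters without any
#' optimization -- useful for closed-form checks and for conditioning on a
#' known kernel.
#'
#' @param X n x d input matrix.
#' @param Y n x m target matrix.
#' @param kernel An [ard_params] object with d length scales.
#' @param noise_variance Observation-noise variance (> 0).
#' @param label Optional expert label.
#' @return A `gp_expert` object (unfitted: hyperparameters as supplied).
#' @export
gp_expert <- function(X, Y, kernel, noise_variance, label = NULL) {
  X <- as_num_matrix(X, "X"); Y <- as_num_matrix(Y, "Y")
  stopifnot(inherits(kernel, "ard_params"), noise_variance > 0,
            nrow(X) == nrow(Y), ncol(X) == length(kernel$lengthscales))
  K <- kernel_matrix(X, params = kernel)
  fac <- chol_noisy(K, noise_variance, kernel$variance)
  alpha <- backsolve(fac$R, forwardsolve(t(fac$R), Y))
  nlml <- 0.5 * sum(Y * alpha) + ncol(Y) * sum(log(diag(fac$R))) +
    0.5 * nrow(X) * ncol(Y) * log(2 * pi)
  structure(
    list(kernel = kernel, noise_variance = noise_variance, X = X, Y = Y,
         chol = fac$R, alpha = alpha, jitter = fac$jitter, nlml = nlml,
         label = label,
         feature_names = colnames(X) %||% paste0("x", seq_len(ncol(X))),
         output_names = colnames(Y) %||% paste0("y", seq_len(ncol(Y))),
         method = "exact", iterations = 0L, converged = TRUE),
    class = "gp_expert")
}

median_pairwise_ls <- function(X) {
  n <- nrow(X)
  idx <- if (n > 200L) sample.int(n, 200L) else seq_len(n)
  vapply(seq_len(ncol(X)), function(j) {
    dj <- abs(outer(X[idx, j], X[idx, j], `-`))
    v <- median(dj[upper.tri(dj)])
    if (!is.finite(v) || v <= 0) v <- max(sd(X[, j]), 1)
    v
  }, numeric(1))
}

#' Fit a single Gaussian-process expert
#'
#' Minimizes the NLML, summed across all output columns, over the log of the
#' SE-ARD hyperparameters. The fitted length scales are the basis of the
#' ARD feature-relevance ranking (see [feature_relevance()]).
#'
#' @param X n x d numeric matrix of (typically clr-transformed) microbial
#'   profiles, samples in rows.
#' @param Y n x m numeric matrix of (typically clr-transformed) metabolite
#'   targets.
#' @param init Optional [ard_params] initialization. Default: signal variance
#'   1, length scales set to the per-dimension median pairwise distance.
#' @param noise_init Initial observation-noise variance (default 0.1).
#' @param optimizer `"lbfgs"` (default; analytic gradients) or `"adam"`
#'   (stochastic-optimizer schedule matching the gating network: learning
#'   rate 0.01 decayed by 0.95 every 500 steps).
#' @param maxit Maximum optimizer iterations; 0 returns the initialization
#'   unchanged.
#' @param label Optional phenotype label this expert models.
#' @param sparse Optional list enabling the variational inducing-point
#'   approximation for large blocks: `list(n_inducing = 128, threshold = 2000,
#'   force = FALSE)`. When the block exceeds `threshold` samples (or `force`
#'   is set) the expert is fitted by maximizing a collapsed evidence lower
#'   bound with kmeans-selected inducing points instead of the exact NLML.
#' @return A `gp_expert` object with elements `kernel` ([ard_params]),
#'   `noise_variance`, `X`, `Y`, cached Cholesky factor, summed `nlml`, and
#'   fitting metadata.
#' @export
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(40), 20, 2)
#' Y <- cbind(sin(X[, 1]) + rnorm(20, sd = 0.1))
#' fit <- fit_gp_expert(X, Y, maxit = 30)
#' glance(fit)
fit_gp_expert <- function(X, Y, init = NULL, noise_init = 0.1,
                          optimizer = c("lbfgs", "adam"), maxit = 100,
                          label = NULL, sparse = NULL) {
  X <- as_num_matrix(X, "X"); Y <- as_num_matrix(Y, "Y")
  optimizer <- match.arg(optimizer)
  n <- nrow(X); d <- ncol(X)
  if (nrow(Y) != n) stop_moegpr("X and Y must have the same number of rows")
  if (n < 2L) stop_moegpr("a GP expert needs at least 2 training samples")
  if (any(apply(Y, 2L, function(y) all(y == 0)))) {
    stop_moegpr("constant-zero target column(s); drop them before fitting")
  }
  init <- init %||% ard_params(1, median_pairwise_ls(X))
  if (length(init$lengthscales) != d) stop_moegpr("init lengthscales must have length ", d)

  sp <- modifyList(list(n_inducing = 128L, threshold = 2000L, force = FALSE),
                   sparse %||% list())
  if (isTRUE(sp$force) || (!is.null(sparse) && n > sp$threshold)) {
    return(fit_gp_expert_sparse(X, Y, init, noise_init, maxit, label, sp))
  }

  theta <- theta_pack(init$variance, init$lengthscales, noise_init)
  D2 <- sqdiff_per_dim(X)
  iterations <- 0L; converged <- TRUE
  if (maxit > 0L) {
    if (optimizer == "lbfgs") {
      opt <- optim(theta,
                   fn = function(th) nlml_objective(th, X, Y, D2, grad = FALSE)$value,
                   gr = function(th) nlml_objective(th, X, Y, D2)$gradient,
                   method = "L-BFGS-B", lower = log(1e-8), upper = log(1e8),
                   control = list(maxit = maxit))
      if (opt$value <= nlml_objective(theta, X, Y, D2, grad = FALSE)$value) theta <- opt$par
      iterations <- opt$counts[["function"]]
      converged <- opt$convergence %in% c(0L, 1L)
      if (!converged) warning("GP hyperparameter optimization did not converge; returning best iterate",
                              call. = FALSE)
    } else {
      st <- adam_state(length(theta))
      best <- list(theta = theta, value = Inf)
      for (it in seq_len(maxit)) {
        ob <- nlml_objective(theta, X, Y, D2)
        if (ob$value < best$value) best <- list(theta = theta, value = ob$value)
        lr <- 0.01 * 0.95^((it - 1L) %/% 500L)
        st <- adam_step(st, ob$gradient, lr)
        theta <- theta - st$update
      }
      if (nlml_objective(theta, X, Y, D2, grad = FALSE)$value > best$value) theta <- best$theta
      iterations <- maxit
    }
  }
  p <- theta_unpack(theta, d)
  final <- nlml_objective(theta, X, Y, D2)
  structure(
    list(kernel = ard_params(p$variance, p$lengthscales),
         noise_variance = p$noise,
         X = X, Y = Y,
         chol = final$chol, alpha = final$alpha, jitter = final$jitter,
         nlml = final$value, label = label,
         feature_names = colnames(X) %||% paste0("x", seq_len(d)),
         output_names = colnames(Y) %||% paste0("y", seq_len(ncol(Y))),
         method = "exact", iterations = iterations, converged = converged),
    class = "gp_expert")
}

#' Negative log marginal likelihood of a fitted expert
#'
#' 0.5 y' (K + noise I)^-1 y + 0.5 log|K + noise I| + (n/2) log 2 pi,
#' evaluated with the cached Cholesky factorization.
#'
#' @param model A fitted `gp_expert`.
#' @param column Output column index; `NULL` (default) sums over all columns.
#' @return The NLML value (finite).
#' @export
gp_nlml <- function(model, column = NULL) {
  stopifnot(inherits(model, "gp_expert"))
  if (model$method != "exact") stop_moegpr("gp_nlml() requires an exactly fitted expert")
  R <- model$chol; n <- nrow(model$X)
  cols <- column %||% seq_len(ncol(model$Y))
  Yc <- model$Y[, cols, drop = FALSE]
  a <- model$alpha[, cols, drop = FALSE]
  0.5 * sum(Yc * a) + length(cols) * sum(log(diag(R))) +
    0.5 * n * length(cols) * log(2 * pi)
}

#' Posterior prediction from a fitted expert
#'
#' Posterior mean `K(X*, X)[K + noise I]^-1 y` per output column and posterior
#' variance `k(x*, x*) - K(x*, X)(K + noise I)^-1 K(X, x*)`, which is shared
#' across output columns (all outputs share one kernel) and broadcast.
#'
#' @param object A fitted `gp_expert`.
#' @param Xstar p x d matrix of prediction inputs.
#' @param include_noise If `TRUE`, the observation-noise variance is added to
#'   the latent-function variance, giving the predictive variance of new
#'   observations (used by the mixture).
#' @param ... Unused.
#' @return A list with `mean` (p x m) and `variance` (p x m, non-negative).
#' @export
predict.gp_expert <- function(object, Xstar, include_noise = FALSE, ...) {
  Xstar <- as_num_matrix(Xstar, "Xstar")
  if (ncol(Xstar) != ncol(object$X)) {
    stop_moegpr("Xstar has ", ncol(Xstar), " columns; expert expects ", ncol(object$X))
  }
  m <- ncol(object$Y)
  if (object$method == "sparse") return(predict_sparse(object, Xstar, include_noise))
  Kx <- kernel_matrix(Xstar, object$X, params = object$kernel)
  mu <- Kx %*% object$alpha
  v <- forwardsolve(t(object$chol), t(Kx))
  var_lat <- pmax(object$kernel$variance - colSums(v^2), 0)
  if (include_noise) var_lat <- var_lat + object$noise_variance
  list(mean = `colnames<-`(mu, object$output_names),
       variance = matrix(var_lat, nrow(Xstar), m,
                         dimnames = list(NULL, object$output_names)))
}

#' @export
print.gp_expert <- function(x, ...) {
  cat("<gp_expert", if (!is.null(x$label)) paste0(" '", x$label, "'"), "> ",
      nrow(x$X), " samples, ", ncol(x$X), " features, ", ncol(x$Y), " outputs (",
      x$method, ")\n", sep = "")
  cat("  variance = ", signif(x$kernel$variance, 4),
      ", noise = ", signif(x$noise_variance, 4),
      ", nlml = ", signif(x$nlml, 6), "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the ARD length scales of a fitted expert
#'
#' @param x A fitted `gp_expert`.
#' @param ... Unused.
#' @return A tibble with one row per input feature: `feature`, `lengthscale`,
#'   `inverse_lengthscale`, `rank` (1 = most relevant).
#' @method tidy gp_expert
#' @export
tidy.gp_expert <- function(x, ...) {
  ls <- x$kernel$lengthscales
  tb <- tibble::tibble(feature = x$feature_names,
                       lengthscale = ls,
                       inverse_lengthscale = 1 / ls)
  tb <- dplyr::arrange(tb, dplyr::desc(.data$inverse_lengthscale), .data$feature)
  dplyr::mutate(tb, rank = dplyr::row_number())
}

#' One-row summary of a fitted expert
#'
#' @param x A fitted `gp_expert`.
#' @param ... Unused.
#' @return A one-row tibble with sizes, hyperparameters and final NLML.
#' @method glance gp_expert
#' @export
glance.gp_expert <- function(x, ...) {
  tibble::tibble(n = nrow(x$X), d = ncol(x$X), n_outputs = ncol(x$Y),
                 variance = x$kernel$variance, noise_variance = x$noise_variance,
                 nlml = x$nlml, iterations = x$iterations,
                 converged = x$converged, method = x$method)
}

#' @importFrom rlang .data
NULL

# ---- variational inducing-point path (collapsed bound) ---------------------

sparse_bound <- function(theta, X, Y, Z) {
  d <- ncol(X); n <- nrow(X); m <- ncol(Y); k <- nrow(Z)
  p <- theta_unpack(theta, d)
  params <- ard_params(p$variance, p$lengthscales)
  Kmm <- kernel_matrix(Z, params = params, jitter = 1e-6 * p$variance)
  Kmn <- kernel_matrix(Z, X, params = params)
  Lm <- chol(Kmm)
  V <- forwardsolve(t(Lm), Kmn)                       # Qnn = V'V
  B <- diag(k) + tcrossprod(V) / p$noise
  LB <- chol(B)
  logdet <- n * log(p$noise) + 2 * sum(log(diag(LB)))
  C <- forwardsolve(t(LB), V %*% Y) / p$noise         # k x m
  quad <- (sum(Y^2) - sum(C^2) * p$noise) / p$noise
  tr_term <- (n * p$variance - sum(V^2)) / (2 * p$noise)
  0.5 * quad + 0.5 * m * logdet + 0.5 * n * m * log(2 * pi) + m * tr_term
}

fit_gp_expert_sparse <- function(X, Y, init, noise_init, maxit, label, sp) {
  n <- nrow(X); d <- ncol(X)
  k <- min(sp$n_inducing, n)
  Z <- if (k < n) {
    km <- suppressWarnings(kmeans(X, centers = k, iter.max = 30L, nstart = 1L))
    km$centers
  } else X
  theta <- theta_pack(init$variance, init$lengthscales, noise_init)
  if (maxit > 0L) {
    opt <- optim(theta, fn = sparse_bound, X = X, Y = Y, Z = Z,
                 method = "L-BFGS-B", lower = log(1e-8), upper = log(1e8),
                 control = list(maxit = maxit))
    if (opt$value <= sparse_bound(theta, X, Y, Z)) theta <- opt$par
  }
  p <- theta_unpack(theta, d)
  params <- ard_params(p$variance, p$lengthscales)
  Kmm <- kernel_matrix(Z, params = params, jitter = 1e-6 * p$variance)
  Kmn <- kernel_matrix(Z, X, params = params)
  Sigma <- solve(Kmm + tcrossprod(Kmn) / p$noise)     # (Kmm + Kmn Knm / noise)^-1
  structure(
    list(kernel = params, noise_variance = p$noise, X = X, Y = Y,
         inducing = Z, Kmm_inv = solve(Kmm), Sigma = Sigma,
         proj = Sigma %*% (Kmn %*% Y) / p$noise,
         nlml = sparse_bound(theta, X, Y, Z), label = label,
         feature_names = colnames(X) %||% paste0("x", seq_len(d)),
         output_names = colnames(Y) %||% paste0("y", seq_len(ncol(Y))),
         method = "sparse", iterations = maxit, converged = TRUE),
    class = "gp_expert")
}

predict_sparse <- function(object, Xstar, include_noise) {
  Kxm <- kernel_matrix(Xstar, object$inducing, params = object$kernel)
  mu <- Kxm %*% object$proj
  var_lat <- object$kernel$variance -
    rowSums((Kxm %*% object$Kmm_inv) * Kxm) +
    rowSums((Kxm %*% object$Sigma) * Kxm)
  var_lat <- pmax(var_lat, 0)
  if (include_noise) var_lat <- var_lat + object$noise_variance
  m <- ncol(object$Y)
  list(mean = `colnames<-`(mu, object$output_names),
       variance = matrix(var_lat, nrow(Xstar), m,
                         dimnames = list(NULL, object$output_names)))
}
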