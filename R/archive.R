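#' @title Model archives
#' @description A fitted mixture is saved as a versioned JSON archive holding
#'   every expert's hyperparameters and training subset, the gating weights,
#'   and the allocation -- enough to reload and predict without refitting.
#'   Cached matrix factorizations are rebuilt on load.
#' @name archive
NULL

ARCHIVE_VERSION <- 1L

#' Save a fitted mixture model
#'
#' @param model A fitted `moe_gp`.
#' @param path Output file (JSON).
#' @return Invisibly, `path`.
#' @export
write_moe_model <- function(model, path) {
  stopifnot(inherits(model, "moe_gp"))
  experts <- lapply(model$experts, function(ex) {
    e <- list(label = ex$label, variance = ex$kernel$variance,
              lengthscales = ex$kernel$lengthscales,
              noise_variance = ex$noise_variance,
              method = ex$method, X = ex$X, Y = ex$Y,
              feature_names = ex$feature_names, output_names = ex$output_names)
    if (ex$method == "sparse") e$inducing <- ex$inducing
    e
  })
  obj <- list(
    schema = "moegpr/moe_gp", version = ARCHIVE_VERSION,
    experts = experts,
    gating = list(d = model$gating$d, L = model$gating$L,
                  hidden = model$gating$hidden,
                  dropout_rate = model$gating$dropout_rate,
                  layers = lapply(model$gating$layers,
                                  function(l) list(W = l$W, b = l$b))),
    allocation = list(strategy = model$allocation$strategy,
                      partition = model$allocation$partition,
                      expert_labels = model$allocation$expert_labels,
                      n = model$allocation$n),
    seed = model$seed,
    feature_names = model$feature_names, output_names = model$output_names)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

as_matrix_json <- function(x) {
  if (is.matrix(x)) return(x)
  do.call(rbind, lapply(x, function(row) as.numeric(unlist(row))))
}

#' Load a fitted mixture model
#'
#' Rebuilds the cached kernel factorizations from the stored hyperparameters
#' and training subsets; predictions from the reloaded model are identical
#' to the original's.
#'
#' @param path A file written by [write_moe_model()].
#' @return A `moe_gp` object.
#' @export
read_moe_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(obj$schema, "moegpr/moe_gp")) stop_moegpr("not a moegpr model archive: ", path)
  if (obj$version > ARCHIVE_VERSION) stop_moegpr("archive version ", obj$version, " is newer than this package supports")
  experts <- lapply(obj$experts, function(e) {
    X <- as_matrix_json(e$X); Y <- as_matrix_json(e$Y)
    params <- ard_params(e$variance, as.numeric(unlist(e$lengthscales)))
    noise <- e$noise_variance
    method <- e$method
    base <- list(kernel = params, noise_variance = noise, X = X, Y = Y,
                 label = e$label,
                 feature_names = as.character(unlist(e$feature_names)),
                 output_names = as.character(unlist(e$output_names)),
                 method = method, iterations = NA_integer_, converged = TRUE)
    colnames(X) <- base$feature_names
    if (identical(method, "sparse")) {
      Z <- as_matrix_json(e$inducing)
      Kmm <- kernel_matrix(Z, params = params, jitter = 1e-6 * params$variance)
      Kmn <- kernel_matrix(Z, X, params = params)
      Sigma <- solve(Kmm + tcrossprod(Kmn) / noise)
      base <- c(base, list(inducing = Z, Kmm_inv = solve(Kmm), Sigma = Sigma,
                           proj = Sigma %*% (Kmn %*% Y) / noise,
                           nlml = NA_real_))
    } else {
      K <- kernel_matrix(X, params = params)
      fac <- chol_noisy(K, noise, params$variance)
      alpha <- backsolve(fac$R, forwardsolve(t(fac$R), Y))
      base <- c(base, list(chol = fac$R, alpha = alpha, jitter = fac$jitter))
      base$nlml <- 0.5 * sum(Y * alpha) + ncol(Y) * sum(log(diag(fac$R))) +
        0.5 * nrow(X) * ncol(Y) * log(2 * pi)
    }
    structure(base, class = "gp_expert")
  })
  gating <- structure(
    list(layers = lapply(obj$gating$layers,
                         function(l) list(W = as_matrix_json(l$W),
                                          b = as.numeric(unlist(l$b)))),
         d = obj$gating$d, L = obj$gating$L,
         hidden = as.integer(unlist(obj$gating$hidden)),
         dropout_rate = obj$gating$dropout_rate),
    class = "gating_params")
  allocation <- structure(
    list(strategy = obj$allocation$strategy,
         partition = lapply(obj$allocation$partition, function(p) as.integer(unlist(p))),
         expert_labels = as.character(unlist(obj$allocation$expert_labels)),
         n = obj$allocation$n),
    class = "expert_allocation")
  structure(list(experts = experts, gating = gating, allocation = allocation,
                 gating_loss_value = NA_real_, gating_steps_run = NA_integer_,
                 config = moe_config(), seed = obj$seed,
                 feature_names = unlist(obj$feature_names),
                 output_names = unlist(obj$output_names)),
            class = "moe_gp")
}
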