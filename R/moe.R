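#' @title Mixture of GP experts
#' @description Assembles phenotype-allocated GP experts and the softmax
#'   gating network into one predictive model: each expert is fitted on its
#'   sample block by NLML minimization, the gating network is then trained on
#'   all samples by minimizing the mixture negative log-likelihood with the
#'   experts' predictive distributions held fixed, and predictions are
#'   combined by moment matching.
#' @name moe
NULL

#' Allocate training samples to experts
#'
#' Partitions samples into disjoint blocks, one per expert.
#'
#' * `"phenotype"` (default): one expert per distinct label; each block is
#'   exactly that label's samples.
#' * `"random"`: the same number of experts as distinct labels, but samples
#'   shuffled (seeded) into label-agnostic, equal-as-possible blocks.
#' * `"double"`: each label's block split into two halves (sizes differing by
#'   at most 1), doubling the expert count.
#'
#' @param labels Character/factor vector of per-sample phenotype labels.
#' @param strategy `"phenotype"`, `"random"` or `"double"`.
#' @param seed Seed for the random strategy's shuffle (and the double split).
#' @param min_block Blocks smaller than this trigger a warning (tiny blocks
#'   give each expert too little data to learn from).
#' @return An `expert_allocation` object: list with `strategy`, `partition`
#'   (list of sample-index vectors), and `expert_labels`.
#' @export
#' @examples
#' allocate_experts(c("A", "A", "B", "B", "B"), "double", seed = 1)
allocate_experts <- function(labels, strategy = c("phenotype", "random", "double"),
                             seed = 1L, min_block = 5L) {
  strategy <- match.arg(strategy)
  labels <- as.character(labels)
  n <- length(labels)
  ulab <- sort(unique(labels))
  partition <- switch(
    strategy,
    phenotype = lapply(ulab, function(l) which(labels == l)),
    random = {
      L <- length(ulab)
      idx <- withr::with_seed(seed, sample.int(n))
      unname(split(idx, sort(rep_len(seq_len(L), n))))
    },
    double = {
      out <- list()
      for (l in ulab) {
        ids <- which(labels == l)
        ids <- withr::with_seed(seed, sample(ids))
        h <- ceiling(length(ids) / 2)
        out <- c(out, list(sort(ids[seq_len(h)]), sort(ids[-seq_len(h)])))
      }
      out
    })
  expert_labels <- switch(strategy,
    phenotype = ulab,
    random = paste0("random", seq_along(partition)),
    double = paste0(rep(ulab, each = 2L), c("_1", "_2")))
  if (any(lengths(partition) == 0L)) stop_moegpr("empty expert block; too few samples")
  small <- lengths(partition) < min_block
  if (any(small)) {
    warning("expert block(s) ", paste(expert_labels[small], collapse = ", "),
            " have fewer than ", min_block,
            " samples; the corresponding experts may be unreliable", call. = FALSE)
  }
  structure(list(strategy = strategy, partition = lapply(partition, sort),
                 expert_labels = expert_labels, n = n),
            class = "expert_allocation")
}

#' @export
print.expert_allocation <- function(x, ...) {
  cat("<expert_allocation> strategy =", x$strategy, "| L =", length(x$partition), "\n")
  cat(paste0("  ", x$expert_labels, ": ", lengths(x$partition), " samples\n"), sep = "")
  invisible(x)
}

#' Model configuration for the GP-expert mixture
#'
#' Defaults follow the reference training recipe: a 128/64-unit gating
#' network with dropout 0.2, Adam with initial learning rate 0.01 decayed by
#' a factor of 0.95 every 500 steps, up to 2000 gating steps with early
#' stopping (patience 200), and full-batch updates for up to 512 samples.
#'
#' @param hidden Gating hidden-layer sizes.
#' @param dropout_rate Gating dropout rate.
#' @param lr,lr_decay,decay_every,gating_steps,patience,batch_size Gating
#'   optimizer schedule.
#' @param gating_loss `"mixture"` (default; mixture negative log-likelihood
#'   with experts frozen) or `"supervised"` (cross-entropy against the
#'   allocation's expert assignment).
#' @param val_frac Fraction of training samples held out to monitor gating
#'   early stopping (default 0.2; 0 monitors the training loss).
#' @param gp_maxit Maximum NLML optimizer iterations per expert.
#' @param gp_optimizer `"lbfgs"` or `"adam"` for the expert hyperparameters.
#' @param joint_rounds Number of optional end-to-end refinement rounds
#'   (re-assign samples to their highest-responsibility expert, refit, retrain
#'   gating); 0 disables.
#' @param min_block Minimum expert block size before a warning.
#' @param sparse `NULL` for exact experts, or a list passed to
#'   [fit_gp_expert()]'s `sparse` argument.
#' @return A `moe_config` list.
#' @export
moe_config <- function(hidden = c(128L, 64L), dropout_rate = 0.2,
                       lr = 0.01, lr_decay = 0.95, decay_every = 500L,
                       gating_steps = 2000L, patience = 200L, batch_size = NULL,
                       val_frac = 0.2, gating_loss = c("mixture", "supervised"),
                       gp_maxit = 100L, gp_optimizer = "lbfgs",
                       joint_rounds = 0L, min_block = 5L, sparse = NULL) {
  structure(list(hidden = hidden, dropout_rate = dropout_rate, lr = lr,
                 lr_decay = lr_decay, decay_every = decay_every,
                 gating_steps = gating_steps, patience = patience,
                 batch_size = batch_size, val_frac = val_frac,
                 gating_loss = match.arg(gating_loss),
                 gp_maxit = gp_maxit, gp_optimizer = gp_optimizer,
                 joint_rounds = joint_rounds, min_block = min_block,
                 sparse = sparse),
            class = "moe_config")
}

#' Moment-matched moments of a finite Gaussian mixture
#'
#' Given per-sample expert weights and each expert's predictive mean and
#' variance, returns the mixture mean `mu = sum_l w_l f_l` and total variance
#' `sigma^2 = sum_l w_l (v_l + (f_l - mu)^2)` -- within-expert uncertainty
#' plus between-expert spread.
#'
#' @param weights p x L matrix of non-negative weights, rows summing to 1.
#' @param means List of L p x m per-expert mean matrices.
#' @param variances List of L p x m per-expert variance matrices.
#' @return A list with `mean` and `variance` (p x m each).
#' @export
mixture_moments <- function(weights, means, variances) {
  L <- ncol(weights)
  stopifnot(length(means) == L, length(variances) == L)
  mu <- matrix(0, nrow(means[[1L]]), ncol(means[[1L]]))
  for (l in seq_len(L)) mu <- mu + weights[, l] * means[[l]]
  v <- matrix(0, nrow(mu), ncol(mu))
  for (l in seq_len(L)) {
    v <- v + weights[, l] * (variances[[l]] + (means[[l]] - mu)^2)
  }
  list(mean = mu, variance = v)
}

# Per-expert log density log N(y_i | f_l(x_i), v_l(x_i) I_m) for all
# samples. For samples inside an expert's own training block the in-sample
# posterior interpolates (near-zero error and variance), which would turn
# the gating targets into overconfident hard labels; those entries are
# replaced by the expert's leave-one-out predictive density, computed in
# closed form from the cached factorization (mu_i = y_i - alpha_i / A^-1_ii,
# v_i = 1 / A^-1_ii, noise included since A = K + noise I).
expert_logdens <- function(experts, X, Y, blocks = NULL) {
  m <- ncol(Y)
  ld <- vapply(experts, function(ex) {
    pr <- predict(ex, X, include_noise = TRUE)
    v <- pr$variance[, 1L]
    -0.5 * m * log(2 * pi * v) - rowSums((Y - pr$mean)^2) / (2 * v)
  }, numeric(nrow(X)))
  if (!is.null(blocks)) {
    for (l in seq_along(experts)) {
      ex <- experts[[l]]
      if (ex$method != "exact") next
      idx <- blocks[[l]]
      Ainv_diag <- diag(chol2inv(ex$chol))
      v_loo <- 1 / Ainv_diag
      resid_loo <- ex$alpha / Ainv_diag             # y_i - mu_loo_i
      ld[idx, l] <- -0.5 * m * log(2 * pi * v_loo) -
        rowSums(resid_loo^2) / (2 * v_loo)
    }
  }
  ld
}

#' Fit the gating-network mixture of GP experts
#'
#' Two-phase training. Phase 1 fits one GP expert per allocation block by
#' NLML minimization. Phase 2 trains the gating network on all training
#' samples by minimizing the mixture negative log-likelihood
#' `-sum_i log sum_l w_l(x_i) N(y_i | f_l(x_i), v_l(x_i))` with the experts'
#' predictive means/variances fixed. Optional refinement rounds
#' (`config$joint_rounds > 0`) re-assign samples to their
#' highest-responsibility expert and refit.
#'
#' @param data A preprocessed (clr-scale) [paired_data] object, or `NULL` if
#'   `X`, `Y`, `labels` are given directly.
#' @param strategy Expert-allocation strategy (see [allocate_experts()]);
#'   ignored when `allocation` is supplied.
#' @param allocation Optional precomputed [allocate_experts()] result.
#' @param config A [moe_config()] list.
#' @param seed Root seed for all randomness (gating init, dropout, shuffles).
#' @param X,Y Optional matrices overriding `data` (microbial inputs and
#'   metabolite targets).
#' @param labels Optional label vector when `X`/`Y` are given.
#' @return A fitted `moe_gp` object.
#' @export
#' @examples
#' spec <- synth_spec(n_per_group = c(15, 15), d = 6, m = 3, s = 2, seed = 1)
#' pd <- preprocess_paired(generate_paired(spec)$data)
#' fit <- fit_moe(pd, config = moe_config(gating_steps = 50, gp_maxit = 20))
#' fit
fit_moe <- function(data = NULL, strategy = "phenotype", allocation = NULL,
                    config = moe_config(), seed = 1L,
                    X = NULL, Y = NULL, labels = NULL) {
  if (!is.null(data)) {
    stopifnot(inherits(data, "paired_data"))
    X <- data$microbial; Y <- data$metabolite; labels <- data$labels
  }
  X <- as_num_matrix(X, "X"); Y <- as_num_matrix(Y, "Y")
  labels <- labels %||% rep("all", nrow(X))
  allocation <- allocation %||%
    allocate_experts(labels, strategy, seed = seed, min_block = config$min_block)
  L <- length(allocation$partition)

  fit_block <- function(idx, lab) {
    fit_gp_expert(X[idx, , drop = FALSE], Y[idx, , drop = FALSE],
                  optimizer = config$gp_optimizer, maxit = config$gp_maxit,
                  label = lab, sparse = config$sparse)
  }
  experts <- purrr::map2(allocation$partition, allocation$expert_labels, fit_block)

  train_phase2 <- function(experts, seed_offset = 0L) {
    gp <- gating_init(ncol(X), L, hidden = config$hidden,
                      dropout_rate = config$dropout_rate,
                      seed = seed + seed_offset)
    if (config$gating_steps <= 0L || L == 1L) {
      return(list(params = gp, loss = NA_real_, steps_run = 0L))
    }
    if (config$gating_loss == "supervised") {
      tidx <- integer(nrow(X))
      for (l in seq_len(L)) tidx[allocation$partition[[l]]] <- l
      train_gating(gp, X, target_idx = tidx, steps = config$gating_steps,
                   lr = config$lr, lr_decay = config$lr_decay,
                   decay_every = config$decay_every, patience = config$patience,
                   batch_size = config$batch_size, val_frac = config$val_frac,
                   seed = seed + seed_offset + 1L)
    } else {
      train_gating(gp, X,
                   logdens = expert_logdens(experts, X, Y, allocation$partition),
                   steps = config$gating_steps,
                   lr = config$lr, lr_decay = config$lr_decay,
                   decay_every = config$decay_every, patience = config$patience,
                   batch_size = config$batch_size, val_frac = config$val_frac,
                   seed = seed + seed_offset + 1L)
    }
  }
  gt <- train_phase2(experts)

  if (config$joint_rounds > 0L && L > 1L) {
    for (round in seq_len(config$joint_rounds)) {
      ld <- expert_logdens(experts, X, Y)
      logits <- gating_forward_cache(gt$params, X, training = FALSE)$logits
      resp <- row_softmax((logits - row_logsumexp(logits)) + ld)
      assign <- max.col(resp, ties.method = "first")
      blocks <- lapply(seq_len(L), function(l) which(assign == l))
      if (any(lengths(blocks) < max(2L, config$min_block))) break
      allocation$partition <- blocks
      experts <- purrr::map2(blocks, allocation$expert_labels, fit_block)
      gt <- train_phase2(experts, seed_offset = 10L * round)
    }
  }

  structure(list(experts = experts, gating = gt$params, allocation = allocation,
                 gating_loss_value = gt$loss, gating_steps_run = gt$steps_run,
                 config = config, seed = seed,
                 feature_names = colnames(X) %||% paste0("x", seq_len(ncol(X))),
                 output_names = colnames(Y) %||% paste0("y", seq_len(ncol(Y)))),
            class = "moe_gp")
}

#' @export
print.moe_gp <- function(x, ...) {
  cat("<moe_gp> ", length(x$experts), " expert(s), strategy = ",
      x$allocation$strategy, "\n", sep = "")
  for (ex in x$experts) {
    cat("  - '", ex$label %||% "?", "': n = ", nrow(ex$X),
        ", nlml = ", signif(ex$nlml, 6), "\n", sep = "")
  }
  if (!is.na(x$gating_loss_value)) {
    cat("  gating mixture loss = ", signif(x$gating_loss_value, 6),
        " after ", x$gating_steps_run, " steps\n", sep = "")
  }
  invisible(x)
}

#' Moment-matched mixture prediction
#'
#' For each new sample, expert weights `w_l(x)` come from the evaluation-mode
#' gating network (no dropout), and the experts' Gaussian predictive
#' distributions are combined by moment matching:
#' mean `mu(x) = sum_l w_l(x) f_l(x)` and variance
#' `sigma^2(x) = sum_l w_l(x) (v_l(x) + (f_l(x) - mu(x))^2)`, where `v_l`
#' includes the expert's observation noise. The variance therefore never
#' falls below the weighted within-expert variance: disagreement between
#' experts adds spread.
#'
#' @param object A fitted `moe_gp`.
#' @param newdata A [paired_data] object or a p x d numeric matrix of
#'   clr-scale microbial profiles.
#' @param ... Unused.
#' @return A `moe_prediction` object: `mean` (p x m), `variance` (p x m),
#'   `expert_weights` (p x L), and `per_expert` diagnostics.
#' @export
predict.moe_gp <- function(object, newdata, ...) {
  Xs <- if (inherits(newdata, "paired_data")) newdata$microbial else as_num_matrix(newdata, "newdata")
  if (ncol(Xs) != length(object$feature_names)) {
    stop_moegpr("newdata has ", ncol(Xs), " features; model expects ",
                length(object$feature_names))
  }
  L <- length(object$experts)
  per <- lapply(object$experts, predict, Xstar = Xs, include_noise = TRUE)
  W <- gating_forward(object$gating, Xs, training = FALSE)
  mo <- mixture_moments(W, lapply(per, `[[`, "mean"), lapply(per, `[[`, "variance"))
  mu <- mo$mean; v <- mo$variance
  colnames(mu) <- colnames(v) <- object$output_names
  colnames(W) <- vapply(object$experts, function(e) e$label %||% "expert", "")
  structure(list(mean = mu, variance = v, expert_weights = W, per_expert = per),
            class = "moe_prediction")
}

#' @export
print.moe_prediction <- function(x, ...) {
  cat("<moe_prediction> ", nrow(x$mean), " samples x ", ncol(x$mean),
      " metabolites, ", ncol(x$expert_weights), " expert(s)\n", sep = "")
  invisible(x)
}

#' Credible intervals from a mixture prediction
#'
#' Central `k_sigma`-standard-deviation bands `mu +/- k_sigma * sqrt(sigma^2)`;
#' the default `k_sigma = 2` gives the conventional 95% credible interval.
#'
#' @param pred A `moe_prediction`.
#' @param k_sigma Half-width in posterior standard deviations.
#' @return A list with `lower` and `upper` p x m matrices.
#' @export
credible_interval <- function(pred, k_sigma = 2) {
  stopifnot(inherits(pred, "moe_prediction"))
  s <- sqrt(pmax(pred$variance, 0))
  list(lower = pred$mean - k_sigma * s, upper = pred$mean + k_sigma * s)
}

#' Tidy a mixture prediction into long format
#'
#' @param x A `moe_prediction`.
#' @param k_sigma Credible-interval half-width in standard deviations.
#' @param ... Unused.
#' @return A tibble with columns `sample`, `metabolite`, `mean`, `variance`,
#'   `lower`, `upper`.
#' @method tidy moe_prediction
#' @export
tidy.moe_prediction <- function(x, k_sigma = 2, ...) {
  ci <- credible_interval(x, k_sigma)
  long <- function(m, name) {
    tibble::as_tibble(as.data.frame(m)) |>
      dplyr::mutate(sample = seq_len(nrow(m))) |>
      tidyr::pivot_longer(-"sample", names_to = "metabolite", values_to = name)
  }
  long(x$mean, "mean") |>
    dplyr::left_join(long(x$variance, "variance"), by = c("sample", "metabolite")) |>
    dplyr::left_join(long(ci$lower, "lower"), by = c("sample", "metabolite")) |>
    dplyr::left_join(long(ci$upper, "upper"), by = c("sample", "metabolite"))
}

#' Tidy a fitted mixture: one row per expert
#'
#' @param x A fitted `moe_gp`.
#' @param ... Unused.
#' @return A tibble with expert label, block size, hyperparameters, NLML.
#' @method tidy moe_gp
#' @export
tidy.moe_gp <- function(x, ...) {
  purrr::map2_dfr(x$experts, seq_along(x$experts), function(ex, i) {
    dplyr::mutate(glance(ex), expert = ex$label %||% paste0("expert", i), .before = 1L)
  })
}

#' One-row summary of a fitted mixture
#'
#' @param x A fitted `moe_gp`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance moe_gp
#' @export
glance.moe_gp <- function(x, ...) {
  tibble::tibble(n_experts = length(x$experts),
                 strategy = x$allocation$strategy,
                 n = x$allocation$n,
                 d = length(x$feature_names),
                 n_outputs = length(x$output_names),
                 gating_loss = x$gating_loss_value,
                 gating_steps = x$gating_steps_run)
}

#' Plot predictions with credible intervals
#'
#' Observed values, predicted means and the 2-sigma band for one metabolite,
#' samples ordered by observed value.
#'
#' @param object A `moe_prediction`.
#' @param observed p x m matrix of observed values.
#' @param metabolite Column name or index to plot.
#' @param k_sigma Interval half-width.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot moe_prediction
#' @export
autoplot.moe_prediction <- function(object, observed, metabolite = 1L,
                                    k_sigma = 2, ...) {
  j <- if (is.character(metabolite)) match(metabolite, colnames(object$mean)) else metabolite
  ci <- credible_interval(object, k_sigma)
  df <- tibble::tibble(observed = observed[, j], mean = object$mean[, j],
                       lower = ci$lower[, j], upper = ci$upper[, j]) |>
    dplyr::arrange(.data$observed) |>
    dplyr::mutate(idx = dplyr::row_number())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$idx)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), colour = "darkorange") +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), colour = "purple4", size = 1) +
    ggplot2::labs(x = "sample (ordered by observed value)", y = "abundance (clr)",
                  title = colnames(object$mean)[j] %||% paste("metabolite", j)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
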