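#' @title Softmax gating network
#' @description A small feedforward network with ReLU hidden layers and a
#'   softmax output that maps a sample's microbial profile to a probability
#'   vector over experts. Default architecture: input -> 128 -> 64 -> L,
#'   with dropout after the last hidden layer during training.
#' @name gating
NULL

# ---- Adam optimizer (flat-vector state) ------------------------------------

adam_state <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(state, grad, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  state$update <- lr * mhat / (sqrt(vhat) + eps)
  state
}

#' Initialize gating-network parameters
#'
#' Weights are drawn from a symmetric uniform distribution scaled by fan-in
#' (`U(-1/sqrt(fan_in), 1/sqrt(fan_in))`), biases start at zero; the draw is
#' fully determined by `seed`.
#'
#' @param d Input dimension (number of microbial features).
#' @param L Number of experts (output dimension), at least 1.
#' @param hidden Integer vector of hidden-layer sizes; default `c(128, 64)`.
#'   An empty vector gives a single affine layer `d -> L`.
#' @param dropout_rate Dropout probability applied after the last hidden
#'   layer's activation during training only (default 0.2).
#' @param seed Integer seed for the weight draw.
#' @return A `gating_params` object (list of `W`/`b` layers plus metadata).
#' @export
#' @examples
#' g <- gating_init(d = 30, L = 3, seed = 1)
#' w <- gating_forward(g, matrix(rnorm(150), 5, 30))
#' rowSums(w)  # all 1
gating_init <- function(d, L, hidden = c(128L, 64L), dropout_rate = 0.2, seed = 1L) {
  if (L < 1L) stop_moegpr("need at least one expert (L >= 1)")
  if (d < 1L) stop_moegpr("input dimension must be >= 1")
  if (dropout_rate < 0 || dropout_rate >= 1) stop_moegpr("dropout_rate must be in [0, 1)")
  sizes <- c(d, as.integer(hidden), L)
  layers <- withr::with_seed(seed, {
    lapply(seq_len(length(sizes) - 1L), function(j) {
      fan_in <- sizes[j]
      a <- 1 / sqrt(fan_in)
      list(W = matrix(runif(sizes[j + 1L] * fan_in, -a, a), sizes[j + 1L], fan_in),
           b = numeric(sizes[j + 1L]))
    })
  })
  structure(list(layers = layers, d = d, L = L, hidden = as.integer(hidden),
                 dropout_rate = dropout_rate),
            class = "gating_params")
}

#' @export
print.gating_params <- function(x, ...) {
  cat("<gating_params> ", paste(c(x$d, x$hidden, x$L), collapse = " -> "),
      " (dropout ", x$dropout_rate, ")\n", sep = "")
  invisible(x)
}

# forward pass keeping activations and dropout masks for backprop
gating_forward_cache <- function(params, X, training = FALSE) {
  nl <- length(params$layers)
  acts <- vector("list", nl + 1L)
  acts[[1L]] <- X
  masks <- vector("list", nl)
  for (j in seq_len(nl)) {
    Z <- acts[[j]] %*% t(params$layers[[j]]$W) +
      matrix(params$layers[[j]]$b, nrow(X), length(params$layers[[j]]$b), byrow = TRUE)
    if (j < nl) {
      A <- pmax(Z, 0)                                   # element-wise rectifier
      if (training && j == nl - 1L && params$dropout_rate > 0) {
        keep <- 1 - params$dropout_rate
        masks[[j]] <- matrix(rbinom(length(A), 1L, keep) / keep, nrow(A), ncol(A))
        A <- A * masks[[j]]
      }
      acts[[j + 1L]] <- A
    } else {
      acts[[j + 1L]] <- Z                               # logits
    }
  }
  if (!all(is.finite(acts[[nl + 1L]]))) stop_moegpr("non-finite gating activations")
  list(logits = acts[[nl + 1L]], acts = acts, masks = masks)
}

#' Evaluate the gating network
#'
#' Computes per-sample expert weights `w_l(x) = exp(h_l(x)) / sum_j
#' exp(h_j(x))` (softmax with max subtraction, so large logits never
#' overflow). In evaluation mode (`training = FALSE`, the default) the
#' forward pass is deterministic; in training mode dropout is active and the
#' mask draw is seeded when `seed` is supplied.
#'
#' @param params A [gating_init()] object.
#' @param X p x d matrix of inputs.
#' @param training Logical; activates dropout.
#' @param seed Optional seed for the dropout mask (training mode only).
#' @return A p x L matrix of non-negative weights; each row sums to 1.
#' @export
gating_forward <- function(params, X, training = FALSE, seed = NULL) {
  stopifnot(inherits(params, "gating_params"))
  X <- as_num_matrix(X, "X")
  if (ncol(X) != params$d) {
    stop_moegpr("input has ", ncol(X), " columns; gating network expects ", params$d)
  }
  fc <- if (training && !is.null(seed)) {
    withr::with_seed(seed, gating_forward_cache(params, X, training = TRUE))
  } else {
    gating_forward_cache(params, X, training = training)
  }
  row_softmax(fc$logits)
}

# gradient of a loss wrt all parameters, given dL/d(logits)
gating_backward <- function(params, cache, dlogits) {
  nl <- length(params$layers)
  grads <- vector("list", nl)
  delta <- dlogits
  for (j in rev(seq_len(nl))) {
    grads[[j]] <- list(W = crossprod(delta, cache$acts[[j]]),
                       b = colSums(delta))
    if (j > 1L) {
      delta <- delta %*% params$layers[[j]]$W
      if (!is.null(cache$masks[[j - 1L]])) delta <- delta * cache$masks[[j - 1L]]
      delta <- delta * (cache$acts[[j]] > 0)            # ReLU derivative
    }
  }
  grads
}

gating_flatten <- function(layers) unlist(lapply(layers, function(l) c(l$W, l$b)))

gating_unflatten <- function(flat, template) {
  pos <- 0L
  lapply(template, function(l) {
    nw <- length(l$W); nb <- length(l$b)
    W <- matrix(flat[pos + seq_len(nw)], nrow(l$W), ncol(l$W))
    b <- flat[pos + nw + seq_len(nb)]
    pos <<- pos + nw + nb
    list(W = W, b = b)
  })
}

# Mixture negative log-likelihood loss and logit gradient.
# logdens: p x L matrix of per-expert log densities log N(y_i | f_l, v_l).
# Returns loss = -sum_i log sum_l w_il exp(logdens_il) and dL/dlogits = w - r,
# r the posterior responsibilities.
gating_mixture_loss <- function(logits, logdens) {
  logw <- logits - row_logsumexp(logits)
  joint <- logw + logdens
  lse <- row_logsumexp(joint)
  w <- row_softmax(logits)
  r <- exp(joint - lse)
  list(loss = -sum(lse), dlogits = w - r)
}

# Supervised cross-entropy against a hard expert assignment.
gating_ce_loss <- function(logits, target_idx) {
  logw <- logits - row_logsumexp(logits)
  w <- row_softmax(logits)
  onehot <- matrix(0, nrow(logits), ncol(logits))
  onehot[cbind(seq_len(nrow(logits)), target_idx)] <- 1
  list(loss = -sum(logw[onehot == 1]), dlogits = w - onehot)
}

# Train the gating network by Adam with an exponentially decayed learning
# rate (lr * decay^(step %/% decay_every)); full batch for n <= 512 samples,
# else seeded minibatches. Early-stops on (and restores the best parameters
# by) the evaluation-mode loss of a held-out validation split of the training
# samples -- the gating net is flexible enough to overfit its routing targets
# badly if monitored on the optimized samples themselves. val_frac = 0
# monitors the training loss instead.
train_gating <- function(params, X, logdens = NULL, target_idx = NULL,
                         steps = 2000L, lr = 0.01, lr_decay = 0.95,
                         decay_every = 500L, patience = 200L,
                         batch_size = NULL, val_frac = 0.2, seed = 1L) {
  if (steps <= 0L) return(list(params = params, loss = NA_real_, steps_run = 0L))
  n <- nrow(X)
  val_idx <- if (val_frac > 0 && n >= 10L) {
    withr::with_seed(seed + 7L, sort(sample.int(n, max(2L, round(val_frac * n)))))
  } else integer(0)
  fit_idx <- setdiff(seq_len(n), val_idx)
  mon_idx <- if (length(val_idx)) val_idx else seq_len(n)
  nf <- length(fit_idx)
  batch_size <- batch_size %||% if (nf <= 512L) nf else 64L
  flat <- gating_flatten(params$layers)
  st <- adam_state(length(flat))
  best <- list(flat = flat, loss = Inf, step = 0L)
  trace <- numeric(0)
  loss_at <- function(pars, idx) {
    logits <- gating_forward_cache(pars, X[idx, , drop = FALSE], training = FALSE)$logits
    if (!is.null(target_idx)) gating_ce_loss(logits, target_idx[idx])$loss
    else gating_mixture_loss(logits, logdens[idx, , drop = FALSE])$loss
  }
  withr::with_seed(seed, {
    for (step in seq_len(steps)) {
      idx <- if (batch_size >= nf) fit_idx else fit_idx[sample.int(nf, batch_size)]
      lr_t <- lr * lr_decay^((step - 1L) %/% decay_every)
      retry <- 0L
      repeat {
        cache <- gating_forward_cache(params, X[idx, , drop = FALSE],
                                      training = params$dropout_rate > 0)
        lo <- if (!is.null(target_idx)) {
          gating_ce_loss(cache$logits, target_idx[idx])
        } else {
          gating_mixture_loss(cache$logits, logdens[idx, , drop = FALSE])
        }
        if (is.finite(lo$loss)) break
        retry <- retry + 1L
        if (retry > 3L) stop_moegpr("gating loss became non-finite; training aborted")
        lr_t <- lr_t / 2
      }
      grads <- gating_backward(params, cache, lo$dlogits)
      st <- adam_step(st, gating_flatten(grads), lr_t)
      flat <- gating_flatten(params$layers) - st$update
      params$layers <- gating_unflatten(flat, params$layers)
      full <- loss_at(params, mon_idx)
      trace <- c(trace, full)
      if (full < best$loss - 1e-10) best <- list(flat = flat, loss = full, step = step)
      if (step - best$step >= patience) break
    }
  })
  params$layers <- gating_unflatten(best$flat, params$layers)
  list(params = params, loss = best$loss, steps_run = length(trace), trace = trace)
}
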