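#' @title Evaluation metrics and cross-validation
#' @description Spearman-correlation metric suite for predicted vs observed
#'   metabolite profiles -- per-sample SCC across metabolites, per-metabolite
#'   SCC across samples, top-k means, counts above a threshold with
#'   log10(x+1) reporting -- and a label-stratified k-fold cross-validation
#'   harness reporting mean +/- sd over folds.
#' @name evaluation
NULL

#' Spearman's rank correlation coefficient
#'
#' Pearson correlation of mid-ranks (ties receive their average rank).
#' Returns `NA` with a warning when either vector is constant, for which rank
#' correlation is undefined; such values are excluded from metric means.
#'
#' @param a,b Numeric vectors of equal length (>= 2).
#' @return A value in [-1, 1], or `NA_real_`.
#' @export
#' @examples
#' spearman_cor(1:4, c(1, 3, 2, 4)) # 0.8
spearman_cor <- function(a, b) {
  if (length(a) != length(b)) stop_moegpr("vectors must have equal length")
  if (length(a) < 2L) stop_moegpr("need at least 2 observations")
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 2L || sd(a) == 0 || sd(b) == 0) {
    warning("Spearman correlation undefined for constant input; returning NA",
            call. = FALSE)
    return(NA_real_)
  }
  cor(rank(a), rank(b))
}

#' Per-sample SCC between predicted and observed profiles
#'
#' For each sample (row), the Spearman correlation between its predicted and
#' observed metabolite abundances across all metabolites. The mean over
#' samples is the headline accuracy aggregate.
#'
#' @param y_true,y_pred n x m matrices (samples x metabolites).
#' @return A numeric vector of n correlations (possibly `NA` for constant
#'   rows).
#' @export
per_sample_scc <- function(y_true, y_pred) {
  y_true <- as_num_matrix(y_true, "y_true"); y_pred <- as_num_matrix(y_pred, "y_pred")
  stopifnot(all(dim(y_true) == dim(y_pred)))
  vapply(seq_len(nrow(y_true)),
         function(i) suppressWarnings(spearman_cor(y_true[i, ], y_pred[i, ])),
         numeric(1))
}

#' Per-metabolite SCC between predicted and observed profiles
#'
#' Column-wise Spearman correlation across samples; the basis of the top-k
#' and count-above-threshold metrics.
#'
#' @inheritParams per_sample_scc
#' @return A numeric vector of m correlations.
#' @export
per_metabolite_scc <- function(y_true, y_pred) {
  y_true <- as_num_matrix(y_true, "y_true"); y_pred <- as_num_matrix(y_pred, "y_pred")
  stopifnot(all(dim(y_true) == dim(y_pred)))
  out <- vapply(seq_len(ncol(y_true)),
                function(j) suppressWarnings(spearman_cor(y_true[, j], y_pred[, j])),
                numeric(1))
  names(out) <- colnames(y_true)
  out
}

#' Full evaluation report for one prediction
#'
#' Computes the metric suite: mean per-sample SCC; mean SCC of the top-10 and
#' top-50 best-predicted metabolites; mean per-sample SCC restricted to the
#' top-10 metabolites; the number of metabolites with SCC above `threshold`
#' and its `log10(count + 1)` transform (adding 1 avoids log(0)). Undefined
#' (constant-input) correlations are excluded from means and counted in
#' `n_undefined`.
#'
#' @inheritParams per_sample_scc
#' @param top_k Integer vector of top-k sizes (default `c(10, 50)`); values
#'   exceeding the metabolite count are truncated with a warning.
#' @param threshold SCC threshold for the count metric (default 0.5).
#' @return An `eval_report` list; see [glance.eval_report()] for the one-row
#'   summary.
#' @export
evaluate_predictions <- function(y_true, y_pred, top_k = c(10L, 50L),
                                 threshold = 0.5) {
  ps <- per_sample_scc(y_true, y_pred)
  pm <- per_metabolite_scc(y_true, y_pred)
  m <- length(pm)
  top_k_eff <- vapply(top_k, function(k) {
    if (k > m) {
      warning("top-", k, " truncated to the ", m, " available metabolites", call. = FALSE)
      m
    } else as.integer(k)
  }, integer(1))
  pm_sorted <- sort(pm, decreasing = TRUE, na.last = TRUE)
  top_means <- setNames(
    vapply(top_k_eff, function(k) mean(head(pm_sorted, k), na.rm = TRUE), numeric(1)),
    paste0("mean_scc_top", top_k))
  k1 <- top_k_eff[1L]
  top_idx <- order(pm, decreasing = TRUE, na.last = TRUE)[seq_len(k1)]
  ps_top <- if (k1 >= 2L) {
    per_sample_scc(as_num_matrix(y_true)[, top_idx, drop = FALSE],
                   as_num_matrix(y_pred)[, top_idx, drop = FALSE])
  } else rep(NA_real_, length(ps))
  n_gt <- sum(pm > threshold, na.rm = TRUE)
  structure(list(
    per_sample_scc = ps, per_metabolite_scc = pm,
    mean_scc_samples = mean(ps, na.rm = TRUE),
    mean_scc_samples_top10 = mean(ps_top, na.rm = TRUE),
    top_means = top_means, top_k = top_k,
    n_scc_gt_threshold = n_gt, threshold = threshold,
    log10_count = log10(n_gt + 1),
    n_undefined = sum(is.na(ps)) + sum(is.na(pm))),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  print(glance(x))
  invisible(x)
}

#' One-row summary of an evaluation report
#'
#' @param x An [evaluate_predictions()] result.
#' @param ... Unused.
#' @return A one-row tibble with the aggregate metrics.
#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) {
  tb <- tibble::tibble(mean_scc_samples = x$mean_scc_samples,
                       mean_scc_samples_top10 = x$mean_scc_samples_top10,
                       n_scc_gt_threshold = x$n_scc_gt_threshold,
                       log10_count = x$log10_count,
                       n_undefined = x$n_undefined)
  for (nm in names(x$top_means)) tb[[nm]] <- unname(x$top_means[[nm]])
  dplyr::relocate(tb, dplyr::starts_with("mean_scc_top"),
                  .after = "mean_scc_samples_top10")
}

#' Tidy per-metabolite correlations
#'
#' @param x An [evaluate_predictions()] result.
#' @param ... Unused.
#' @return A tibble with `metabolite` and `scc`, ordered by descending SCC.
#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) {
  tibble::tibble(metabolite = names(x$per_metabolite_scc) %||%
                   paste0("met", seq_along(x$per_metabolite_scc)),
                 scc = unname(x$per_metabolite_scc)) |>
    dplyr::arrange(dplyr::desc(.data$scc))
}

#' Label-stratified fold assignment
#'
#' Each label's samples are shuffled (seeded) and dealt round-robin into `k`
#' folds, so every fold mirrors the label composition. If some label has
#' fewer than `k` samples, `k` is reduced to the smallest label count with a
#' warning.
#'
#' @param labels Per-sample label vector.
#' @param k Number of folds (default 5).
#' @param seed Shuffle seed.
#' @return An integer vector of fold indices in `1..k`.
#' @export
stratified_folds <- function(labels, k = 5L, seed = 1L) {
  labels <- as.character(labels)
  min_n <- min(table(labels))
  if (min_n < k) {
    warning("smallest label has ", min_n, " samples; reducing folds from ",
            k, " to ", min_n, call. = FALSE)
    k <- min_n
  }
  if (k < 2L) stop_moegpr("need at least 2 samples per label for cross-validation")
  folds <- integer(length(labels))
  withr::with_seed(seed, {
    for (l in sort(unique(labels))) {
      ids <- sample(which(labels == l))
      folds[ids] <- rep_len(seq_len(k), length(ids))
    }
  })
  folds
}

# preprocessing statistics fitted on training samples only, applied to both
# training and held-out samples (per-row clr itself uses no cross-sample
# statistics)
fit_preprocessor <- function(train, max_zero_fraction = 0.5, which = "both",
                             base = exp(1)) {
  stats_for <- function(m) {
    keep <- colMeans(m == 0) <= max_zero_fraction
    fill <- vapply(seq_len(ncol(m)), function(j) {
      pos <- m[, j] > 0
      if (any(pos)) 0.5 * min(m[pos, j]) else NA_real_
    }, numeric(1))
    list(keep = keep, fill = fill)
  }
  list(microbial = stats_for(train$microbial),
       metabolite = stats_for(train$metabolite),
       which = which, base = base)
}

apply_preprocessor <- function(data, prep) {
  for (tab in c("microbial", "metabolite")) {
    m <- data[[tab]][, prep[[tab]]$keep, drop = FALSE]
    fill <- prep[[tab]]$fill[prep[[tab]]$keep]
    for (j in which(colSums(m == 0) > 0L)) {
      m[m[, j] == 0, j] <- fill[j]
    }
    do_clr <- prep$which == "both" || prep$which == tab
    data[[tab]] <- if (do_clr) clr_rows(m, prep$base) else m
    data$transformed[[tab]] <- if (do_clr) "clr" else "raw"
  }
  data
}

#' Stratified cross-validation of the mixture model
#'
#' Splits the dataset into label-stratified folds, and for each fold fits the
#' full pipeline on the training portion and evaluates on the held-out
#' portion. Feature filtering and zero-replacement statistics are computed
#' from the training fold only (the clr transform itself is per-sample).
#' Raw datasets are preprocessed per fold; already-transformed datasets are
#' used as-is.
#'
#' @param data A [paired_data] object (raw or preprocessed).
#' @param k Number of folds (default 5).
#' @param strategy Expert-allocation strategy.
#' @param config A [moe_config()].
#' @param seed Root seed (fold assignment, model fitting).
#' @param top_k,threshold Passed to [evaluate_predictions()].
#' @return A `cv_report`: tibble of per-fold metrics (`folds`), the fold
#'   assignment, and a `summary` tibble of mean +/- sd over folds.
#' @export
crossvalidate <- function(data, k = 5L, strategy = "phenotype",
                          config = moe_config(), seed = 1L,
                          top_k = c(10L, 50L), threshold = 0.5) {
  stopifnot(inherits(data, "paired_data"))
  folds <- stratified_folds(data$labels, k = k, seed = seed)
  k <- max(folds)
  raw <- all(data$transformed == "raw")
  fold_rows <- purrr::map_dfr(seq_len(k), function(f) {
    tr_idx <- which(folds != f); te_idx <- which(folds == f)
    subset_pd <- function(idx) {
      out <- data
      out$microbial <- data$microbial[idx, , drop = FALSE]
      out$metabolite <- data$metabolite[idx, , drop = FALSE]
      out$sample_ids <- data$sample_ids[idx]
      out$labels <- data$labels[idx]
      out
    }
    train <- subset_pd(tr_idx); test <- subset_pd(te_idx)
    if (raw) {
      prep <- fit_preprocessor(train)
      train <- apply_preprocessor(train, prep)
      test <- apply_preprocessor(test, prep)
    }
    fit <- fit_moe(train, strategy = strategy, config = config, seed = seed + f)
    pred <- predict(fit, test)
    rep <- evaluate_predictions(test$metabolite, pred$mean,
                                top_k = top_k, threshold = threshold)
    dplyr::mutate(glance(rep), fold = f, n_test = length(te_idx), .before = 1L)
  })
  metric_cols <- setdiff(names(fold_rows), c("fold", "n_test"))
  summary <- tidyr::pivot_longer(fold_rows[metric_cols], dplyr::everything(),
                                 names_to = "metric") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     sd = sd(.data$value, na.rm = TRUE), .groups = "drop")
  structure(list(folds = fold_rows, fold_assignment = folds,
                 summary = summary, k = k, strategy = strategy, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report> ", x$k, "-fold stratified CV, strategy = ", x$strategy,
      "\n", sep = "")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-24s %.3f +/- %.3f\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}

#' Per-fold metrics of a cross-validation run
#'
#' @param x A [crossvalidate()] result.
#' @param ... Unused.
#' @return The per-fold metrics tibble.
#' @method tidy cv_report
#' @export
tidy.cv_report <- function(x, ...) x$folds

#' Mean +/- sd summary of a cross-validation run
#'
#' @param x A [crossvalidate()] result.
#' @param ... Unused.
#' @return A tibble with one row per metric.
#' @method glance cv_report
#' @export
glance.cv_report <- function(x, ...) x$summary
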