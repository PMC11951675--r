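#' @title ARD feature relevance
#' @description The SE-ARD kernel assigns each microbial feature its own
#'   length scale; features that drive the metabolite profile are fitted with
#'   small length scales (large inverse length scales), irrelevant ones are
#'   down-weighted through large length scales. Ranking features by inverse
#'   length scale -- per expert -- yields a phenotype-specific relevance
#'   ordering.
#' @name interpret
NULL

relevance_one <- function(model, expert_name) {
  ls <- model$kernel$lengthscales
  feats <- model$feature_names
  tb <- tibble::tibble(expert = expert_name,
                       feature = feats,
                       lengthscale = ls,
                       inverse_lengthscale = 1 / ls)
  tb <- dplyr::arrange(tb, dplyr::desc(.data$inverse_lengthscale), .data$feature)
  dplyr::mutate(tb, rank = dplyr::row_number())
}

#' ARD feature-relevance ranking
#'
#' Computes per-expert inverse length scales `1 / l_i` and ranks features by
#' descending inverse length scale (ties broken lexicographically by feature
#' name, so the ordering is deterministic). Accepts a single fitted expert --
#' the pooled single-GP baseline ranking -- or a whole fitted mixture, which
#' yields one phenotype-specific ranking per expert.
#'
#' @param model A fitted `gp_expert` or `moe_gp`.
#' @return A tibble of class `feature_relevance` with columns `expert`,
#'   `feature`, `lengthscale`, `inverse_lengthscale`, `rank`.
#' @export
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
#' fit <- fit_gp_expert(X, cbind(X[, 1] + rnorm(20, sd = 0.1)), maxit = 40)
#' feature_relevance(fit)
feature_relevance <- function(model) {
  tb <- if (inherits(model, "gp_expert")) {
    relevance_one(model, model$label %||% "pooled")
  } else if (inherits(model, "moe_gp")) {
    purrr::map2_dfr(model$experts, seq_along(model$experts), function(ex, i) {
      relevance_one(ex, ex$label %||% paste0("expert", i))
    })
  } else {
    stop_moegpr("feature_relevance() expects a gp_expert or moe_gp")
  }
  class(tb) <- c("feature_relevance", class(tb))
  tb
}

#' Top-k most relevant features per expert
#'
#' @param relevance A [feature_relevance()] tibble.
#' @param k Number of features to keep per expert (default 10); must not
#'   exceed the number of features.
#' @return The filtered tibble (rank <= k), still ordered by rank within
#'   expert.
#' @export
top_features <- function(relevance, k = 10L) {
  stopifnot(inherits(relevance, "feature_relevance"))
  d <- max(relevance$rank)
  if (k < 1L || k > d) stop_moegpr("k must be between 1 and the number of features (", d, ")")
  dplyr::filter(relevance, .data$rank <= k)
}

#' Write a relevance ranking to TSV
#'
#' Columns: rank, feature, inverse_lengthscale, expert.
#'
#' @param relevance A [feature_relevance()] tibble.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_relevance <- function(relevance, path) {
  readr::write_tsv(dplyr::select(relevance, "rank", "feature",
                                 "inverse_lengthscale", "expert"), path)
  invisible(path)
}

#' Horizontal-bar relevance plot
#'
#' One panel per expert, features ordered by inverse length scale.
#'
#' @param object A [feature_relevance()] tibble.
#' @param k Number of top features per expert to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot feature_relevance
#' @export
autoplot.feature_relevance <- function(object, k = 10L, ...) {
  df <- top_features(object, min(k, max(object$rank)))
  ggplot2::ggplot(df, ggplot2::aes(
      x = .data$inverse_lengthscale,
      y = stats::reorder(interaction(.data$feature, .data$expert, drop = TRUE),
                         .data$inverse_lengthscale))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~expert, scales = "free_y") +
    ggplot2::scale_y_discrete(labels = function(l) sub("\\..*$", "", l)) +
    ggplot2::labs(x = "inverse length scale (1/l)", y = NULL) +
    ggplot2::theme_minimal()
}
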