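#' Construct a paired microbiome-metabolome dataset
#'
#' Bundles an aligned microbial abundance matrix, a metabolite abundance
#' matrix, and per-sample phenotype labels into a single object. Rows are
#' samples (shared order across both tables), columns are features. Both
#' tables start life as raw non-negative abundances; [clr_transform()] marks
#' them as transformed.
#'
#' @param microbial Numeric matrix or data frame, samples in rows, taxa in
#'   columns.
#' @param metabolite Numeric matrix or data frame, samples in rows,
#'   metabolites in columns, same row order as `microbial`.
#' @param labels Character or factor vector of per-sample phenotype labels
#'   (e.g. disease state), length `nrow(microbial)`.
#' @param sample_ids Optional character vector of sample identifiers; defaults
#'   to the row names, or `s1..sn`.
#' @param transformed Named character vector with elements `microbial` and
#'   `metabolite`, each `"raw"` or `"clr"`. Defaults to raw.
#'
#' @return An object of class `paired_data`: a list with elements
#'   `microbial`, `metabolite`, `sample_ids`, `labels`, `transformed`, and a
#'   `provenance` list recording preprocessing steps.
#' @export
#' @examples
#' mb <- matrix(rpois(12, 5), 4, 3, dimnames = list(NULL, paste0("taxon", 1:3)))
#' mt <- matrix(rpois(8, 5), 4, 2, dimnames = list(NULL, paste0("met", 1:2)))
#' pd <- paired_data(mb, mt, labels = c("H", "H", "D", "D"))
#' pd
paired_data <- function(microbial, metabolite, labels,
                        sample_ids = NULL,
                        transformed = c(microbial = "raw", metabolite = "raw")) {
  microbial <- as_num_matrix(microbial, "microbial table")
  metabolite <- as_num_matrix(metabolite, "metabolite table")
  if (nrow(microbial) != nrow(metabolite)) {
    stop_moegpr("microbial and metabolite tables must have the same number of samples (",
                nrow(microbial), " vs ", nrow(metabolite), ")")
  }
  n <- nrow(microbial)
  sample_ids <- sample_ids %||% rownames(microbial) %||% paste0("s", seq_len(n))
  if (length(sample_ids) != n) stop_moegpr("sample_ids length must equal the sample count")
  if (length(labels) != n) stop_moegpr("labels length must equal the sample count")
  if (anyNA(labels)) stop_moegpr("missing phenotype labels are not allowed")
  if (is.null(colnames(microbial))) colnames(microbial) <- paste0("taxon", seq_len(ncol(microbial)))
  if (is.null(colnames(metabolite))) colnames(metabolite) <- paste0("met", seq_len(ncol(metabolite)))
  rownames(microbial) <- rownames(metabolite) <- sample_ids
  transformed <- c(microbial = unname(transformed[["microbial"]]),
                   metabolite = unname(transformed[["metabolite"]]))
  for (tab in c("microbial", "metabolite")) {
    m <- if (tab == "microbial") microbial else metabolite
    if (!all(is.finite(m))) stop_moegpr("non-finite value in ", tab, " table")
    if (transformed[[tab]] == "raw" && any(m < 0)) {
      stop_moegpr("raw ", tab, " abundances must be non-negative")
    }
  }
  structure(
    list(microbial = microbial, metabolite = metabolite,
         sample_ids = as.character(sample_ids), labels = as.character(labels),
         transformed = transformed, provenance = list()),
    class = "paired_data"
  )
}

#' @export
print.paired_data <- function(x, ...) {
  cat("<paired_data> ", length(x$sample_ids), " samples\n", sep = "")
  cat("  microbial:  ", ncol(x$microbial), " features (", x$transformed[["microbial"]], ")\n", sep = "")
  cat("  metabolite: ", ncol(x$metabolite), " features (", x$transformed[["metabolite"]], ")\n", sep = "")
  tab <- table(x$labels)
  cat("  labels:     ", paste0(names(tab), "=", tab, collapse = ", "), "\n", sep = "")
  if (length(x$provenance)) {
    cat("  steps:      ", paste(vapply(x$provenance, `[[`, "", "step"), collapse = " -> "), "\n", sep = "")
  }
  invisible(x)
}

#' Coerce a paired dataset to a tibble
#'
#' Returns one table in long-friendly wide form: a `sample_id` column, the
#' phenotype `label`, then one column per feature.
#'
#' @param x A [paired_data] object.
#' @param table Which table to extract, `"microbial"` or `"metabolite"`.
#' @param ... Unused.
#' @return A tibble with `n` rows.
#' @method as_tibble paired_data
#' @export
as_tibble.paired_data <- function(x, table = c("microbial", "metabolite"), ...) {
  table <- match.arg(table)
  tibble::as_tibble(as.data.frame(x[[table]])) |>
    dplyr::mutate(sample_id = x$sample_ids, label = x$labels, .before = 1L)
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

read_delim_table <- function(path, delim = NULL) {
  if (!file.exists(path)) stop_moegpr("file not found: ", path)
  delim <- delim %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE, trim_ws = TRUE)
  if (ncol(df) < 2L) stop_moegpr("table ", path, " needs a sample-ID column plus data columns")
  df
}

table_to_matrix <- function(df, path, transpose = FALSE) {
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1L], is.numeric, logical(1)))[1L]
    cell <- which(is.na(suppressWarnings(as.numeric(df[[bad + 1L]]))))[1L]
    stop_moegpr("non-numeric abundance value in ", path,
                " (row ", cell %||% NA, ", column '", names(df)[bad + 1L], "')")
  }
  rownames(m) <- ids
  if (transpose) m <- t(m)
  m
}

#' Read paired abundance tables and sample metadata
#'
#' Reads a microbial table, a metabolite table and a metadata table
#' (TSV or CSV; first column sample IDs, header row feature/metadata names),
#' restricts all three to their common samples, aligns row order, and returns
#' a [paired_data] object. Samples missing from any file are dropped with a
#' warning.
#'
#' @param microbial_path,metabolite_path,metadata_path File paths.
#' @param label_column Name of the metadata column holding phenotype labels.
#' @param delim Field delimiter; `NULL` guesses from the extension
#'   (`.csv` = comma, otherwise tab).
#' @param transpose If `TRUE`, abundance tables are stored features-in-rows
#'   and transposed on read.
#' @return A [paired_data] object.
#' @export
read_paired_tables <- function(microbial_path, metabolite_path, metadata_path,
                               label_column = "label", delim = NULL,
                               transpose = FALSE) {
  mb <- table_to_matrix(read_delim_table(microbial_path, delim), microbial_path, transpose)
  mt <- table_to_matrix(read_delim_table(metabolite_path, delim), metabolite_path, transpose)
  meta <- read_delim_table(metadata_path, delim)
  if (!label_column %in% names(meta)) {
    stop_moegpr("label column '", label_column, "' not found in ", metadata_path)
  }
  meta_ids <- as.character(meta[[1L]])
  labels <- as.character(meta[[label_column]])
  keep_meta <- !is.na(labels)
  common <- Reduce(intersect, list(rownames(mb), rownames(mt), meta_ids[keep_meta]))
  if (length(common) == 0L) stop_moegpr("no overlapping samples across the three tables")
  n_union <- length(unique(c(rownames(mb), rownames(mt), meta_ids)))
  if (length(common) < n_union) {
    warning(n_union - length(common), " sample(s) absent from at least one table were dropped",
            call. = FALSE)
  }
  labels <- labels[match(common, meta_ids)]
  paired_data(mb[common, , drop = FALSE], mt[common, , drop = FALSE],
              labels = labels, sample_ids = common)
}

add_provenance <- function(data, step, ...) {
  data$provenance <- c(data$provenance, list(c(list(step = step), list(...))))
  data
}

#' Remove sparse features from both tables
#'
#' Drops every microbial and metabolite feature whose fraction of zero
#' abundances exceeds `max_zero_fraction` (strictly greater than; a feature
#' with exactly that fraction of zeros is retained). Must be applied to raw
#' tables, before zero replacement.
#'
#' @param data A raw [paired_data] object.
#' @param max_zero_fraction Maximum tolerated zero fraction per feature
#'   (default 0.5: features with more than half their values zero are removed).
#' @return The filtered [paired_data].
#' @export
filter_sparse_features <- function(data, max_zero_fraction = 0.5) {
  stopifnot(inherits(data, "paired_data"))
  raw_tabs <- names(data$transformed)[data$transformed == "raw"]
  if (length(raw_tabs) == 0L) {
    stop_moegpr("filter_sparse_features() requires raw tables (apply before clr_transform)")
  }
  removed <- integer(2); names(removed) <- c("microbial", "metabolite")
  for (tab in raw_tabs) {
    zf <- colMeans(data[[tab]] == 0)
    keep <- zf <= max_zero_fraction
    removed[[tab]] <- sum(!keep)
    if (!any(keep)) {
      stop_moegpr("all ", ncol(data[[tab]]), " ", tab, " features exceed the ",
                  max_zero_fraction, " zero-fraction threshold")
    }
    data[[tab]] <- data[[tab]][, keep, drop = FALSE]
  }
  add_provenance(data, "filter_sparse_features",
                 max_zero_fraction = max_zero_fraction,
                 removed_microbial = removed[["microbial"]],
                 removed_metabolite = removed[["metabolite"]])
}

#' Replace zero abundances with small positive values
#'
#' Compositional log-ratio transforms require strictly positive entries; this
#' replaces zeros feature by feature, leaving nonzero entries untouched.
#'
#' @param data A raw [paired_data] object.
#' @param rule `"half-min"` (default): each zero becomes half the smallest
#'   positive value of its feature (scale-aware multiplicative-replacement
#'   convention); `"fixed"`: each zero becomes `epsilon`.
#' @param epsilon Replacement value for `rule = "fixed"`.
#' @return A [paired_data] with all entries strictly positive.
#' @export
replace_zeros <- function(data, rule = c("half-min", "fixed"), epsilon = 1e-6) {
  stopifnot(inherits(data, "paired_data"))
  rule <- match.arg(rule)
  raw_tabs <- names(data$transformed)[data$transformed == "raw"]
  if (length(raw_tabs) == 0L) {
    stop_moegpr("replace_zeros() requires raw tables")
  }
  for (tab in raw_tabs) {
    m <- data[[tab]]
    zero_cols <- which(colSums(m == 0) > 0L)
    for (j in zero_cols) {
      pos <- m[, j] > 0
      if (!any(pos)) {
        stop_moegpr("feature '", colnames(m)[j], "' in the ", tab,
                    " table is entirely zero; run filter_sparse_features() first")
      }
      fill <- if (rule == "half-min") 0.5 * min(m[pos, j]) else epsilon
      m[!pos, j] <- fill
    }
    data[[tab]] <- m
  }
  add_provenance(data, "replace_zeros", rule = rule,
                 epsilon = if (rule == "fixed") epsilon else NA_real_)
}

clr_rows <- function(m, base) {
  lm <- log(m, base = base)
  sweep(lm, 1L, rowMeans(lm), `-`)
}

#' Centered log-ratio transform
#'
#' Replaces each selected row x by `log(x_j / geometric_mean(x))`, the
#' standard normalization for compositional abundance data; transformed rows
#' sum to zero. All entries must be strictly positive (see [replace_zeros()]).
#'
#' @param data A [paired_data] object with positive raw tables.
#' @param which Which table(s) to transform: `"both"` (default),
#'   `"microbial"` or `"metabolite"`.
#' @param base Logarithm base; natural log by default (base 10 available for
#'   cross-checks -- the ratio structure, and all rank-based metrics, are
#'   unaffected by the base).
#' @return The transformed [paired_data]; the `transformed` flags record
#'   which tables are on the clr scale.
#' @export
clr_transform <- function(data, which = c("both", "microbial", "metabolite"),
                          base = exp(1)) {
  stopifnot(inherits(data, "paired_data"))
  which <- match.arg(which)
  tabs <- if (which == "both") c("microbial", "metabolite") else which
  for (tab in tabs) {
    if (data$transformed[[tab]] != "raw") next
    m <- data[[tab]]
    if (any(m <= 0)) {
      stop_moegpr("non-positive entries in the ", tab,
                  " table; run replace_zeros() before clr_transform()")
    }
    data[[tab]] <- clr_rows(m, base)
    data$transformed[[tab]] <- "clr"
  }
  add_provenance(data, "clr_transform", which = which, base = base)
}

#' Standard preprocessing pipeline
#'
#' Convenience wrapper chaining [filter_sparse_features()], [replace_zeros()]
#' and [clr_transform()] with the package defaults.
#'
#' @inheritParams filter_sparse_features
#' @inheritParams replace_zeros
#' @inheritParams clr_transform
#' @return A preprocessed [paired_data].
#' @export
preprocess_paired <- function(data, max_zero_fraction = 0.5,
                              rule = "half-min", epsilon = 1e-6,
                              which = "both", base = exp(1)) {
  data |>
    filter_sparse_features(max_zero_fraction) |>
    replace_zeros(rule = rule, epsilon = epsilon) |>
    clr_transform(which = which, base = base)
}

#' Write a paired dataset to disk
#'
#' Writes the microbial table, metabolite table and metadata as delimited
#' text (same dialect [read_paired_tables()] reads) plus a key-value
#' provenance sidecar recording the preprocessing applied.
#'
#' @param data A [paired_data] object.
#' @param dir Output directory (created if needed).
#' @param delim Field delimiter (default tab).
#' @return Invisibly, a named character vector of the four file paths.
#' @export
write_paired_tables <- function(data, dir, delim = "\t") {
  stopifnot(inherits(data, "paired_data"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (delim == ",") "csv" else "tsv"
  paths <- file.path(dir, paste0(c("microbial", "metabolite", "metadata", "provenance"),
                                 c(rep(paste0(".", ext), 3), ".txt")))
  names(paths) <- c("microbial", "metabolite", "metadata", "provenance")
  for (tab in c("microbial", "metabolite")) {
    df <- data.frame(sample_id = data$sample_ids, data[[tab]], check.names = FALSE)
    readr::write_delim(df, paths[[tab]], delim = delim)
  }
  readr::write_delim(data.frame(sample_id = data$sample_ids, label = data$labels),
                     paths[["metadata"]], delim = delim)
  prov <- c(paste0("transformed_microbial=", data$transformed[["microbial"]]),
            paste0("transformed_metabolite=", data$transformed[["metabolite"]]),
            unlist(lapply(data$provenance, function(p) {
              paste0(p$step, ".", names(p)[-1], "=", unlist(p[-1]))
            })))
  writeLines(prov, paths[["provenance"]])
  invisible(paths)
}
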