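# Independent dense-linear-algebra oracles used to cross-check the package's
# cached-factorization implementations. Deliberately naive: solve() on the
# full covariance, closed-form rank formulas, explicit enumeration.

oracle_gp_predict <- function(X, Y, params, noise, Xs, jitter = 0) {
  A <- kernel_matrix(X, params = params) + diag(noise + jitter, nrow(X))
  Kx <- kernel_matrix(Xs, X, params = params)
  mean <- Kx %*% solve(A, Y)
  var <- params$variance - diag(Kx %*% solve(A, t(Kx)))
  list(mean = mean, variance = var)
}

oracle_nlml <- function(X, y, params, noise, jitter = 0) {
  n <- nrow(X)
  A <- kernel_matrix(X, params = params) + diag(noise + jitter, n)
  0.5 * drop(t(y) %*% solve(A, y)) +
    0.5 * as.numeric(determinant(A, logarithm = TRUE)$modulus) +
    0.5 * n * log(2 * pi)
}

# no-ties closed form 1 - 6 sum(d^2) / (n (n^2 - 1))
oracle_spearman_noties <- function(a, b) {
  n <- length(a)
  1 - 6 * sum((rank(a) - rank(b))^2) / (n * (n^2 - 1))
}

# brute-force mixture moments by explicit enumeration over experts, one
# sample/metabolite at a time
oracle_mixture_moments <- function(w, f, v) {
  mu <- sum(w * f)
  list(mean = mu, variance = sum(w * (v + (f - mu)^2)))
}

rand_paired_files <- function(dir, ids_mb, ids_mt, ids_meta, d = 3, m = 2,
                              labels = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(ids, k, prefix, path) {
    df <- data.frame(sample_id = ids,
                     matrix(seq_len(length(ids) * k), length(ids), k,
                            dimnames = list(NULL, paste0(prefix, seq_len(k)))))
    readr::write_tsv(df, path)
  }
  wr(ids_mb, d, "taxon", file.path(dir, "microbial.tsv"))
  wr(ids_mt, m, "met", file.path(dir, "metabolite.tsv"))
  labels <- labels %||% rep(c("H", "D"), length.out = length(ids_meta))
  readr::write_tsv(data.frame(sample_id = ids_meta, label = labels),
                   file.path(dir, "metadata.tsv"))
  file.path(dir, c("microbial.tsv", "metabolite.tsv", "metadata.tsv"))
}

`%||%` <- rlang::`%||%`
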