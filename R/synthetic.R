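#' @title Synthetic paired microbiome-metabolome data
#' @description Generates paired abundance tables with known ground truth:
#'   zero-inflated compositional taxa profiles, and metabolite profiles
#'   driven by a small causal subset of taxa through group-specific smooth
#'   maps (linear, sinusoidal, or a draw from an SE-ARD GP) plus Gaussian
#'   noise. Every pipeline stage -- filtering, zero replacement, clr, expert
#'   allocation, gating, ARD ranking, calibration -- can be tested against
#'   the recorded truth without any external download.
#' @name synthetic
NULL

#' Specification for a synthetic paired dataset
#'
#' @param n_per_group Integer vector of per-group sample counts.
#' @param d Number of taxa.
#' @param m Number of metabolites.
#' @param s Number of causal taxa per group (ignored when `causal_sets`
#'   given).
#' @param groups Group (phenotype) names; default `g1..gG`.
#' @param causal_sets Optional list of causal taxon index vectors, one per
#'   group; default draws `s` distinct taxa per group.
#' @param mapping Taxa-to-metabolite map per group: `"linear"`,
#'   `"sin"` or `"gp"` (a function drawn from an SE-ARD GP with short length
#'   scales on the causal dimensions and effectively infinite ones
#'   elsewhere -- the exactly well-specified case). Recycled across groups.
#' @param opposing If `TRUE`, all groups share one linear coefficient matrix
#'   with alternating sign, giving deliberately conflicting taxa-metabolite
#'   maps across groups.
#' @param noise_sd Standard deviation of the additive Gaussian noise on the
#'   latent metabolite signal (default 0.1).
#' @param group_shift Scale of the per-taxon group mean shifts (default 1).
#'   Small values give phenotype clusters that overlap heavily per dimension
#'   (heterogeneity not visible to a stationary kernel metric), large values
#'   give well-separated clusters.
#' @param zero_inflation Target overall fraction of zero taxa counts
#'   (default 0.3); a fifth of the non-causal taxa receive an elevated zero
#'   probability so that the sparse-feature filter has work to do.
#' @param metabolite_scale `"abundance"` (default): metabolite tables are
#'   `exp(latent)`, positive abundances that feed the full clr pipeline;
#'   `"latent"`: the latent values are used directly and the table is marked
#'   as already transformed (used for calibration studies where the GP model
#'   is exactly well-specified).
#' @param causal_lengthscale,irrelevant_lengthscale GP-map length scales for
#'   causal and non-causal dimensions (`mapping = "gp"`).
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(n_per_group = c(50L, 50L), d = 30L, m = 20L, s = 3L,
                       groups = NULL, causal_sets = NULL,
                       mapping = "linear", opposing = FALSE,
                       noise_sd = 0.1, zero_inflation = 0.3, group_shift = 1,
                       metabolite_scale = c("abundance", "latent"),
                       causal_lengthscale = 2, irrelevant_lengthscale = 1e6,
                       seed = 1L) {
  G <- length(n_per_group)
  groups <- groups %||% paste0("g", seq_len(G))
  stopifnot(length(groups) == G, d >= 1L, m >= 1L, all(n_per_group >= 1L))
  if (is.null(causal_sets)) {
    if (s > d) stop_moegpr("cannot pick ", s, " causal taxa out of ", d)
    causal_sets <- withr::with_seed(seed, {
      lapply(seq_len(G), function(g) sort(sample.int(d, s)))
    })
  }
  lapply(causal_sets, function(cs) {
    if (any(cs < 1L | cs > d)) stop_moegpr("causal taxon index out of range 1..", d)
  })
  mapping <- rep_len(mapping, G)
  stopifnot(all(mapping %in% c("linear", "sin", "gp")))
  structure(list(n_per_group = as.integer(n_per_group), d = as.integer(d),
                 m = as.integer(m), groups = groups, causal_sets = causal_sets,
                 mapping = mapping, opposing = opposing, noise_sd = noise_sd,
                 zero_inflation = zero_inflation, group_shift = group_shift,
                 metabolite_scale = match.arg(metabolite_scale),
                 causal_lengthscale = causal_lengthscale,
                 irrelevant_lengthscale = irrelevant_lengthscale,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

# draw m function values at X from a zero-mean GP with SE-ARD kernel
gp_draw <- function(X, lengthscales, m) {
  K <- kernel_matrix(X, params = ard_params(1, lengthscales), jitter = 1e-8)
  t(chol(K)) %*% matrix(rnorm(nrow(X) * m), nrow(X), m)
}

#' Generate a synthetic paired dataset
#'
#' See [synth_spec()] for the generative model. Taxa log-abundances are
#' Gaussian around group-specific means, exponentiated, zero-masked, and
#' closed to relative abundances; the latent metabolite signal is the
#' group's map applied to the clr-transformed causal taxa, plus noise.
#'
#' @param spec A [synth_spec()].
#' @return A list with `data` (a [paired_data]) and `truth` (causal sets,
#'   map coefficients or GP draws, latent signal, group assignment).
#' @export
#' @examples
#' out <- generate_paired(synth_spec(n_per_group = c(20, 20), d = 10, m = 5, seed = 7))
#' out$data
generate_paired <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  G <- length(spec$groups); d <- spec$d; m <- spec$m
  n <- sum(spec$n_per_group)
  group_of <- rep(seq_len(G), spec$n_per_group)
  withr::with_seed(spec$seed, {
    mu <- spec$group_shift * matrix(rnorm(G * d), G, d)
    Z <- mu[group_of, , drop = FALSE] + matrix(rnorm(n * d), n, d)
    raw <- exp(Z)
    zi <- spec$zero_inflation
    if (zi > 0) {
      causal_all <- unique(unlist(spec$causal_sets))
      eligible <- setdiff(seq_len(d), causal_all)
      n_rare <- min(length(eligible), max(1L, round(0.2 * d)))
      rare <- if (n_rare > 0L) sample(eligible, n_rare) else integer(0)
      p_hi <- min(0.9, zi + 0.4)
      p_lo <- max(0, (zi * d - length(rare) * p_hi) / (d - length(rare)))
      pz <- rep(p_lo, d); pz[rare] <- p_hi
      mask <- matrix(rbinom(n * d, 1L, rep(pz, each = n)), n, d) == 1L
      raw[mask] <- 0
    }
    comp <- raw / pmax(rowSums(raw), .Machine$double.eps)
    # latent clr inputs used by the taxa -> metabolite maps (half-min zero
    # replacement, natural log)
    filled <- comp
    for (j in seq_len(d)) {
      pos <- filled[, j] > 0
      if (!all(pos)) {
        filled[!pos, j] <- if (any(pos)) 0.5 * min(filled[pos, j]) else 1e-9
      }
    }
    Xclr <- clr_rows(filled, exp(1))

    signal <- matrix(0, n, m)
    coefs <- vector("list", G)
    for (g in seq_len(G)) {
      rows <- which(group_of == g)
      cs <- spec$causal_sets[[g]]
      Xc <- Xclr[rows, cs, drop = FALSE]
      if (spec$mapping[g] == "gp") {
        ls <- rep(spec$irrelevant_lengthscale, d)
        ls[cs] <- spec$causal_lengthscale
        signal[rows, ] <- gp_draw(Xclr[rows, , drop = FALSE], ls, m)
        coefs[[g]] <- list(type = "gp", lengthscales = ls)
      } else {
        B <- if (spec$opposing && g > 1L) {
          (-1)^(g - 1L) * coefs[[1L]]$B
        } else {
          matrix(rnorm(length(cs) * m), length(cs), m) / sqrt(length(cs))
        }
        signal[rows, ] <- if (spec$mapping[g] == "sin") sin(1.5 * Xc %*% B) else Xc %*% B
        coefs[[g]] <- list(type = spec$mapping[g], B = B)
      }
    }
    latent <- signal + spec$noise_sd * matrix(rnorm(n * m), n, m)
    met <- if (spec$metabolite_scale == "abundance") exp(latent) else latent
    taxa_names <- sprintf("taxon%02d", seq_len(d))
    met_names <- sprintf("met%02d", seq_len(m))
    colnames(comp) <- taxa_names; colnames(met) <- met_names
    data <- paired_data(
      comp, met, labels = spec$groups[group_of],
      sample_ids = sprintf("s%03d", seq_len(n)),
      transformed = c(microbial = "raw",
                      metabolite = if (spec$metabolite_scale == "latent") "clr" else "raw"))
    list(data = data,
         truth = list(spec = spec, causal_sets = spec$causal_sets,
                      coefs = coefs, signal = signal, latent = latent,
                      clr_inputs = Xclr, group = group_of))
  })
}

#' Named fixture presets
#'
#' Canned [synth_spec()] configurations used throughout the test suite:
#'
#' * `tiny` -- 20 samples, 8 taxa, 4 metabolites, 2 groups; smoke tests.
#' * `ard` -- 150 samples, 30 taxa of which 3 causal, GP map; relevance
#'   recovery.
#' * `heterogeneous` -- 2 groups of 60 with disjoint causal sets and
#'   opposing linear maps; expert-allocation comparisons.
#' * `calibration` -- 160 samples, latent-scale metabolites drawn from the
#'   GP the model assumes; interval-coverage checks.
#'
#' @param name Preset name.
#' @param dir Optional directory; when given, the three input tables (plus
#'   provenance) are written there in the dialect [read_paired_tables()]
#'   reads. Latent-scale metabolite values are exponentiated on disk so the
#'   written table is a valid raw abundance table.
#' @param seed Seed passed to the spec.
#' @return A list with `spec`, `data`, `truth`, and (if `dir` given) `paths`.
#' @export
make_fixture <- function(name = c("tiny", "ard", "heterogeneous", "calibration"),
                         dir = NULL, seed = 1L) {
  name <- match.arg(name)
  spec <- switch(name,
    tiny = synth_spec(n_per_group = c(10L, 10L), d = 8L, m = 4L, s = 2L,
                      groups = c("healthy", "disease"), mapping = "linear",
                      noise_sd = 0.1, zero_inflation = 0.3, seed = seed),
    ard = synth_spec(n_per_group = 150L, d = 30L, m = 5L, s = 3L,
                     groups = "all", mapping = "gp", noise_sd = 0.1,
                     zero_inflation = 0.25, seed = seed),
    heterogeneous = {
      cs <- withr::with_seed(seed, {
        perm <- sample.int(20L)
        list(sort(perm[1:3]), sort(perm[4:6]))
      })
      synth_spec(n_per_group = c(60L, 60L), d = 20L, m = 8L,
                 groups = c("healthy", "disease"), causal_sets = cs,
                 mapping = "sin", opposing = TRUE, noise_sd = 0.2,
                 zero_inflation = 0.25, group_shift = 0.6, seed = seed)
    },
    calibration = synth_spec(n_per_group = 160L, d = 10L, m = 5L, s = 3L,
                             groups = "all", mapping = "gp", noise_sd = 0.3,
                             zero_inflation = 0, metabolite_scale = "latent",
                             seed = seed))
  out <- generate_paired(spec)
  if (!is.null(dir)) {
    disk <- out$data
    if (spec$metabolite_scale == "latent") {
      disk$metabolite <- exp(disk$metabolite)
      disk$transformed[["metabolite"]] <- "raw"
    }
    out$paths <- write_paired_tables(disk, dir)
  }
  c(list(spec = spec), out)
}
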