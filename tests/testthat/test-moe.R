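test_that("expert allocation strategies partition samples as specified", {
  labels <- c("A", "A", "B", "B", "B")

  ph <- allocate_experts(labels, "phenotype", min_block = 1)
  expect_length(ph$partition, 2L)
  expect_identical(lengths(ph$partition), c(2L, 3L))
  expect_identical(ph$expert_labels, c("A", "B"))
  expect_identical(ph$partition[[1]], c(1L, 2L))

  db <- allocate_experts(labels, "double", seed = 1, min_block = 1)
  expect_length(db$partition, 4L)
  expect_identical(sort(unlist(db$partition)), 1:5)       # disjoint cover
  expect_identical(lengths(db$partition)[1:2], c(1L, 1L)) # A halved
  expect_setequal(lengths(db$partition)[3:4], c(2L, 1L))  # B halved, diff <= 1

  rd <- allocate_experts(labels, "random", seed = 1, min_block = 1)
  expect_length(rd$partition, 2L)                         # L = n distinct labels
  expect_setequal(lengths(rd$partition), c(3L, 2L))
  expect_identical(sort(unlist(rd$partition)), 1:5)
  rd2 <- allocate_experts(labels, "random", seed = 1, min_block = 1)
  expect_identical(rd$partition, rd2$partition)

  expect_warning(allocate_experts(labels, "phenotype", min_block = 5), "fewer than")
})

test_that("mixture moments match the hand case and brute-force enumeration", {
  # w = (1/2, 1/2), f = (0, 2), v = (1, 1): mu = 1, sigma^2 = 2
  mo <- mixture_moments(matrix(c(0.5, 0.5), 1),
                        list(matrix(0), matrix(2)),
                        list(matrix(1), matrix(1)))
  expect_equal(mo$mean[1, 1], 1)
  expect_equal(mo$variance[1, 1], 2)

  withr::with_seed(13, {
    for (rep in 1:20) {
      L <- sample(2:5, 1)
      w <- matrix(rexp(L), 1); w <- w / sum(w)
      f <- rnorm(L); v <- rexp(L)
      got <- mixture_moments(w, lapply(f, matrix), lapply(v, matrix))
      want <- oracle_mixture_moments(drop(w), f, v)
      expect_equal(got$mean[1, 1], want$mean, tolerance = 1e-10)
      expect_equal(got$variance[1, 1], want$variance, tolerance = 1e-10)
    }
  })

  # identical expert means: the between-expert spread term vanishes
  mo2 <- mixture_moments(matrix(c(0.3, 0.7), 1),
                         list(matrix(1.5), matrix(1.5)),
                         list(matrix(0.4), matrix(0.9)))
  expect_equal(mo2$variance[1, 1], 0.3 * 0.4 + 0.7 * 0.9)
})

test_that("moment-matched variance agrees with hierarchical sampling", {
  w <- c(0.2, 0.5, 0.3); f <- c(-1, 0.5, 2); v <- c(0.3, 1, 0.1)
  mo <- oracle_mixture_moments(w, f, v)
  withr::with_seed(17, {
    n <- 1e5
    comp <- sample.int(3, n, replace = TRUE, prob = w)
    draws <- rnorm(n, f[comp], sqrt(v[comp]))
  })
  # MC standard error of a sample variance ~ sqrt((m4 - var^2)/n)
  m4 <- mean((draws - mean(draws))^4)
  se <- sqrt((m4 - mo$variance^2) / length(draws))
  expect_lt(abs(var(draws) - mo$variance), 3 * se)
})

fit_tiny_moe <- function(seed = 1, strategy = "phenotype", ...) {
  fx <- make_fixture("tiny", seed = seed)
  pd <- preprocess_paired(fx$data)
  cfg <- modifyList(moe_config(gating_steps = 60, gp_maxit = 25, min_block = 2),
                    list(...))
  list(pd = pd, fit = fit_moe(pd, strategy = strategy, config = cfg, seed = seed))
}

test_that("a single-expert mixture reduces exactly to its GP expert", {
  fx <- make_fixture("tiny", seed = 2)
  pd <- preprocess_paired(fx$data)
  pd$labels <- rep("all", length(pd$labels))
  fit <- fit_moe(pd, config = moe_config(gating_steps = 50, gp_maxit = 25), seed = 2)
  expect_length(fit$experts, 1L)
  pr <- predict(fit, pd)
  single <- predict(fit$experts[[1]], pd$microbial, include_noise = TRUE)
  expect_equal(unname(pr$mean), unname(single$mean))
  expect_equal(unname(pr$variance), unname(single$variance))
  expect_true(all(pr$expert_weights == 1))
})

test_that("zero gating steps leave a freshly initialized gate but fitted experts", {
  out <- fit_tiny_moe(seed = 3, gating_steps = 0)
  expect_identical(out$fit$gating_steps_run, 0L)
  expect_length(out$fit$experts, 2L)
  expect_s3_class(out$fit$experts[[1]], "gp_expert")
  ref <- gating_init(ncol(out$pd$microbial), 2L,
                     hidden = out$fit$config$hidden,
                     dropout_rate = out$fit$config$dropout_rate, seed = 3)
  expect_identical(out$fit$gating$layers, ref$layers)
})

test_that("mixture predictions obey the variance decomposition bounds", {
  out <- fit_tiny_moe(seed = 4)
  pr <- predict(out$fit, out$pd)
  expect_lt(max(abs(rowSums(pr$expert_weights) - 1)), 1e-9)
  # sigma^2 >= sum_l w_l v_l elementwise (spread term non-negative)
  within <- matrix(0, nrow(pr$mean), ncol(pr$mean))
  for (l in seq_along(out$fit$experts)) {
    within <- within + pr$expert_weights[, l] * pr$per_expert[[l]]$variance
  }
  expect_true(all(pr$variance >= within - 1e-12))
})

test_that("gating routes samples of each group to that group's expert", {
  wins <- 0L
  for (seed in 1:3) {
    fx <- make_fixture("heterogeneous", seed = seed)
    pd <- preprocess_paired(fx$data)
    fit <- fit_moe(pd, config = moe_config(gating_steps = 200, gp_maxit = 40),
                   seed = seed)
    pr <- predict(fit, pd)
    own <- vapply(seq_along(pd$labels), function(i) {
      pr$expert_weights[i, match(pd$labels[i], fit$allocation$expert_labels)]
    }, numeric(1))
    wins <- wins + (mean(own) > 0.5)
  }
  expect_gte(wins, 2L)
})

test_that("credible intervals follow mu +/- k sigma", {
  pred <- structure(list(mean = matrix(1), variance = matrix(4),
                         expert_weights = matrix(1), per_expert = list()),
                    class = "moe_prediction")
  ci <- credible_interval(pred, 2)
  expect_equal(ci$lower[1, 1], -3)
  expect_equal(ci$upper[1, 1], 5)
  pred$variance <- matrix(0)
  ci0 <- credible_interval(pred, 2)
  expect_equal(ci0$lower, ci0$upper)
  expect_equal(ci0$lower, pred$mean)
})

test_that("models round-trip through the JSON archive with identical predictions", {
  out <- fit_tiny_moe(seed = 6)
  path <- withr::local_tempfile(fileext = ".json")
  write_moe_model(out$fit, path)
  back <- read_moe_model(path)
  pr1 <- predict(out$fit, out$pd)
  pr2 <- predict(back, out$pd)
  expect_equal(pr1$mean, pr2$mean, tolerance = 1e-12)
  expect_equal(pr1$variance, pr2$variance, tolerance = 1e-12)
  expect_equal(pr1$expert_weights, pr2$expert_weights, tolerance = 1e-12)
  expect_identical(back$allocation$strategy, "phenotype")
})

test_that("tidy/glance/autoplot summarize fitted mixtures", {
  out <- fit_tiny_moe(seed = 7)
  td <- tidy(out$fit)
  expect_identical(nrow(td), 2L)
  expect_true(all(c("expert", "nlml", "noise_variance") %in% names(td)))
  gl <- glance(out$fit)
  expect_identical(gl$n_experts, 2L)
  pr <- predict(out$fit, out$pd)
  long <- tidy(pr)
  expect_identical(nrow(long), nrow(pr$mean) * ncol(pr$mean))
  expect_true(all(long$lower <= long$upper))
  p <- ggplot2::autoplot(pr, observed = out$pd$metabolite, metabolite = 1)
  expect_s3_class(p, "ggplot")
})

test_that("joint refinement rounds keep a valid model", {
  out <- fit_tiny_moe(seed = 8, joint_rounds = 1L)
  pr <- predict(out$fit, out$pd)
  expect_true(all(is.finite(pr$mean)))
  expect_true(all(pr$variance >= 0))
})
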