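rand_problem <- function(n, d, m, seed) {
  withr::with_seed(seed, {
    list(X = matrix(rnorm(n * d), n, d),
         Y = matrix(rnorm(n * m), n, m),
         params = ard_params(exp(runif(1, -1, 1)), exp(runif(d, -0.7, 0.7))),
         noise = exp(runif(1, -3, -0.5)))
  })
}

test_that("posterior prediction and NLML match the dense oracle", {
  for (seed in 1:8) {
    pr <- rand_problem(sample(5:30, 1), sample(1:5, 1), 2, seed)
    mod <- gp_expert(pr$X, pr$Y, pr$params, pr$noise)
    Xs <- matrix(rnorm(4 * ncol(pr$X)), 4, ncol(pr$X))
    got <- predict(mod, Xs)
    want <- oracle_gp_predict(pr$X, pr$Y, pr$params, pr$noise, Xs, mod$jitter)
    expect_equal(unname(got$mean), unname(want$mean), tolerance = 1e-8)
    expect_equal(unname(got$variance[, 1]), unname(want$variance), tolerance = 1e-8)
    expect_equal(gp_nlml(mod, 1),
                 oracle_nlml(pr$X, pr$Y[, 1], pr$params, pr$noise, mod$jitter),
                 tolerance = 1e-8)
  }
})

test_that("one-point NLML equals its closed form", {
  # k(x,x) + noise = 1, y = 0: only the 0.5 log(2 pi) term remains
  mod <- gp_expert(matrix(0, 1, 1), matrix(0, 1, 1), ard_params(0.5, 1), 0.5)
  expect_equal(gp_nlml(mod), 0.5 * log(2 * pi), tolerance = 1e-6)
})

test_that("doubling the targets quadruples the NLML quadratic form", {
  pr <- rand_problem(12, 3, 1, 21)
  m1 <- gp_expert(pr$X, pr$Y, pr$params, pr$noise)
  m2 <- gp_expert(pr$X, 2 * pr$Y, pr$params, pr$noise)
  quad <- function(m) 0.5 * sum(m$Y * m$alpha)
  expect_equal(quad(m2), 4 * quad(m1), tolerance = 1e-10)
})

test_that("posterior interpolates at vanishing noise and reverts to the prior far away", {
  pr <- rand_problem(10, 2, 1, 5)
  mod <- gp_expert(pr$X, pr$Y, pr$params, 1e-8)
  at_train <- predict(mod, pr$X)
  expect_equal(unname(at_train$mean), unname(pr$Y), tolerance = 1e-4)
  expect_lt(max(at_train$variance), 1e-4)

  far <- matrix(1e4, 1, 2)
  out <- predict(mod, far)
  expect_lt(abs(out$mean[1, 1]), 1e-8)
  expect_equal(unname(out$variance[1, 1]), pr$params$variance, tolerance = 1e-8)
})

test_that("posterior variance never exceeds the prior variance", {
  for (seed in 1:5) {
    pr <- rand_problem(15, 3, 1, seed + 100)
    mod <- gp_expert(pr$X, pr$Y, pr$params, pr$noise)
    Xs <- matrix(rnorm(30), 10, 3)
    expect_true(all(predict(mod, Xs)$variance <= pr$params$variance + 1e-12))
  }
})

test_that("conditioning on an extra observation never increases posterior variance", {
  pr <- rand_problem(12, 2, 1, 33)
  Xs <- matrix(rnorm(12), 6, 2)
  small <- gp_expert(pr$X[1:11, ], pr$Y[1:11, , drop = FALSE], pr$params, pr$noise)
  # force the same (zero-jitter) matrix in both models for a clean comparison
  full <- gp_expert(pr$X, pr$Y, pr$params, pr$noise)
  expect_true(all(predict(full, Xs)$variance <=
                  predict(small, Xs)$variance + 1e-10))
})

test_that("analytic NLML gradient matches central finite differences", {
  for (seed in 1:4) {
    pr <- rand_problem(10, 3, 2, seed + 50)
    theta <- log(c(pr$params$variance, pr$params$lengthscales, pr$noise))
    D2 <- moegpr:::sqdiff_per_dim(pr$X)
    an <- moegpr:::nlml_objective(theta, pr$X, pr$Y, D2)$gradient
    num <- vapply(seq_along(theta), function(i) {
      e <- replace(numeric(length(theta)), i, 1e-6)
      (moegpr:::nlml_objective(theta + e, pr$X, pr$Y, D2, grad = FALSE)$value -
       moegpr:::nlml_objective(theta - e, pr$X, pr$Y, D2, grad = FALSE)$value) / 2e-6
    }, numeric(1))
    expect_equal(an, num, tolerance = 1e-5)
  }
})

test_that("fitting improves the NLML and a zero-iteration run returns the init", {
  pr <- rand_problem(25, 3, 2, 61)
  init <- ard_params(1, c(1, 1, 1))
  fit0 <- fit_gp_expert(pr$X, pr$Y, init = init, noise_init = 0.1, maxit = 0)
  expect_equal(fit0$kernel$lengthscales, init$lengthscales)
  expect_equal(fit0$kernel$variance, init$variance)
  expect_equal(fit0$noise_variance, 0.1)

  fit <- fit_gp_expert(pr$X, pr$Y, init = init, noise_init = 0.1, maxit = 50)
  expect_lte(fit$nlml, fit0$nlml + 1e-8)
})

test_that("fitted lengthscales recover relevance structure", {
  # data generated with a short lengthscale on dim 1, long on dim 2
  ok_order <- 0L
  for (seed in 1:6) {
    withr::with_seed(seed, {
      n <- 120
      X <- matrix(rnorm(n * 2), n, 2)
      f <- sin(2.5 * X[, 1]) + 0.05 * X[, 2]
      Y <- cbind(f + rnorm(n, sd = 0.1))
    })
    fit <- fit_gp_expert(X, Y, maxit = 60)
    ok_order <- ok_order + (fit$kernel$lengthscales[1] < fit$kernel$lengthscales[2])
  }
  expect_gte(ok_order, 5L)

  # an input the target does not depend on at all gets a larger lengthscale
  withr::with_seed(9, {
    X <- matrix(rnorm(200), 100, 2)
    Y <- cbind(sin(2 * X[, 1]) + rnorm(100, sd = 0.05))
  })
  fit <- fit_gp_expert(X, Y, maxit = 60)
  expect_gt(fit$kernel$lengthscales[2], fit$kernel$lengthscales[1])
})

test_that("training-row permutation leaves predictions unchanged", {
  pr <- rand_problem(20, 3, 2, 71)
  perm <- withr::with_seed(1, sample.int(20))
  f1 <- fit_gp_expert(pr$X, pr$Y, init = pr$params, noise_init = 0.2, maxit = 30)
  f2 <- fit_gp_expert(pr$X[perm, ], pr$Y[perm, ], init = pr$params,
                      noise_init = 0.2, maxit = 30)
  Xs <- matrix(rnorm(9), 3, 3)
  expect_equal(predict(f1, Xs)$mean, predict(f2, Xs)$mean, tolerance = 1e-6)
})

test_that("the inducing-point approximation agrees with exact inference", {
  # smooth 1-function data so the posterior is well-determined
  withr::with_seed(81, {
    X <- matrix(runif(80, -2, 2), 40, 2)
    Y <- cbind(sin(X[, 1]) + 0.5 * X[, 2] + rnorm(40, sd = 0.1))
    Xs <- matrix(runif(10, -2, 2), 5, 2)
  })
  init <- ard_params(1, c(1, 1))
  # fixed hyperparameters, inducing set = training set: the approximate
  # posterior is exact
  exact <- fit_gp_expert(X, Y, init = init, noise_init = 0.05, maxit = 0)
  sp_full <- fit_gp_expert(X, Y, init = init, noise_init = 0.05, maxit = 0,
                           sparse = list(force = TRUE, n_inducing = 40))
  expect_equal(predict(sp_full, Xs)$mean, predict(exact, Xs)$mean,
               tolerance = 1e-4)
  # fewer inducing points still approximate the exact posterior mean
  sp <- fit_gp_expert(X, Y, init = init, noise_init = 0.05, maxit = 0,
                      sparse = list(force = TRUE, n_inducing = 20))
  expect_identical(sp$method, "sparse")
  expect_equal(predict(sp, Xs)$mean, predict(exact, Xs)$mean, tolerance = 0.1)
  # optimizing the collapsed bound does not worsen it
  sp_opt <- fit_gp_expert(X, Y, init = init, noise_init = 0.05, maxit = 30,
                          sparse = list(force = TRUE, n_inducing = 20))
  expect_lte(sp_opt$nlml, sp$nlml + 1e-6)
})

test_that("degenerate fits are rejected with clear errors", {
  expect_error(fit_gp_expert(matrix(1, 1, 2), matrix(1, 1, 1)), "at least 2")
  expect_error(fit_gp_expert(matrix(rnorm(10), 5, 2), matrix(0, 5, 1)),
               "constant-zero")
  pr <- rand_problem(5, 2, 1, 91)
  mod <- gp_expert(pr$X, pr$Y, pr$params, pr$noise)
  expect_error(predict(mod, matrix(1, 1, 3)), "columns")
})

test_that("tidy and glance summarize a fitted expert", {
  pr <- rand_problem(15, 3, 2, 95)
  colnames(pr$X) <- c("b_taxon", "a_taxon", "c_taxon")
  fit <- fit_gp_expert(pr$X, pr$Y, maxit = 20)
  td <- tidy(fit)
  expect_identical(nrow(td), 3L)
  expect_identical(td$rank, 1:3)
  expect_true(all(diff(td$inverse_lengthscale) <= 0))
  gl <- glance(fit)
  expect_identical(gl$n, 15L)
  expect_identical(gl$method, "exact")
})
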