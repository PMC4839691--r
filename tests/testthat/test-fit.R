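test_that("folds form a seeded random equal partition", {
  f <- make_folds(10000, 10, seed = 3)
  expect_length(f, 10000)
  expect_equal(unname(table(f)), rep(1000, 10), ignore_attr = TRUE)
  expect_identical(f, make_folds(10000, 10, seed = 3))
  expect_false(identical(f, make_folds(10000, 10, seed = 4)))
  expect_error(make_folds(1001, 10), "divisible")
})

test_that("balancing equates correct and incorrect trial counts", {
  trials <- tibble::tibble(trial = 1:1000,
                           correct = c(rep(TRUE, 790), rep(FALSE, 210)))
  bal <- balance_trials(trials, seed = 1)
  expect_equal(sum(bal$correct), 210)
  expect_equal(sum(!bal$correct), 210)
  # already balanced: unchanged up to identity
  even <- tibble::tibble(trial = 1:10, correct = rep(c(TRUE, FALSE), 5))
  expect_equal(balance_trials(even, seed = 9), even)
  # different seeds: same size, membership varies over a toy set
  toy <- tibble::tibble(trial = 1:6,
                        correct = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  picks <- vapply(1:20, function(s) {
    paste(balance_trials(toy, seed = s)$trial, collapse = ",")
  }, character(1))
  expect_true(all(vapply(1:20, function(s) {
    nrow(balance_trials(toy, seed = s)) == 4
  }, logical(1))))
  expect_gt(length(unique(picks)), 1)
  expect_error(balance_trials(tibble::tibble(correct = c(TRUE, TRUE))),
               "both")
})

test_that("deviance and classification rate match closed forms", {
  expect_equal(binomial_deviance(rep(c(0, 1), 500), rep(0.5, 1000)),
               1386.294, tolerance = 1e-3)
  expect_equal(binomial_deviance(1, 0.25), -2 * log(0.25))
  expect_equal(round(binomial_deviance(1, 0.25), 4), 2.7726)
  y <- rep(c(0, 1), 50)
  p_perfect <- ifelse(y == 1, 1 - 1e-12, 1e-12)
  expect_lt(binomial_deviance(y, p_perfect), 1e-9)

  expect_equal(classification_rate(rep(1, 10), rep(0.9, 10)), 100)
  # ties at 0.5 predict r = 1, so balanced responses score 50%
  expect_equal(classification_rate(rep(c(0, 1), 50), rep(0.5, 100)), 50)
  p_rand <- withr::with_seed(2, stats::runif(10000))
  expect_lt(abs(classification_rate(rep(c(0, 1), 5000), p_rand) - 50), 1.5)
})

test_that("model probabilities follow the logistic closed form", {
  skel <- list(
    label = "t", beta = matrix(0, 2, 3), beta_std = matrix(0, 2, 3),
    intercept = 0, n_channels = 2, n_frames = 3,
    standardization = list(center = rep(0, 6), scale = rep(1, 6))
  )
  m0 <- structure(skel, class = "aci_model")
  x <- matrix(rnorm(18), 3, 6)
  expect_equal(predict(m0, x), rep(0.5, 3))
  m1 <- m0
  m1$intercept <- 10
  expect_true(all(predict(m1, x) >= 0.9999))
  # hand-computed logistic on 3 trials with a known weight vector
  m2 <- m0
  m2$beta_std <- matrix(c(1, -1, 0.5, 0, 0, 2), 2, 3, byrow = TRUE)
  x3 <- matrix(c(1, 0, 0, 0, 0, 0,
                 0, 1, 0, 0, 0, 0,
                 1, 1, 1, 1, 1, 1), 3, 6, byrow = TRUE)
  eta <- drop(x3 %*% as.vector(t(m2$beta_std)))
  expect_equal(predict(m2, x3), plogis(eta), tolerance = 1e-12)
  expect_error(predict(m2, x3[, 1:5]), "columns")
})

test_that("the near-unpenalized fit matches the glm oracle", {
  set.seed(42)
  n <- 200
  nc <- 6
  nf <- 8
  x <- matrix(rnorm(n * nc * nf), n, nc * nf)
  b0 <- as.vector(t(outer(sin(seq(0, pi, length.out = nc)),
                          cos(seq(0, pi, length.out = nf))))) / 4
  y <- rbinom(n, 1, plogis(drop(x %*% b0)))
  fit <- fit_penalized_logistic(x, y, lambda = 1e-6, dims = c(nc, nf),
                                ridge = 1)
  g <- stats::glm(y ~ x, family = stats::binomial)
  expect_equal(fit$deviance, stats::deviance(g), tolerance = 1e-4)
  expect_equal(fit$beta, unname(stats::coef(g)[-1]), tolerance = 1e-2)
})

test_that("the penalized fit matches an independent convex minimizer", {
  set.seed(7)
  n <- 150
  nc <- 5
  nf <- 9
  p <- nc * nf
  x <- matrix(rnorm(n * p), n, p)
  y <- rbinom(n, 1, plogis(drop(x %*% rnorm(p, sd = 0.3))))
  lambda <- 5
  ridge <- 1e-3
  # independent objective: explicit difference matrices in the same
  # channel-major ordering (frame index fastest)
  idx <- function(ch, fr) (ch - 1) * nf + fr
  dt <- do.call(rbind, lapply(seq_len(nc), function(ch) {
    t(vapply(seq_len(nf - 1), function(fr) {
      e <- numeric(p); e[idx(ch, fr + 1)] <- 1; e[idx(ch, fr)] <- -1; e
    }, numeric(p)))
  }))
  df <- do.call(rbind, lapply(seq_len(nf), function(fr) {
    t(vapply(seq_len(nc - 1), function(ch) {
      e <- numeric(p); e[idx(ch + 1, fr)] <- 1; e[idx(ch, fr)] <- -1; e
    }, numeric(p)))
  }))
  obj <- function(theta) {
    eta <- theta[1] + drop(x %*% theta[-1])
    -2 * sum(y * eta - log(1 + exp(eta))) +
      lambda * (sum((dt %*% theta[-1])^2) + sum((df %*% theta[-1])^2)) +
      ridge * lambda * sum(theta[-1]^2)
  }
  gr <- function(theta) {
    eta <- theta[1] + drop(x %*% theta[-1])
    r <- plogis(eta) - y
    c(2 * sum(r),
      2 * drop(crossprod(x, r)) +
        2 * lambda * (crossprod(dt) + crossprod(df)) %*% theta[-1] +
        2 * ridge * lambda * theta[-1])
  }
  oracle <- stats::nlminb(numeric(p + 1), obj, gr,
                          control = list(iter.max = 2000, eval.max = 4000,
                                         rel.tol = 1e-14))
  fit <- fit_penalized_logistic(x, y, lambda, dims = c(nc, nf),
                                ridge = ridge)
  expect_lt(abs(fit$objective - oracle$objective) /
              abs(oracle$objective), 1e-6)
  expect_lte(fit$gradient_norm, 1e-6)
})

test_that("extreme smoothing and separable data stay well behaved", {
  set.seed(3)
  x <- matrix(rnorm(40 * 12), 40, 12)
  y <- rep(c(0, 1), 20)
  fit <- fit_penalized_logistic(x, y, lambda = 1e8, dims = c(3, 4))
  expect_lte(max(abs(fit$beta)), 1e-3)
  # perfectly separable toy set: the penalty precludes divergence
  xs <- matrix(c(rnorm(10, -3), rnorm(10, 3)), 20, 1)
  xs <- cbind(xs, matrix(rnorm(20 * 11), 20, 11))
  ys <- rep(c(0, 1), each = 10)
  fs <- fit_penalized_logistic(xs, ys, lambda = 1, dims = c(3, 4))
  expect_true(all(is.finite(fs$beta)))
  expect_gt(fs$deviance, 0)
})

test_that("cross-validated deviance is U-shaped over the smoothing grid", {
  sim <- fix_small_experiment()
  cv <- cross_validate_aci(sim$predictors, sim$trials,
                           lambda_grid = c(0.1, 30, 3e5), seed = 21)
  s <- cv$summary
  best <- s$lambda[which.min(s$cvd)]
  expect_equal(best, 30)
  expect_lt(s$cvd[s$lambda == 30], s$cvd[s$lambda == 0.1])
  expect_lt(s$cvd[s$lambda == 30], s$cvd[s$lambda == 3e5])
})

test_that("shuffled responses yield chance-level cross-validation", {
  sim <- fix_small_experiment()
  shuffled <- sim$trials
  shuffled$response <- withr::with_seed(13, sample(shuffled$response))
  cv <- cross_validate_aci(sim$predictors, shuffled, lambda_grid = 100,
                           seed = 22)
  expect_gt(cv$summary$cvr, 47)
  expect_lt(cv$summary$cvr, 53)
  chance <- mean(cv$scores$n_test) * (-2 * log(0.5))
  expect_lt(abs(cv$summary$cvd - chance) / chance, 0.1)
})

test_that("lambda selection minimizes cohort mean CVD, ties to smoother", {
  fake_cv <- function(cvd) {
    structure(list(summary = tibble::tibble(
      lambda = c(1, 10, 100), cvd = cvd, cvr = 50
    )), class = "aci_cv")
  }
  expect_equal(select_lambda(fake_cv(c(5, 3, 4))), 10)
  # two observers with minima at adjacent grid points: mean decides
  expect_equal(select_lambda(list(fake_cv(c(5, 3, 4)),
                                  fake_cv(c(6, 5, 1)))), 100)
  # exact tie goes to the larger lambda
  expect_equal(select_lambda(fake_cv(c(4, 3, 3))), 100)
})

test_that("the refit model dominates the null model on training data", {
  sim <- fix_small_experiment()
  m <- fit_aci(sim$trials, predictors = sim$predictors, lambda = 30,
               seed = 23, label = "dom")
  null_dev <- 2 * m$n_balanced * log(2)  # all-0.5 model on balanced data
  expect_lte(m$deviance_train, null_dev)
  expect_lte(m$gradient_norm, 1e-6)
  expect_equal(dim(m$beta), c(16, 20))
  expect_equal(length(m$fold_fits), 10)
})

test_that("the fitted map recovers the generating template", {
  sim <- fix_small_experiment()
  m <- fit_aci(sim$trials, predictors = sim$predictors, lambda = 30,
               seed = 24, label = "rec")
  expect_gt(cor(as.vector(m$beta), as.vector(sim$observer$template)), 0.5)
})

test_that("tidy and glance expose the model in tabular form", {
  sim <- fix_small_experiment()
  m <- fit_aci(sim$trials, predictors = sim$predictors, lambda = 30,
               seed = 25, label = "tab")
  td <- tidy(m)
  expect_equal(nrow(td), 16 * 20)
  expect_named(td, c("channel", "frame", "time_ms", "freq_hz", "estimate",
                     "estimate_std"))
  expect_equal(td$estimate[td$channel == 3 & td$frame == 7], m$beta[3, 7])
  gl <- glance(m)
  expect_equal(gl$lambda, 30)
  expect_equal(gl$cvd, m$cvd)
  p <- autoplot(m)
  expect_s3_class(p, "ggplot")
})

test_that("model serialization round-trips predictions", {
  sim <- fix_small_experiment()
  m <- fit_aci(sim$trials, predictors = sim$predictors, lambda = 30,
               seed = 26, label = "io")
  stem <- withr::local_tempfile()
  write_aci_model(m, stem)
  back <- read_aci_model(stem)
  expect_equal(back$beta, m$beta, tolerance = 1e-12)
  expect_equal(back$lambda, m$lambda)
  expect_equal(back$cvd, m$cvd)
  x <- sim$predictors[1:50, ]
  expect_equal(predict(back, x), predict(m, x), tolerance = 1e-10)
})
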