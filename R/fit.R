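#' Random equal-size cross-validation folds
#'
#' Randomly partitions `n` trials into `n_folds` folds of exactly equal
#' size, as required by the 10-fold cross-validation that selects the
#' smoothing level (10,000 trials split into 10 sets of 1,000).
#'
#' @param n Number of trials, or a trial tibble.
#' @param n_folds Number of folds.
#' @param seed Seed for the random partition.
#' @return Integer vector of fold labels in `1:n_folds`.
#' @export
make_folds <- function(n, n_folds = 10, seed = 1) {
  if (is.data.frame(n)) n <- nrow(n)
  if (n %% n_folds != 0) {
    stop_input("n (%d) is not divisible by n_folds (%d)", n, n_folds)
  }
  withr::with_seed(seed, sample(rep(seq_len(n_folds), n / n_folds)))
}

# indices (sorted) of a class-balanced subsample: the majority class of
# `correct` is subsampled without replacement down to the minority count
balance_index <- function(correct, seed = 1) {
  idx_t <- which(correct)
  idx_f <- which(!correct)
  if (length(idx_t) == 0 || length(idx_f) == 0) {
    stop_input("both correct and incorrect trials are required to balance")
  }
  m <- min(length(idx_t), length(idx_f))
  keep <- withr::with_seed(seed, c(
    if (length(idx_t) > m) sample(idx_t, m) else idx_t,
    if (length(idx_f) > m) sample(idx_f, m) else idx_f
  ))
  sort(keep)
}

#' Equate the proportions of correct and incorrect trials
#'
#' Subsamples the majority class (without replacement, seeded) so that the
#' returned subset has exactly as many correctly as incorrectly categorized
#' trials. Applied to every training and test set so that the participant's
#' performance level does not bias model estimation or evaluation.
#'
#' @param trials Trial tibble with a logical `correct` column.
#' @param seed Seed for the subsample.
#' @return The balanced subset of `trials` (original order preserved).
#' @export
balance_trials <- function(trials, seed = 1) {
  trials[balance_index(trials$correct, seed), , drop = FALSE]
}

#' Cochleogram predictor matrix for a trial table
#'
#' Rebuilds each trial's noisy stimulus from its target label, noise seed
#' and SNR, computes its cochleogram, and flattens it into one predictor row
#' (channel-major ordering; see [flatten_cochleogram()]). Trial tables
#' therefore never need to store waveforms: the noise seed reproduces them
#' bit-identically.
#'
#' @param trials Trial tibble.
#' @param targets Target set used in the experiment.
#' @param filterbank,n_frames Cochleogram front end (must match the
#'   simulation).
#' @param floor_db Log-compression floor.
#' @return Numeric matrix `n_trials x (n_channels * n_frames)` with
#'   attributes `n_channels`, `n_frames`, `frame_times`,
#'   `center_frequencies`.
#' @export
trial_predictors <- function(trials, targets,
                             filterbank = gammatone_filterbank(),
                             n_frames = 81, floor_db = -60) {
  plan <- make_coch_plan(filterbank, nrow(targets$waveforms), n_frames)
  n <- nrow(trials)
  x <- matrix(0, n, nrow(filterbank) * n_frames)
  for (i in seq_len(n)) {
    noise <- generate_noise(trials$noise_seed[i], targets$total_duration_ms,
                            targets$sample_rate)
    mix <- mix_at_snr(targets$waveforms[, trials$target[i]], noise,
                      trials$snr_db[i])
    e <- coch_apply(mix, plan)
    v <- 10 * log10(e)
    x[i, ] <- as.vector(t(pmax(v, max(v) + floor_db)))
  }
  attr(x, "n_channels") <- nrow(filterbank)
  attr(x, "n_frames") <- n_frames
  attr(x, "frame_times") <- plan$frame_times
  attr(x, "center_frequencies") <- filterbank$cf_hz
  class(x) <- c("aci_predictors", class(x))
  x
}

# row subsetting keeps the lattice metadata so subsets remain fittable
#' @export
`[.aci_predictors` <- function(x, i, j, ..., drop = FALSE) {
  m <- x
  class(m) <- setdiff(class(m), "aci_predictors")
  out <- if (missing(i)) {
    m[, j, drop = drop]
  } else if (missing(j)) {
    m[i, , drop = drop]
  } else {
    m[i, j, drop = drop]
  }
  if (missing(j) && is.matrix(out)) {
    for (a in c("n_channels", "n_frames", "frame_times",
                "center_frequencies")) {
      attr(out, a) <- attr(x, a)
    }
    class(out) <- class(x)
  }
  out
}

# smoothness penalty operator: first differences along the frame (time) and
# channel (frequency) axes of the unflattened map, plus a ridge component.
# Works on the channel-major flattened vector; returns P %*% b and b' P b
# without materializing P.
penalty_apply <- function(b, n_channels, n_frames, ridge) {
  m <- matrix(b, n_frames, n_channels)      # [frame, channel]
  dt <- m[-1, , drop = FALSE] - m[-n_frames, , drop = FALSE]
  df <- m[, -1, drop = FALSE] - m[, -n_channels, drop = FALSE]
  v <- matrix(0, n_frames, n_channels)
  v[-n_frames, ] <- v[-n_frames, , drop = FALSE] - dt
  v[-1, ] <- v[-1, , drop = FALSE] + dt
  v[, -n_channels] <- v[, -n_channels, drop = FALSE] - df
  v[, -1] <- v[, -1, drop = FALSE] + df
  list(Pb = as.vector(v) + ridge * b,
       quad = sum(dt^2) + sum(df^2) + ridge * sum(b^2))
}

# dense penalty matrix (small problems only; Newton polish and oracles)
penalty_matrix <- function(n_channels, n_frames, ridge) {
  p <- n_channels * n_frames
  vapply(seq_len(p), function(j) {
    e <- numeric(p)
    e[j] <- 1
    penalty_apply(e, n_channels, n_frames, ridge)$Pb
  }, numeric(p))
}

#' Smoothness-penalized logistic regression
#'
#' Fits the classification-image GLM: binary responses `y` are regressed on
#' the flattened cochleogram predictors `x` by minimizing
#' `binomial deviance + lambda * (||D_t b||^2 + ||D_f b||^2)
#'  + ridge * lambda * ||b||^2`,
#' where `D_t`, `D_f` are first-difference operators along the time and
#' frequency axes of the weight map. The smoothness term penalizes abrupt
#' variations in the map; the small ridge removes the constant-map null
#' space so the objective is strictly convex. The intercept is unpenalized.
#'
#' The objective is minimized by L-BFGS-B with analytic gradients; for
#' problems with at most `newton_max_p` predictors a dense Newton polish
#' then drives the gradient infinity-norm below `gtol`.
#'
#' @param x Predictor matrix (standardized by the caller for comparability
#'   of `lambda` across observers).
#' @param y Binary responses (0/1).
#' @param lambda Smoothing level (>= 0).
#' @param dims `c(n_channels, n_frames)` of the weight-map lattice; defaults
#'   to the attributes of `x`, or a `1 x p` chain lattice.
#' @param ridge Relative ridge weight (default 1e-3).
#' @param beta_init,intercept_init Warm-start values.
#' @param control List: `maxit` (2000), `factr` (1e4), `restarts` (2),
#'   `newton_max_p` (600), `gtol` (1e-8).
#' @return List with `beta`, `intercept`, `objective`, `deviance`,
#'   `gradient_norm` (infinity norm at the solution), `converged`,
#'   `iterations`.
#' @export
fit_penalized_logistic <- function(x, y, lambda, dims = NULL, ridge = 1e-3,
                                   beta_init = NULL, intercept_init = 0,
                                   control = list()) {
  ctl <- utils::modifyList(
    list(maxit = 2000L, factr = 1e4, restarts = 2L, newton_max_p = 600L,
         gtol = 1e-8),
    control
  )
  if (lambda < 0) stop_input("lambda must be >= 0")
  y <- as.numeric(y)
  if (length(y) != nrow(x)) stop_input("length(y) != nrow(x)")
  if (length(unique(y)) < 2) stop_input("both response classes required")
  p <- ncol(x)
  if (is.null(dims)) {
    nc <- attr(x, "n_channels") %||% 1L
    nf <- attr(x, "n_frames") %||% p
  } else {
    nc <- dims[1]
    nf <- dims[2]
  }
  if (nc * nf != p) stop_input("dims (%d x %d) do not match ncol(x) = %d",
                               nc, nf, p)
  obj <- function(theta) {
    a <- theta[1]
    b <- theta[-1]
    eta <- a + drop(x %*% b)
    dev <- 2 * sum(log1pexp(eta) - y * eta)
    dev + lambda * penalty_apply(b, nc, nf, ridge)$quad
  }
  grad <- function(theta) {
    a <- theta[1]
    b <- theta[-1]
    eta <- a + drop(x %*% b)
    r <- plogis(eta) - y
    c(2 * sum(r),
      2 * drop(crossprod(x, r)) + 2 * lambda * penalty_apply(b, nc, nf,
                                                             ridge)$Pb)
  }
  theta <- c(intercept_init, beta_init %||% numeric(p))
  iterations <- 0L
  conv <- 1L
  for (k in seq_len(ctl$restarts + 1L)) {
    fit <- optim(theta, obj, grad, method = "L-BFGS-B",
                 control = list(maxit = ctl$maxit, factr = ctl$factr,
                                lmm = 20))
    theta <- fit$par
    iterations <- iterations + fit$counts[["function"]]
    conv <- fit$convergence
    if (conv == 0L) break
  }
  # Newton polish on small lattices: exact gradient-norm contract
  if (p <= ctl$newton_max_p) {
    pm <- penalty_matrix(nc, nf, ridge)
    for (it in seq_len(50L)) {
      g <- grad(theta)
      if (max(abs(g)) <= ctl$gtol) break
      eta <- theta[1] + drop(x %*% theta[-1])
      w <- plogis(eta) * (1 - plogis(eta))
      xw <- cbind(1, x) * w
      h <- 2 * crossprod(cbind(1, x), xw)
      h[-1, -1] <- h[-1, -1] + 2 * lambda * pm
      step <- tryCatch(solve(h, g), error = function(e) NULL)
      if (is.null(step)) break
      f0 <- obj(theta)
      alpha <- 1
      repeat {
        cand <- theta - alpha * step
        if (obj(cand) <= f0 || alpha < 1e-8) break
        alpha <- alpha / 2
      }
      theta <- theta - alpha * step
      iterations <- iterations + 1L
    }
  }
  g_inf <- max(abs(grad(theta)))
  converged <- conv == 0L || g_inf <= ctl$gtol
  if (!converged) {
    stop_input(
      "penalized logistic fit did not converge (gradient inf-norm %.3g)",
      g_inf)
  }
  a <- theta[1]
  b <- theta[-1]
  eta <- a + drop(x %*% b)
  list(beta = b, intercept = a, objective = obj(theta),
       deviance = 2 * sum(log1pexp(eta) - y * eta),
       gradient_norm = g_inf, converged = converged,
       iterations = iterations)
}

#' Binomial deviance of predicted probabilities
#'
#' `-2 * sum(y * log(p) + (1 - y) * log(1 - p))`, the cross-validated
#' deviance (CVD) metric when computed on held-out balanced test trials.
#'
#' @param y Binary responses (0/1).
#' @param p Predicted probabilities in (0, 1).
#' @return Deviance (scalar, >= 0).
#' @export
binomial_deviance <- function(y, p) {
  -2 * sum(y * log(p) + (1 - y) * log(1 - p))
}

#' Classification rate of predicted probabilities
#'
#' Percentage of trials whose response is predicted by thresholding `p` at
#' 0.5; `p = 0.5` counts as predicting `y = 1`. This is the cross-validation
#' rate (CVR) when computed on held-out balanced test trials.
#'
#' @inheritParams binomial_deviance
#' @return Percentage in \[0, 100\].
#' @export
classification_rate <- function(y, p) {
  100 * mean((p >= 0.5) == (y == 1))
}

# probabilities of a fitted (beta, intercept) on standardized predictors
predict_proba <- function(beta, intercept, x_std) {
  clip01(plogis(intercept + drop(x_std %*% beta)))
}

standardize_cols <- function(x, center, scale) {
  sweep(sweep(x, 2, center, "-"), 2, scale, "/")
}

#' Cross-validate the smoothing level of a classification-image fit
#'
#' For every `lambda` and every fold, fits the penalized logistic model on
#' the balanced training set (all other folds) and evaluates deviance and
#' classification rate on the balanced held-out fold. Predictors are
#' standardized per bin (mean/SD over all trials) before fitting. Fits are
#' warm-started across folds and lambdas.
#'
#' @param x Raw (unstandardized) predictor matrix from
#'   [trial_predictors()].
#' @param trials Trial tibble aligned with `x` (uses `response`, `correct`).
#' @param lambda_grid Smoothing levels to evaluate.
#' @param n_folds Number of folds.
#' @param seed Seed for fold assignment and balancing subsamples.
#' @param folds Optional externally supplied fold labels.
#' @param ridge,control Passed to [fit_penalized_logistic()].
#' @return An `aci_cv` list: `scores` (tibble lambda/fold/deviance/rate/
#'   n_test), `summary` (per-lambda mean CVD and CVR), `fits` (per lambda,
#'   per fold fitted beta/intercept), `folds`, `test_sets` (balanced test
#'   indices per fold), `standardization`, `seed`.
#' @export
cross_validate_aci <- function(x, trials, lambda_grid, n_folds = 10,
                               seed = 1, folds = NULL, ridge = 1e-3,
                               control = list()) {
  if (length(lambda_grid) < 1) stop_input("need at least one lambda")
  lambda_grid <- sort(lambda_grid)
  n <- nrow(x)
  if (is.null(folds)) folds <- make_folds(n, n_folds, seed = seed)
  n_folds <- max(folds)
  bal_seeds <- derive_seeds(seed + 1L, 2L * n_folds)
  center <- colMeans(x)
  scale <- pmax(apply(x, 2, sd), 1e-8)
  xs <- standardize_cols(x, center, scale)
  y <- as.numeric(trials$response)
  nc <- attr(x, "n_channels")
  nf <- attr(x, "n_frames")
  train_sets <- vector("list", n_folds)
  test_sets <- vector("list", n_folds)
  for (k in seq_len(n_folds)) {
    tr_idx <- which(folds != k)
    te_idx <- which(folds == k)
    train_sets[[k]] <- tr_idx[balance_index(trials$correct[tr_idx],
                                            bal_seeds[2 * k - 1])]
    test_sets[[k]] <- te_idx[balance_index(trials$correct[te_idx],
                                           bal_seeds[2 * k])]
  }
  fits <- vector("list", length(lambda_grid))
  names(fits) <- as.character(lambda_grid)
  rows <- list()
  warm <- NULL
  for (li in seq_along(lambda_grid)) {
    lam <- lambda_grid[li]
    fold_fits <- vector("list", n_folds)
    for (k in seq_len(n_folds)) {
      idx <- train_sets[[k]]
      fit <- fit_penalized_logistic(
        xs[idx, , drop = FALSE], y[idx], lam, dims = c(nc, nf),
        ridge = ridge,
        beta_init = warm$beta, intercept_init = warm$intercept %||% 0,
        control = control
      )
      warm <- fit
      te <- test_sets[[k]]
      p <- predict_proba(fit$beta, fit$intercept, xs[te, , drop = FALSE])
      rows[[length(rows) + 1L]] <- tibble(
        lambda = lam, fold = k,
        deviance = binomial_deviance(y[te], p),
        rate = classification_rate(y[te], p),
        n_test = length(te)
      )
      fold_fits[[k]] <- list(beta = fit$beta, intercept = fit$intercept)
    }
    fits[[li]] <- fold_fits
  }
  scores <- dplyr::bind_rows(rows)
  summary <- scores |>
    dplyr::group_by(.data$lambda) |>
    dplyr::summarise(cvd = mean(.data$deviance), cvr = mean(.data$rate),
                     .groups = "drop")
  structure(
    list(scores = scores, summary = summary, fits = fits, folds = folds,
         train_sets = train_sets, test_sets = test_sets,
         standardization = list(center = center, scale = scale),
         seed = seed, lambda_grid = lambda_grid),
    class = "aci_cv"
  )
}

#' Select the smoothing level shared by a cohort
#'
#' The smoothing level is the grid value with the lowest mean
#' cross-validated deviance averaged over all observers in the cohort (one
#' observer is a cohort of one). Ties are broken toward the larger lambda
#' (the smoother map).
#'
#' @param cv_results An `aci_cv` object or a (possibly named) list of them,
#'   one per observer.
#' @return Selected lambda (scalar).
#' @export
select_lambda <- function(cv_results) {
  if (inherits(cv_results, "aci_cv")) cv_results <- list(cv_results)
  per_obs <- dplyr::bind_rows(lapply(cv_results, function(cv) cv$summary),
                              .id = "observer")
  pooled <- per_obs |>
    dplyr::group_by(.data$lambda) |>
    dplyr::summarise(mean_cvd = mean(.data$cvd), .groups = "drop")
  best <- pooled$mean_cvd <= min(pooled$mean_cvd) + 1e-12
  max(pooled$lambda[best])
}

#' Fit an observer's Auditory Classification Image
#'
#' End-to-end single-observer estimation: builds (or takes) the cochleogram
#' predictor matrix, standardizes each bin, runs `n_folds`-fold
#' cross-validation over `lambda_grid` with balanced training and test sets,
#' selects the smoothing level with the lowest mean cross-validated deviance
#' (unless `lambda` is supplied, e.g. a cohort-level choice), and refits the
#' final weight map on the full balanced trial set at that level.
#'
#' @param trials Trial tibble from [run_experiment()] or [read_trials()].
#' @param targets Target set used in the experiment (ignored if
#'   `predictors` given).
#' @param filterbank,n_frames Cochleogram front end.
#' @param lambda Fixed smoothing level; `NULL` selects it from
#'   `lambda_grid` by cross-validation.
#' @param lambda_grid Grid for cross-validated selection (also evaluated
#'   when `lambda` is fixed, at that single value).
#' @param n_folds Number of cross-validation folds.
#' @param seed Seed for folds and balancing.
#' @param predictors Optional precomputed [trial_predictors()] matrix.
#' @param ridge,control Passed to [fit_penalized_logistic()].
#' @param label Observer identifier stored in the model.
#' @return An `aci_model` object; see [tidy.aci_model()],
#'   [glance.aci_model()], [autoplot.aci_model()].
#' @export
fit_aci <- function(trials, targets = NULL,
                    filterbank = gammatone_filterbank(), n_frames = 81,
                    lambda = NULL, lambda_grid = default_lambda_grid(),
                    n_folds = 10, seed = 1, predictors = NULL,
                    ridge = 1e-3, control = list(), label = "obs") {
  if (is.null(predictors)) {
    if (is.null(targets)) stop_input("need targets or predictors")
    predictors <- trial_predictors(trials, targets, filterbank, n_frames)
  }
  grid <- if (is.null(lambda)) lambda_grid else lambda
  cv <- cross_validate_aci(predictors, trials, grid, n_folds = n_folds,
                           seed = seed, ridge = ridge, control = control)
  lambda_star <- if (is.null(lambda)) select_lambda(cv) else lambda
  at <- cv$summary[abs(cv$summary$lambda - lambda_star) < 1e-12, ]
  nc <- attr(predictors, "n_channels")
  nf <- attr(predictors, "n_frames")
  xs <- standardize_cols(predictors, cv$standardization$center,
                         cv$standardization$scale)
  full_bal <- balance_index(trials$correct, cv$seed)
  warm <- cv$fits[[as.character(lambda_star)]][[1]]
  final <- fit_penalized_logistic(
    xs[full_bal, , drop = FALSE], as.numeric(trials$response)[full_bal],
    lambda_star, dims = c(nc, nf), ridge = ridge,
    beta_init = warm$beta, intercept_init = warm$intercept,
    control = control
  )
  beta_map_std <- unflatten_cochleogram(final$beta, nc, nf)
  beta_map <- unflatten_cochleogram(
    final$beta / cv$standardization$scale, nc, nf)
  structure(
    list(label = label,
         beta = beta_map, beta_std = beta_map_std,
         intercept = final$intercept, lambda = lambda_star,
         cvd = at$cvd, cvr = at$cvr, cv = cv$summary,
         standardization = cv$standardization,
         folds = cv$folds, test_sets = cv$test_sets,
         fold_fits = cv$fits[[as.character(lambda_star)]],
         n_channels = nc, n_frames = nf,
         frame_times = attr(predictors, "frame_times"),
         center_frequencies = attr(predictors, "center_frequencies"),
         n_trials = nrow(trials), n_balanced = length(full_bal),
         ridge = ridge, seed = seed,
         gradient_norm = final$gradient_norm,
         deviance_train = final$deviance),
    class = "aci_model"
  )
}

#' Default smoothing grid
#'
#' Ten logarithmically spaced smoothing levels between 1 and 1e5.
#'
#' @return Numeric vector of length 10.
#' @export
default_lambda_grid <- function() {
  10^seq(0, 5, length.out = 10)
}

#' @export
print.aci_model <- function(x, ...) {
  cat(sprintf("<aci_model> '%s': %d x %d weight map\n", x$label,
              x$n_channels, x$n_frames))
  cat(sprintf("  lambda = %.4g, CVD = %.1f, CVR = %.1f%%, %d trials (%d balanced)\n",
              x$lambda, x$cvd, x$cvr, x$n_trials, x$n_balanced))
  invisible(x)
}

#' Tidy an ACI model into a long per-bin tibble
#'
#' @param x An `aci_model`.
#' @param ... Unused.
#' @return Tibble with one row per time-frequency bin: `channel`, `frame`,
#'   `time_ms`, `freq_hz`, `estimate` (weight on the raw dB predictor
#'   scale) and `estimate_std` (weight on the standardized scale). Positive
#'   weights push the decision toward 'ga' (r = 1).
#' @export
tidy.aci_model <- function(x, ...) {
  df <- tidy_map(x$beta, x$frame_times, x$center_frequencies)
  df$estimate <- df$value
  df$value <- NULL
  df$estimate_std <- as.vector(x$beta_std)
  df
}

#' One-row summary of an ACI model
#'
#' @param x An `aci_model`.
#' @param ... Unused.
#' @return Tibble with `label`, `lambda`, `cvd`, `cvr`, `intercept`,
#'   `n_trials`, `n_balanced`, `gradient_norm`.
#' @export
glance.aci_model <- function(x, ...) {
  tibble(label = x$label, lambda = x$lambda, cvd = x$cvd, cvr = x$cvr,
         intercept = x$intercept, n_trials = x$n_trials,
         n_balanced = x$n_balanced, gradient_norm = x$gradient_norm)
}

#' Predict response probabilities from an ACI model
#'
#' Applies the model's stored per-bin standardization to new predictors and
#' returns the logistic probabilities of responding 'ga' (r = 1), clipped
#' away from 0 and 1.
#'
#' @param object An `aci_model`.
#' @param newdata Predictor matrix ([trial_predictors()], raw scale).
#' @param ... Unused.
#' @return Probability vector.
#' @export
predict.aci_model <- function(object, newdata, ...) {
  if (ncol(newdata) != object$n_channels * object$n_frames) {
    stop_input("newdata has %d columns; model expects %d", ncol(newdata),
               object$n_channels * object$n_frames)
  }
  xs <- standardize_cols(newdata, object$standardization$center,
                         object$standardization$scale)
  predict_proba(as.vector(t(object$beta_std)), object$intercept, xs)
}

#' @export
autoplot.aci_model <- function(object, ...) {
  plot_aci(object, ...)
}
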