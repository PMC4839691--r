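#' Bundle an observer's evaluation data for cross-prediction
#'
#' Collects everything needed to evaluate any model on this observer's
#' held-out data: the raw predictor matrix, the responses, and the balanced
#' test sets of the observer's own cross-validation folds (so that auto- and
#' cross-prediction are scored on the exact same trials).
#'
#' @param model The observer's fitted `aci_model`.
#' @param predictors Raw predictor matrix for all of the observer's trials.
#' @param trials The observer's trial tibble.
#' @return An `aci_data` list with `label`, `predictors`, `responses`,
#'   `test_sets`, `standardization`.
#' @export
aci_data <- function(model, predictors, trials) {
  structure(
    list(label = model$label, predictors = predictors,
         responses = as.numeric(trials$response),
         test_sets = model$test_sets,
         standardization = model$standardization),
    class = "aci_data"
  )
}

#' Cross-prediction deviance of one model on another observer's data
#'
#' Evaluates model `j`'s per-fold fits on observer `k`'s balanced held-out
#' test sets and returns the mean deviance over folds. With `j = k` this
#' reproduces the auto-prediction CVD exactly. By default the predictors of
#' observer `k` are standardized with model `j`'s stored standardization
#' (the model is treated as a fixed decision rule); set
#' `standardize = "data"` to use observer `k`'s own standardization.
#'
#' @param model An `aci_model` (model j).
#' @param data An [aci_data()] bundle (observer k).
#' @param standardize `"model"` (default) or `"data"`.
#' @return Mean deviance over observer k's balanced test folds.
#' @export
cross_predict <- function(model, data, standardize = c("model", "data")) {
  standardize <- match.arg(standardize)
  if (ncol(data$predictors) != model$n_channels * model$n_frames) {
    stop_input("predictor dimension %d does not match model (%d)",
               ncol(data$predictors), model$n_channels * model$n_frames)
  }
  if (length(model$fold_fits) != length(data$test_sets)) {
    stop_input("model and data use different numbers of folds")
  }
  std <- if (standardize == "model") model$standardization else
    data$standardization
  devs <- vapply(seq_along(data$test_sets), function(k) {
    idx <- data$test_sets[[k]]
    xs <- standardize_cols(data$predictors[idx, , drop = FALSE],
                           std$center, std$scale)
    fit <- model$fold_fits[[k]]
    p <- predict_proba(fit$beta, fit$intercept, xs)
    binomial_deviance(data$responses[idx], p)
  }, numeric(1))
  mean(devs)
}

#' Full auto/cross-prediction deviance matrix for a cohort
#'
#' Computes the N x N matrix whose entry (j, k) is the mean deviance of
#' model j predicting observer k's balanced held-out data; the diagonal is
#' the auto-prediction CVD.
#'
#' @param models List of `aci_model`s.
#' @param data_list List of matching [aci_data()] bundles (same order).
#' @param standardize Passed to [cross_predict()].
#' @return An `aci_prediction_matrix`: list with `observers`, `cross_cvd`
#'   (N x N matrix, model j in row j, data k in column k), `auto_cvd`,
#'   `auto_rate` (diagonal CVR, taken from the models).
#' @export
prediction_matrix <- function(models, data_list,
                              standardize = c("model", "data")) {
  standardize <- match.arg(standardize)
  n <- length(models)
  if (length(data_list) != n) stop_input("models and data_list differ in length")
  labels <- vapply(models, function(m) m$label, character(1))
  cc <- matrix(NA_real_, n, n, dimnames = list(model = labels,
                                               data = labels))
  for (j in seq_len(n)) {
    for (k in seq_len(n)) {
      cc[j, k] <- cross_predict(models[[j]], data_list[[k]], standardize)
    }
  }
  structure(
    list(observers = labels, cross_cvd = cc, auto_cvd = diag(cc),
         auto_rate = vapply(models, function(m) m$cvr, numeric(1))),
    class = "aci_prediction_matrix"
  )
}

#' @export
print.aci_prediction_matrix <- function(x, ...) {
  cat(sprintf("<aci_prediction_matrix> %d observers\n",
              length(x$observers)))
  print(round(x$cross_cvd, 1))
  invisible(x)
}

#' @export
tidy.aci_prediction_matrix <- function(x, ...) {
  n <- length(x$observers)
  tibble(
    model = rep(x$observers, times = n),
    data = rep(x$observers, each = n),
    deviance = as.vector(x$cross_cvd),
    type = ifelse(rep(x$observers, times = n) == rep(x$observers, each = n),
                  "auto", "cross")
  )
}

#' Strategy specificity of each listener
#'
#' The specificity of observer k is the mean cross-prediction deviance of
#' their data under the other observers' models minus their own
#' auto-prediction deviance. High values indicate that a substantial part of
#' the observer's responses is predictable only by their own classification
#' image, i.e. an idiosyncratic listening strategy.
#'
#' @param pm An [prediction_matrix()] result.
#' @return Tibble with `observer`, `auto_cvd`, `mean_cross_cvd`,
#'   `specificity`.
#' @export
specificity <- function(pm) {
  n <- length(pm$observers)
  if (n < 2) stop_input("specificity needs at least 2 observers")
  mean_cross <- vapply(seq_len(n), function(k) {
    mean(pm$cross_cvd[-k, k])
  }, numeric(1))
  tibble(
    observer = pm$observers,
    auto_cvd = unname(pm$auto_cvd),
    mean_cross_cvd = mean_cross,
    specificity = mean_cross - unname(pm$auto_cvd)
  )
}
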