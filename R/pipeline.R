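#' Configuration of a simulated classification-image study
#'
#' Captures every choice needed to reproduce an end-to-end synthetic study:
#' cohort composition, per-observer trial counts, staircase settings,
#' cochleogram front end, smoothing grid and all seeds. The defaults are
#' the package's standard study conditions: two groups of 18
#' observers, 10,000 trials each in 20 sessions of 500, a 3-down 1-up
#' staircase, 54 x 81 cochleograms and 10-fold cross-validation with 5000
#' permutations in the group test. Group B observers use a blended
#' template — the ideal template plus a lattice-shifted copy (see
#' [perturbed_observer()]) — emulating a distinct but still competent
#' listening strategy.
#'
#' @param n_per_group Observers per group (length-2 vector or scalar).
#' @param n_trials Trials per observer.
#' @param trials_per_session Session length.
#' @param internal_noise_sd Internal noise of all observers.
#' @param template_shift_b `c(channels, frames)` lattice shift of the
#'   idiosyncratic template component of group B.
#' @param lambda_grid Smoothing grid for cross-validation.
#' @param n_folds Cross-validation folds.
#' @param n_perm Permutations in the cluster test.
#' @param cluster_alpha Per-bin cluster-forming threshold.
#' @param roi_alpha,roi_min_size ROI rule parameters.
#' @param n_channels,fmin,fmax,n_frames Cochleogram front end.
#' @param sample_rate Stimulus sampling rate (Hz).
#' @param start_snr_db,step_db,final_step_db,floor_snr_db,ceiling_snr_db
#'   Staircase settings.
#' @param seed Master seed; every other seed is derived from it.
#' @return An `aci_study_config` list.
#' @export
study_config <- function(n_per_group = c(18, 18), n_trials = 10000,
                         trials_per_session = 500, internal_noise_sd = 0,
                         template_shift_b = c(4, 0),
                         lambda_grid = default_lambda_grid(), n_folds = 10,
                         n_perm = 5000, cluster_alpha = 0.05,
                         roi_alpha = 1e-10, roi_min_size = 7,
                         n_channels = 54, fmin = 100, fmax = 8000,
                         n_frames = 81, sample_rate = 48000,
                         start_snr_db = 0, step_db = 2, final_step_db = 1,
                         floor_snr_db = -30, ceiling_snr_db = 20,
                         seed = 1) {
  if (length(n_per_group) == 1) n_per_group <- rep(n_per_group, 2)
  cfg <- list(
    n_per_group = as.integer(n_per_group), n_trials = as.integer(n_trials),
    trials_per_session = as.integer(trials_per_session),
    internal_noise_sd = internal_noise_sd,
    template_shift_b = as.integer(template_shift_b),
    lambda_grid = lambda_grid, n_folds = as.integer(n_folds),
    n_perm = as.integer(n_perm), cluster_alpha = cluster_alpha,
    roi_alpha = roi_alpha, roi_min_size = as.integer(roi_min_size),
    n_channels = as.integer(n_channels), fmin = fmin, fmax = fmax,
    n_frames = as.integer(n_frames), sample_rate = as.integer(sample_rate),
    start_snr_db = start_snr_db, step_db = step_db,
    final_step_db = final_step_db, floor_snr_db = floor_snr_db,
    ceiling_snr_db = ceiling_snr_db, seed = as.integer(seed)
  )
  structure(cfg, class = "aci_study_config")
}

#' Write or read a study configuration as JSON
#'
#' @param config An [study_config()] object.
#' @param path JSON file path.
#' @return `write_study_config()` returns `path` invisibly;
#'   `read_study_config()` the configuration (round-trips exactly).
#' @export
write_study_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(study_config, raw[setdiff(names(raw), character())])
}

#' Serialize a fitted ACI model to plain-text files
#'
#' Writes `<stem>_beta.csv` (the raw-scale weight map, channels x frames)
#' and `<stem>.json` (intercept, lambda, CVD/CVR, standardization, folds,
#' per-fold fits, coordinates) so that a model can be rebuilt without
#' binary serialization.
#'
#' @param model An `aci_model`.
#' @param stem Output path stem (no extension).
#' @return `stem`, invisibly.
#' @export
write_aci_model <- function(model, stem) {
  utils::write.csv(model$beta, paste0(stem, "_beta.csv"),
                   row.names = FALSE)
  meta <- list(
    label = model$label, intercept = model$intercept,
    lambda = model$lambda, cvd = model$cvd, cvr = model$cvr,
    n_channels = model$n_channels, n_frames = model$n_frames,
    frame_times = model$frame_times,
    center_frequencies = model$center_frequencies,
    n_trials = model$n_trials, n_balanced = model$n_balanced,
    ridge = model$ridge, seed = model$seed,
    gradient_norm = model$gradient_norm,
    standardization = model$standardization,
    beta_std = as.vector(model$beta_std),
    folds = model$folds,
    test_sets = model$test_sets,
    fold_fits = model$fold_fits,
    cv = model$cv
  )
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' @rdname write_aci_model
#' @export
read_aci_model <- function(stem) {
  beta <- as.matrix(utils::read.csv(paste0(stem, "_beta.csv")))
  dimnames(beta) <- NULL
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE,
                              simplifyDataFrame = FALSE,
                              simplifyMatrix = FALSE)
  cv <- dplyr::bind_rows(lapply(meta$cv, function(row) {
    as_tibble(lapply(row, unlist))
  }))
  structure(
    list(label = meta$label, beta = beta,
         beta_std = matrix(unlist(meta$beta_std), meta$n_channels,
                           meta$n_frames),
         intercept = meta$intercept, lambda = meta$lambda, cvd = meta$cvd,
         cvr = meta$cvr, cv = cv,
         standardization = list(
           center = unlist(meta$standardization$center),
           scale = unlist(meta$standardization$scale)),
         folds = unlist(meta$folds),
         test_sets = lapply(meta$test_sets, function(s) {
           as.integer(unlist(s))
         }),
         fold_fits = lapply(meta$fold_fits, function(f) {
           list(beta = unlist(f$beta), intercept = f$intercept)
         }),
         n_channels = meta$n_channels, n_frames = meta$n_frames,
         frame_times = meta$frame_times,
         center_frequencies = meta$center_frequencies,
         n_trials = meta$n_trials, n_balanced = meta$n_balanced,
         ridge = meta$ridge, seed = meta$seed,
         gradient_norm = meta$gradient_norm,
         deviance_train = NA_real_),
    class = "aci_model"
  )
}

#' Plot a classification image
#'
#' Heatmap of the weight map with a diverging palette. Following the usual
#' display convention for this task, red marks bins whose noise energy
#' biases the listener toward 'da' and blue toward 'ga'; since the model
#' codes r = 1 as 'ga' (so positive weights favour 'ga'), the displayed
#' quantity is the 'da'-bias, i.e. the negated weight map. Formant
#' trajectories can be overlaid.
#'
#' @param model An `aci_model` or a channels x frames matrix.
#' @param formant_tracks Optional formant-track table
#'   ([default_formant_tracks()]) to overlay.
#' @param frame_times,center_frequencies Bin coordinates (taken from the
#'   model when available).
#' @return A ggplot object.
#' @export
plot_aci <- function(model, formant_tracks = NULL, frame_times = NULL,
                     center_frequencies = NULL) {
  if (inherits(model, "aci_model")) {
    beta <- model$beta
    frame_times <- frame_times %||% model$frame_times
    center_frequencies <- center_frequencies %||%
      model$center_frequencies
  } else {
    beta <- model
  }
  frame_times <- frame_times %||% seq_len(ncol(beta))
  center_frequencies <- center_frequencies %||% seq_len(nrow(beta))
  df <- tidy_map(-beta, frame_times, center_frequencies)
  lim <- max(abs(df$value))
  if (lim == 0) lim <- 1
  gg <- ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$freq_hz,
                                         fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_gradient2(
      name = "bias", low = "#2166ac", mid = "white", high = "#b2182b",
      limits = c(-lim, lim),
      labels = function(b) ifelse(b > 0, "'da'", ifelse(b < 0, "'ga'", "0"))
    ) +
    ggplot2::labs(x = "time (ms)", y = "frequency (Hz)")
  if (!is.null(formant_tracks)) {
    ft <- formant_tracks[formant_tracks$amp > 0, ]
    gg <- gg + ggplot2::geom_line(
      data = ft,
      ggplot2::aes(.data$time_ms, .data$freq_hz,
                   group = interaction(.data$target, .data$formant),
                   linetype = .data$target),
      inherit.aes = FALSE, linewidth = 0.3
    )
  }
  gg
}

#' Per-session SNR curves for one or more groups
#'
#' Summarizes staircase trajectories as per-session mean SNR (with standard
#' error) per group, the standard learning-curve display for adaptive
#' speech-in-noise experiments.
#'
#' @param trials Trial tibble, or a named list of trial tibbles (one per
#'   observer); an optional `group` column (or `groups` argument) labels
#'   groups.
#' @param groups Optional group label per observer (when `trials` is a
#'   list).
#' @return Tibble with `group`, `session`, `mean_snr_db`, `sem_snr_db`,
#'   `n_observers`.
#' @export
session_curves <- function(trials, groups = NULL) {
  if (is.data.frame(trials)) {
    trials <- list(obs = trials)
  }
  if (is.null(groups)) groups <- rep("all", length(trials))
  per_obs <- dplyr::bind_rows(lapply(seq_along(trials), function(i) {
    s <- session_summary(trials[[i]])
    s$observer <- names(trials)[i] %||% as.character(i)
    s$group <- groups[i]
    s
  }))
  per_obs |>
    dplyr::group_by(.data$group, .data$session) |>
    dplyr::summarise(
      n_observers = dplyr::n(),
      sem_snr_db = sd(.data$mean_snr_db) / sqrt(dplyr::n()),
      mean_snr_db = mean(.data$mean_snr_db),
      .groups = "drop"
    ) |>
    dplyr::select("group", "session", "mean_snr_db", "sem_snr_db",
                  "n_observers")
}

#' Run an end-to-end simulated classification-image study
#'
#' Executes the full synthetic pipeline defined by a [study_config()]:
#' synthesizes the targets, builds the two observer cohorts (group A uses
#' the ideal template; group B the lattice-shifted template), simulates
#' every observer's staircase experiment, cross-validates the smoothing
#' grid per observer, selects the single cohort-level smoothing value with
#' the lowest mean cross-validated deviance, refits every observer at that
#' value, and runs the cohort analyses: prediction matrix and specificity,
#' two-group cluster permutation test, pooled ROI definition with per-ROI
#' group comparison, and per-session SNR curves. All artifacts are written
#' as plain-text files under `out_dir` together with a manifest naming the
#' configuration hash and all seeds.
#'
#' @param config An [study_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with `models`, `trials`, `prediction_matrix`,
#'   `specificity`, `cluster_test`, `rois`, `roi_comparison`,
#'   `session_curves`, `lambda`, `performance`, `out_dir`.
#' @export
run_aci_study <- function(config = study_config(), out_dir = tempfile()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  targets <- synthesize_targets(sample_rate = config$sample_rate)
  fb <- gammatone_filterbank(config$n_channels, config$fmin, config$fmax,
                             config$sample_rate)
  n_total <- sum(config$n_per_group)
  group <- rep(c("A", "B"), config$n_per_group)
  labels <- paste0(group, c(seq_len(config$n_per_group[1]),
                            seq_len(config$n_per_group[2])))
  seeds <- derive_seeds(config$seed, 2L * n_total + 1L)
  base <- ideal_observer(targets, fb, config$n_frames,
                         internal_noise_sd = config$internal_noise_sd)
  obs_b <- perturbed_observer(base, targets, fb, config$n_frames,
                              d_channel = config$template_shift_b[1],
                              d_frame = config$template_shift_b[2],
                              internal_noise_sd = config$internal_noise_sd)
  observers <- lapply(seq_len(n_total), function(i) {
    proto <- if (group[i] == "A") base else obs_b
    template_observer(proto$template, criterion = proto$criterion,
                      internal_noise_sd = config$internal_noise_sd,
                      label = labels[i])
  })
  stair <- staircase_state(config$start_snr_db, config$step_db,
                           config$final_step_db, config$floor_snr_db,
                           config$ceiling_snr_db)
  message("simulating ", n_total, " observers x ", config$n_trials,
          " trials")
  with_stage <- function(stage, observer_id, expr) {
    tryCatch(expr, error = function(e) {
      stop_input("study stage '%s' failed for observer '%s': %s",
                 stage, observer_id, conditionMessage(e))
    })
  }
  trials <- vector("list", n_total)
  cvs <- vector("list", n_total)
  predictors <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    trials[[i]] <- with_stage("simulate", labels[i], run_experiment(
      observers[[i]], targets, config$n_trials, config$trials_per_session,
      seed = seeds[i], staircase = stair, filterbank = fb,
      n_frames = config$n_frames, keep_predictors = TRUE
    ))
    write_trials(trials[[i]],
                 file.path(out_dir, paste0("trials_", labels[i], ".csv")))
    predictors[[i]] <- attr(trials[[i]], "predictors")
    attr(trials[[i]], "predictors") <- NULL
    cvs[[i]] <- with_stage("cross-validate", labels[i], cross_validate_aci(
      predictors[[i]], trials[[i]], config$lambda_grid,
      n_folds = config$n_folds, seed = seeds[n_total + i]
    ))
  }
  names(trials) <- labels
  lambda_star <- select_lambda(cvs)
  message("cohort lambda = ", signif(lambda_star, 4))
  models <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    models[[i]] <- with_stage("refit", labels[i], fit_aci(
      trials[[i]], predictors = predictors[[i]], lambda = lambda_star,
      n_folds = config$n_folds, seed = seeds[n_total + i],
      label = labels[i]
    ))
    write_aci_model(models[[i]],
                    file.path(out_dir, paste0("model_", labels[i])))
  }
  data_list <- lapply(seq_len(n_total), function(i) {
    aci_data(models[[i]], predictors[[i]], trials[[i]])
  })
  pm <- prediction_matrix(models, data_list)
  spec <- specificity(pm)
  readr::write_csv(tidy(pm), file.path(out_dir, "prediction_matrix.csv"))
  readr::write_csv(spec, file.path(out_dir, "specificity.csv"))
  maps_a <- models[group == "A"]
  maps_b <- models[group == "B"]
  ct <- cluster_permutation_test(
    lapply(maps_a, `[[`, "beta"), lapply(maps_b, `[[`, "beta"),
    n_perm = config$n_perm, alpha = config$cluster_alpha,
    seed = seeds[2L * n_total + 1L]
  )
  readr::write_csv(tidy(ct)[, c("cluster", "size", "sign", "stat", "p")],
                   file.path(out_dir, "cluster_test.csv"))
  rois <- define_rois(models, alpha = config$roi_alpha,
                      min_size = config$roi_min_size)
  roi_cmp <- if (nrow(rois) > 0) {
    roi_compare(rois, maps_a, maps_b)
  } else {
    tibble(roi = integer(), mean_a = numeric(), mean_b = numeric(),
           t = numeric(), df = numeric(), p = numeric())
  }
  readr::write_csv(
    as_tibble(rois)[, c("roi", "size", "polarity", "centroid_time_ms",
                        "centroid_freq_hz", "stat")],
    file.path(out_dir, "rois.csv"))
  readr::write_csv(roi_cmp, file.path(out_dir, "roi_comparison.csv"))
  curves <- session_curves(trials, groups = group)
  readr::write_csv(curves, file.path(out_dir, "session_curves.csv"))
  perf <- dplyr::bind_rows(lapply(trials, performance_summary),
                           .id = "observer")
  perf$group <- group
  readr::write_csv(perf, file.path(out_dir, "performance.csv"))
  manifest <- list(
    config = unclass(config), config_hash = rlang::hash(unclass(config)),
    derived_seeds = seeds, lambda = lambda_star,
    package_version = as.character(utils::packageVersion("aclimage")),
    r_version = R.version.string
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(models = models, trials = trials, prediction_matrix = pm,
                 specificity = spec, cluster_test = ct, rois = rois,
                 roi_comparison = roi_cmp, session_curves = curves,
                 lambda = lambda_star, performance = perf,
                 out_dir = out_dir))
}
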