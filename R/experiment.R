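#' Run a simulated categorization-in-noise experiment
#'
#' Simulates `n_trials` trials of the four-alternative /da/-/ga/
#' categorization task. On each trial a target is drawn uniformly, a fresh
#' noise token is generated from a trial-unique seed, the mixture is formed
#' at the staircase's current SNR and power-normalized, the observer
#' responds, and the 3-down 1-up staircase is updated from the correctness
#' of the response. The full chain is reproducible from `seed`.
#'
#' @param observer An [template_observer()] or [psychometric_observer()].
#' @param targets Target set from [synthesize_targets()]; only consulted for
#'   template observers and for target labels.
#' @param n_trials Number of trials; must be divisible by
#'   `trials_per_session`.
#' @param trials_per_session Session length (default 500, so 10,000 trials
#'   form 20 sessions).
#' @param seed Master seed for the experiment.
#' @param staircase Initial staircase state ([staircase_state()]).
#' @param filterbank,n_frames,method Cochleogram front end used by template
#'   observers.
#' @param keep_predictors If `TRUE` (template observers only), the
#'   cochleogram predictor row of every trial is collected during the run
#'   and attached as attribute `"predictors"` (identical to what
#'   [trial_predictors()] would recompute from the table).
#' @return A tibble of trial records with columns `trial`, `session`,
#'   `target`, `noise_seed`, `snr_db`, `response` (0 = 'da', 1 = 'ga') and
#'   `correct`.
#' @export
run_experiment <- function(observer, targets = NULL, n_trials = 10000,
                           trials_per_session = 500, seed = 1,
                           staircase = staircase_state(),
                           filterbank = gammatone_filterbank(),
                           n_frames = 81, method = "spectral",
                           keep_predictors = FALSE) {
  if (n_trials %% trials_per_session != 0) {
    stop_input("n_trials (%d) not divisible by trials_per_session (%d)",
               n_trials, trials_per_session)
  }
  if (is.null(targets)) targets <- synthesize_targets()
  labels <- targets$labels
  is_ga <- targets$classes$stop_class == "ga"
  draws <- withr::with_seed(seed, list(
    target_idx = sample.int(length(labels), n_trials, replace = TRUE),
    noise_seed = sample.int(.Machine$integer.max - 1L, n_trials),
    internal = rnorm(n_trials),
    unif = stats::runif(n_trials)
  ))
  template_mode <- observer$type == "template"
  if (template_mode) {
    plan <- make_coch_plan(filterbank, nrow(targets$waveforms), n_frames)
    tmpl_flat <- as.vector(observer$template)
    dur_ms <- targets$total_duration_ms
    fs <- targets$sample_rate
    floor_db <- -60
    xpred <- if (keep_predictors) {
      matrix(0, n_trials, nrow(filterbank) * n_frames)
    }
  } else if (keep_predictors) {
    stop_input("keep_predictors requires a template observer")
  }
  snr <- numeric(n_trials)
  response <- integer(n_trials)
  correct <- logical(n_trials)
  state <- staircase
  for (i in seq_len(n_trials)) {
    snr[i] <- state$current_snr
    ti <- draws$target_idx[i]
    if (template_mode) {
      noise <- generate_noise(draws$noise_seed[i], dur_ms, fs)
      mixwave <- mix_at_snr(targets$waveforms[, ti], noise, snr[i])
      e <- coch_apply(mixwave, plan)
      v <- 10 * log10(e)
      v <- pmax(v, max(v) + floor_db)
      if (keep_predictors) xpred[i, ] <- as.vector(t(v))
      d <- sum(tmpl_flat * v) - observer$criterion +
        observer$internal_noise_sd * draws$internal[i]
      response[i] <- as.integer(d > 0)
      correct[i] <- response[i] == as.integer(is_ga[ti])
    } else {
      p_correct <- plogis(observer$slope * (snr[i] - observer$midpoint_db))
      correct[i] <- draws$unif[i] < p_correct
      truth <- as.integer(is_ga[ti])
      response[i] <- if (correct[i]) truth else 1L - truth
    }
    state <- staircase_update(state, correct[i])
  }
  out <- tibble(
    trial = seq_len(n_trials),
    session = rep(seq_len(n_trials / trials_per_session),
                  each = trials_per_session),
    target = labels[draws$target_idx],
    noise_seed = draws$noise_seed,
    snr_db = snr,
    response = response,
    correct = correct
  )
  if (template_mode && keep_predictors) {
    attr(xpred, "n_channels") <- nrow(filterbank)
    attr(xpred, "n_frames") <- n_frames
    attr(xpred, "frame_times") <- plan$frame_times
    attr(xpred, "center_frequencies") <- filterbank$cf_hz
    class(xpred) <- c("aci_predictors", class(xpred))
    attr(out, "predictors") <- xpred
  }
  out
}

#' Sensitivity index d-prime
#'
#' `dprime(hit_rate, fa_rate)` is `qnorm(hit_rate) - qnorm(fa_rate)`, the
#' signal-detection sensitivity for a yes/no design where a hit is a 'ga'
#' response to a 'ga' word and a false alarm a 'ga' response to a 'da' word.
#'
#' @param hit_rate,fa_rate Hit and false-alarm rates in (0, 1).
#' @return d-prime value.
#' @export
dprime <- function(hit_rate, fa_rate) {
  qnorm(hit_rate) - qnorm(fa_rate)
}

#' Summarize performance of a trial table
#'
#' Percent correct, mean SNR and d-prime for a table of trial records. Hit
#' and false-alarm rates receive the 1/(2N) edge correction before the
#' z-transform, where N is the per-class trial count.
#'
#' @param trials Trial tibble from [run_experiment()].
#' @param targets Target set (for the da/ga class of each label); defaults
#'   to labels ending in "da"/"ga".
#' @return One-row tibble with `n_trials`, `percent_correct`, `mean_snr_db`,
#'   `hit_rate`, `fa_rate`, `dprime`.
#' @export
performance_summary <- function(trials, targets = NULL) {
  if (nrow(trials) == 0) stop_input("empty trial table")
  is_ga <- if (is.null(targets)) {
    grepl("ga$", trials$target)
  } else {
    trials$target %in%
      targets$classes$target[targets$classes$stop_class == "ga"]
  }
  n_ga <- sum(is_ga)
  n_da <- sum(!is_ga)
  if (n_ga == 0 || n_da == 0) {
    stop_input("both 'da' and 'ga' targets are required for d-prime")
  }
  h <- sum(trials$response == 1 & is_ga) / n_ga
  fa <- sum(trials$response == 1 & !is_ga) / n_da
  h <- min(max(h, 1 / (2 * n_ga)), 1 - 1 / (2 * n_ga))
  fa <- min(max(fa, 1 / (2 * n_da)), 1 - 1 / (2 * n_da))
  tibble(
    n_trials = nrow(trials),
    percent_correct = 100 * mean(trials$correct),
    mean_snr_db = mean(trials$snr_db),
    hit_rate = h,
    fa_rate = fa,
    dprime = dprime(h, fa)
  )
}

#' Per-session summaries of a trial table
#'
#' Mean SNR (with standard error) and percent correct per session, the
#' learning-curve summary of an adaptive-staircase experiment.
#'
#' @param trials Trial tibble; sessions must have equal length.
#' @return Tibble with one row per session: `session`, `n`, `mean_snr_db`,
#'   `sem_snr_db`, `percent_correct`.
#' @export
session_summary <- function(trials) {
  sizes <- table(trials$session)
  if (length(unique(as.integer(sizes))) > 1) {
    stop_input("sessions have unequal lengths")
  }
  trials |>
    dplyr::group_by(.data$session) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_snr_db = mean(.data$snr_db),
      sem_snr_db = sd(.data$snr_db) / sqrt(dplyr::n()),
      percent_correct = 100 * mean(.data$correct),
      .groups = "drop"
    )
}

#' Read and write trial tables as CSV
#'
#' The on-disk schema has exactly the columns `trial`, `session`, `target`,
#' `noise_seed`, `snr_db`, `response`, `correct` and round-trips without
#' loss.
#'
#' @param trials Trial tibble.
#' @param path CSV file path.
#' @return `write_trials()` returns `path` invisibly; `read_trials()` the
#'   trial tibble.
#' @export
write_trials <- function(trials, path) {
  readr::write_csv(trials[, c("trial", "session", "target", "noise_seed",
                              "snr_db", "response", "correct")], path)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    trial = readr::col_integer(),
    session = readr::col_integer(),
    target = readr::col_character(),
    noise_seed = readr::col_integer(),
    snr_db = readr::col_double(),
    response = readr::col_integer(),
    correct = readr::col_logical()
  ))
}
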