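#' Simulated listeners for the phoneme-categorization-in-noise task
#'
#' `template_observer()` defines a linear-template listener: on each trial it
#' computes the inner product between its spectrotemporal weight template and
#' the cochleogram of the noisy stimulus, adds Gaussian internal noise, and
#' responds "ga" (r = 1) when the decision variable exceeds zero. This is
#' the generative counterpart of the GLM fitted by [fit_aci()] and carries
#' the ground-truth template for parameter-recovery checks.
#'
#' `psychometric_observer()` defines a listener characterized only by a
#' logistic psychometric function of SNR: the probability of a correct
#' categorization is `plogis(slope * (snr_db - midpoint))`. It bypasses the
#' stimulus pipeline and is useful for testing the adaptive-staircase
#' machinery analytically.
#'
#' @param template Channels x frames weight matrix (or `cochleogram`).
#' @param criterion Decision criterion subtracted from the template match.
#' @param internal_noise_sd Standard deviation of the additive internal
#'   noise on the decision variable (>= 0).
#' @param label Observer identifier.
#' @return An `aci_observer` object.
#' @export
template_observer <- function(template, criterion = 0,
                              internal_noise_sd = 0, label = "obs") {
  if (inherits(template, "cochleogram")) template <- template$values
  if (!is.matrix(template) || !all(is.finite(template))) {
    stop_input("template must be a finite numeric matrix")
  }
  if (internal_noise_sd < 0) stop_input("internal_noise_sd must be >= 0")
  structure(
    list(type = "template", template = template, criterion = criterion,
         internal_noise_sd = internal_noise_sd, label = label),
    class = "aci_observer"
  )
}

#' @rdname template_observer
#' @param midpoint_db SNR (dB) at which the observer is correct with
#'   probability 0.5.
#' @param slope Psychometric slope per dB.
#' @export
psychometric_observer <- function(midpoint_db = -12, slope = 1,
                                  label = "obs") {
  structure(
    list(type = "psychometric", midpoint_db = midpoint_db, slope = slope,
         label = label),
    class = "aci_observer"
  )
}

#' @export
print.aci_observer <- function(x, ...) {
  if (x$type == "template") {
    cat(sprintf(
      "<aci_observer> '%s': %dx%d template, criterion %.3g, internal noise sd %.3g\n",
      x$label, nrow(x$template), ncol(x$template), x$criterion,
      x$internal_noise_sd))
  } else {
    cat(sprintf(
      "<aci_observer> '%s': psychometric, midpoint %g dB, slope %g/dB\n",
      x$label, x$midpoint_db, x$slope))
  }
  invisible(x)
}

#' Ideal-template observer for a target set
#'
#' Builds the template as the difference between the mean clean-target
#' cochleogram of the 'ga' words and that of the 'da' words, centred to zero
#' mean (so that the overall stimulus level, which is uninformative after
#' power normalization, does not drive the decision) and scaled to unit
#' Frobenius norm. The criterion is the template match with the mean clean
#' cochleogram, placing the decision boundary midway between the classes.
#'
#' Because log-compressed band energies shift asymmetrically once noise is
#' added, the clean-stimulus criterion would leave the observer response-
#' biased in noise; the criterion is therefore calibrated as the midpoint
#' between the mean template match on noisy 'ga' mixtures and on noisy 'da'
#' mixtures (`calibrate_n` mixtures, trial-unique noise) at
#' `calibrate_snr_db`, chosen near the staircase's operating range, which
#' makes hits and correct rejections roughly symmetric there.
#'
#' @param targets An [synthesize_targets()] object.
#' @param filterbank Filterbank used for the cochleograms.
#' @param n_frames Number of cochleogram frames.
#' @param internal_noise_sd Internal noise on the decision variable.
#' @param label Observer identifier.
#' @param method Cochleogram method.
#' @param calibrate_snr_db Reference SNR (dB) for criterion calibration;
#'   `NULL` skips calibration and uses the clean-stimulus criterion.
#' @param calibrate_n Number of calibration mixtures.
#' @param calibrate_seed Seed for the calibration noise tokens.
#' @return An `aci_observer` with the ideal template.
#' @export
ideal_observer <- function(targets, filterbank = gammatone_filterbank(),
                           n_frames = 81, internal_noise_sd = 0,
                           label = "ideal", method = "spectral",
                           calibrate_snr_db = -12, calibrate_n = 120,
                           calibrate_seed = 20160421) {
  maps <- lapply(targets$labels, function(lab) {
    cochleogram(targets$waveforms[, lab], filterbank, n_frames,
                method = method)$values
  })
  names(maps) <- targets$labels
  ga <- targets$classes$target[targets$classes$stop_class == "ga"]
  da <- targets$classes$target[targets$classes$stop_class == "da"]
  tmpl <- Reduce(`+`, maps[ga]) / length(ga) -
    Reduce(`+`, maps[da]) / length(da)
  tmpl <- tmpl - mean(tmpl)
  tmpl <- tmpl / sqrt(sum(tmpl^2))
  if (is.null(calibrate_snr_db)) {
    crit <- mean(vapply(maps, function(m) sum(tmpl * m), numeric(1)))
    return(template_observer(tmpl, criterion = crit,
                             internal_noise_sd = internal_noise_sd,
                             label = label))
  }
  calibrate_observer(tmpl, targets, filterbank, n_frames,
                     internal_noise_sd = internal_noise_sd, label = label,
                     method = method, snr_db = calibrate_snr_db,
                     n = calibrate_n, seed = calibrate_seed)
}

#' Build a template observer with a calibrated decision criterion
#'
#' Sets the criterion of a template observer to the midpoint between the
#' mean template match on noisy 'ga' mixtures and on noisy 'da' mixtures at
#' a reference SNR, so that the observer's responses are roughly unbiased
#' near that operating point. Any template (e.g. a lattice-shifted variant
#' of the ideal template) can be calibrated this way.
#'
#' @param template Channels x frames weight matrix.
#' @param targets An [synthesize_targets()] object.
#' @param filterbank,n_frames,method Cochleogram front end.
#' @param internal_noise_sd Internal noise on the decision variable.
#' @param label Observer identifier.
#' @param snr_db Reference SNR for the calibration mixtures.
#' @param n Number of calibration mixtures.
#' @param seed Seed for the calibration noise tokens.
#' @return An `aci_observer`.
#' @export
calibrate_observer <- function(template, targets,
                               filterbank = gammatone_filterbank(),
                               n_frames = 81, internal_noise_sd = 0,
                               label = "obs", method = "spectral",
                               snr_db = -12, n = 120, seed = 20160421) {
  seeds <- derive_seeds(seed, n)
  ti <- rep_len(seq_along(targets$labels), n)
  matches <- vapply(seq_len(n), function(i) {
    noise <- generate_noise(seeds[i], targets$total_duration_ms,
                            targets$sample_rate)
    mix <- mix_at_snr(targets$waveforms[, ti[i]], noise, snr_db)
    sum(template * cochleogram(mix, filterbank, n_frames,
                               method = method)$values)
  }, numeric(1))
  is_ga <- targets$classes$stop_class[ti] == "ga"
  crit <- (mean(matches[is_ga]) + mean(matches[!is_ga])) / 2
  template_observer(template, criterion = crit,
                    internal_noise_sd = internal_noise_sd, label = label)
}

#' Shift a template on the time-frequency lattice
#'
#' Translates a weight map by whole channels/frames, zero-filling the
#' vacated bins. Used to build cohorts of observers with distinct but
#' equally smooth listening strategies.
#'
#' @param template Channels x frames matrix.
#' @param d_channel,d_frame Shift in channels (positive = toward higher
#'   frequencies) and frames (positive = later).
#' @return Shifted matrix of the same dimensions.
#' @export
shift_template <- function(template, d_channel = 0, d_frame = 0) {
  nc <- nrow(template)
  nf <- ncol(template)
  out <- matrix(0, nc, nf)
  src_c <- seq_len(nc) - d_channel
  src_f <- seq_len(nf) - d_frame
  ok_c <- src_c >= 1 & src_c <= nc
  ok_f <- src_f >= 1 & src_f <= nf
  out[ok_c, ok_f] <- template[src_c[ok_c], src_f[ok_f]]
  out
}

#' Observer with an idiosyncratic but competent listening strategy
#'
#' Builds a template as the base observer's template plus a lattice-shifted
#' copy weighted by `weight`, re-centred and re-normalized, then calibrates
#' the decision criterion (see [calibrate_observer()]). The blend retains
#' the shared task-relevant cue structure — so the observer still performs
#' the task — while reweighting it idiosyncratically; a pure lattice shift
#' would instead destroy discriminability altogether. Used to simulate
#' cohorts of listeners with distinct strategies.
#'
#' @param base A template `aci_observer` (e.g. [ideal_observer()]).
#' @param targets,filterbank,n_frames,method Stimulus front end for the
#'   calibration.
#' @param d_channel,d_frame Lattice shift of the idiosyncratic component.
#' @param weight Weight of the shifted component relative to the base.
#' @param internal_noise_sd Internal noise (defaults to the base's).
#' @param label Observer identifier.
#' @return A calibrated `aci_observer`.
#' @export
perturbed_observer <- function(base, targets,
                               filterbank = gammatone_filterbank(),
                               n_frames = 81, d_channel = 0, d_frame = 0,
                               weight = 1, internal_noise_sd = NULL,
                               label = "perturbed", method = "spectral") {
  tb <- base$template +
    weight * shift_template(base$template, d_channel, d_frame)
  tb <- tb - mean(tb)
  tb <- tb / sqrt(sum(tb^2))
  calibrate_observer(tb, targets, filterbank, n_frames,
                     internal_noise_sd = internal_noise_sd %||%
                       base$internal_noise_sd,
                     label = label, method = method)
}

#' One decision of a template observer
#'
#' Computes the decision variable `d = <template, cochleogram> - criterion +
#' e` with `e ~ N(0, internal_noise_sd^2)` and returns `r = 1` ('ga') if
#' `d > 0`, else `r = 0` ('da').
#'
#' @param observer A template [template_observer()].
#' @param coch A `cochleogram` (or matrix) of the same shape as the
#'   template.
#' @param noise Optional pre-drawn standard-normal deviate for the internal
#'   noise (used by the trial runner for reproducibility); if `NULL` one is
#'   drawn from the current RNG.
#' @return Integer response 0 or 1.
#' @export
decide <- function(observer, coch, noise = NULL) {
  if (observer$type != "template") {
    stop_input("decide() needs a template observer")
  }
  m <- if (inherits(coch, "cochleogram")) coch$values else coch
  if (!all(dim(m) == dim(observer$template))) {
    stop_input("cochleogram shape %dx%d does not match template %dx%d",
               nrow(m), ncol(m), nrow(observer$template),
               ncol(observer$template))
  }
  if (is.null(noise)) noise <- rnorm(1)
  d <- sum(observer$template * m) - observer$criterion +
    observer$internal_noise_sd * noise
  as.integer(d > 0)
}
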