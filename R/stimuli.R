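#' Default formant trajectories for the four /aCCa/ nonword targets
#'
#' Piecewise-linear F1-F4 trajectories for the four nonwords `alda`, `alga`,
#' `aRda` and `aRga`: a first syllable /al/ or /aR/ (328 ms, uvular /R/
#' lowering F3), a short stop closure, then the second syllable /da/ or /ga/
#' whose formant onsets carry the place-of-articulation cue. The /da/ targets
#' start syllable 2 with F2 near 1380 Hz and F3 near 2557 Hz; the /ga/
#' targets start with F2 and F3 converging near 1950-2050 Hz. F1 onset is
#' near 665 Hz for all targets.
#'
#' @param total_duration_ms Total target duration in ms.
#' @param syllable1_duration_ms Duration of the first syllable in ms.
#' @return A tibble with columns `target`, `formant`, `time_ms`, `freq_hz`,
#'   `amp` giving knot points; tracks are linearly interpolated between knots.
#' @export
default_formant_tracks <- function(total_duration_ms = 680,
                                   syllable1_duration_ms = 328) {
  s1 <- syllable1_duration_ms
  tot <- total_duration_ms
  # common knot times: /a/ steady, consonant, closure, release, /a/ steady
  tt <- c(0, 20, s1 - 88, s1 - 68, s1 - 2, s1 + 4, s1 + 13, s1 + 20,
          s1 + 102, tot - 40, tot)
  amp <- c(0, 1, 1, 0.6, 0.6, 0, 0, 0.9, 1, 1, 0)
  vowel <- c(F1 = 700, F2 = 1300, F3 = 2500, F4 = 3500)
  ctx <- list(
    l = c(F1 = 400, F2 = 1050, F3 = 2800, F4 = 3500),
    R = c(F1 = 500, F2 = 1100, F3 = 1700, F4 = 3300)
  )
  onset <- list(
    da = c(F1 = 665, F2 = 1380, F3 = 2557, F4 = 3600),
    ga = c(F1 = 665, F2 = 1950, F3 = 2050, F4 = 3400)
  )
  labels <- c("alda", "alga", "aRda", "aRga")
  rows <- lapply(labels, function(lab) {
    cons <- substr(lab, 2, 2)
    stop_cons <- substr(lab, 3, 4)
    cv <- ctx[[cons]]
    on <- onset[[stop_cons]]
    per_formant <- lapply(names(vowel), function(f) {
      freq <- c(vowel[f], vowel[f], vowel[f], cv[f], cv[f], cv[f],
                on[f], on[f], vowel[f], vowel[f], vowel[f])
      tibble(target = lab, formant = f, time_ms = tt,
             freq_hz = unname(freq), amp = amp)
    })
    dplyr::bind_rows(per_formant)
  })
  dplyr::bind_rows(rows)
}

#' Synthesize the four target nonwords by additive formant synthesis
#'
#' Each target is a sum of four amplitude-modulated sinusoids following the
#' F1-F4 trajectories of `tracks`, sampled at `sample_rate` and
#' power-normalized to unit RMS. This is a formant-synthesized stand-in for
#' recorded natural speech: it preserves the spectrotemporal cue geometry
#' (formant onset frequencies and timing) that the classification-image
#' analysis interrogates, not natural-speech fidelity.
#'
#' @param tracks Formant-track table as produced by
#'   [default_formant_tracks()].
#' @param sample_rate Sampling rate in Hz.
#' @param total_duration_ms Total duration in ms.
#' @param syllable1_duration_ms First-syllable duration in ms.
#' @param formant_amps Relative amplitude of F1-F4 partials.
#' @return An object of class `aci_targets`: a list with `labels`,
#'   `waveforms` (samples x 4 matrix, unit RMS columns), `sample_rate`,
#'   `total_duration_ms`, `syllable1_duration_ms`, `formant_tracks` and a
#'   `classes` tibble giving each target's stop class (da/ga) and context
#'   (l/R).
#' @export
synthesize_targets <- function(tracks = default_formant_tracks(),
                               sample_rate = 48000,
                               total_duration_ms = 680,
                               syllable1_duration_ms = 328,
                               formant_amps = c(1, 0.7, 0.45, 0.3)) {
  labels <- unique(tracks$target)
  if (length(labels) != 4) {
    stop_input("expected formant tracks for exactly 4 targets, got %d",
               length(labels))
  }
  n <- round(total_duration_ms / 1000 * sample_rate)
  t_ms <- (seq_len(n) - 1) / sample_rate * 1000
  waves <- matrix(0, n, length(labels), dimnames = list(NULL, labels))
  for (lab in labels) {
    tr <- tracks[tracks$target == lab, ]
    if (min(tr$time_ms) > 0 || max(tr$time_ms) < total_duration_ms) {
      stop_input("formant tracks for '%s' do not cover [0, %g] ms",
                 lab, total_duration_ms)
    }
    freqs <- sapply(paste0("F", 1:4), function(f) {
      k <- tr[tr$formant == f, ]
      approx(k$time_ms, k$freq_hz, xout = t_ms, rule = 2)$y
    })
    if (any(freqs[, 1] >= freqs[, 2] | freqs[, 2] >= freqs[, 3] |
            freqs[, 3] >= freqs[, 4])) {
      stop_input("formant ordering F1 < F2 < F3 < F4 violated for '%s'", lab)
    }
    x <- numeric(n)
    for (j in 1:4) {
      k <- tr[tr$formant == paste0("F", j), ]
      a <- approx(k$time_ms, k$amp, xout = t_ms, rule = 2)$y
      phase <- 2 * pi * cumsum(freqs[, j]) / sample_rate
      x <- x + formant_amps[j] * a * sin(phase)
    }
    r <- rms(x)
    if (r == 0) {
      stop_input("target '%s' synthesized to silence; cannot power-normalize",
                 lab)
    }
    waves[, lab] <- x / r
  }
  classes <- tibble(
    target = labels,
    stop_class = ifelse(grepl("da$", labels), "da", "ga"),
    context = ifelse(grepl("^al", labels), "l", "R")
  )
  structure(
    list(labels = labels, waveforms = waves, sample_rate = sample_rate,
         total_duration_ms = total_duration_ms,
         syllable1_duration_ms = syllable1_duration_ms,
         formant_tracks = tracks, classes = classes),
    class = "aci_targets"
  )
}

#' @export
print.aci_targets <- function(x, ...) {
  cat(sprintf("<aci_targets> %s\n", paste(x$labels, collapse = ", ")))
  cat(sprintf("  %d samples (%g ms at %d Hz), syllable 1 = %g ms\n",
              nrow(x$waveforms), x$total_duration_ms, x$sample_rate,
              x$syllable1_duration_ms))
  invisible(x)
}

#' Generate a reproducible white-noise token
#'
#' Draws i.i.d. Gaussian samples from the given seed and normalizes the
#' token to unit RMS. The same seed always yields the bit-identical
#' waveform; the caller's RNG state is untouched.
#'
#' @param seed Integer seed identifying the noise realization.
#' @param duration_ms Duration in ms.
#' @param sample_rate Sampling rate in Hz.
#' @return Numeric waveform of `round(duration_ms / 1000 * sample_rate)`
#'   samples with RMS 1.
#' @export
generate_noise <- function(seed, duration_ms = 680, sample_rate = 48000) {
  if (duration_ms <= 0) stop_input("duration must be positive")
  n <- round(duration_ms / 1000 * sample_rate)
  x <- withr::with_seed(as.integer(seed), rnorm(n))
  x / rms(x)
}

#' Mix a target and a noise token at a given SNR
#'
#' The noise gain is set so that, before the final normalization,
#' `20 * log10(RMS(target) / RMS(scaled noise))` equals `snr_db`; the mixture
#' is then power-normalized to unit RMS so that absolute level carries no
#' information.
#'
#' @param target,noise Waveforms of equal length and nonzero RMS.
#' @param snr_db Signal-to-noise ratio in dB (full-waveform RMS definition).
#' @return Mixture waveform with RMS 1.
#' @export
mix_at_snr <- function(target, noise, snr_db) {
  if (length(target) != length(noise)) {
    stop_input("target and noise lengths differ (%d vs %d)",
               length(target), length(noise))
  }
  rt <- rms(target)
  rn <- rms(noise)
  if (rt == 0 || rn == 0) stop_input("zero-RMS input to mix_at_snr")
  g <- rt / rn * 10^(-snr_db / 20)
  y <- target + g * noise
  y / rms(y)
}
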