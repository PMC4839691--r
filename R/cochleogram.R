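#' ERB-rate scale conversions (Glasberg & Moore)
#'
#' @param f Frequency in Hz.
#' @param e ERB-rate (ERB-number) value.
#' @return `hz_to_erb_rate()` maps Hz to ERB-rate; `erb_rate_to_hz()` is its
#'   inverse; `erb_bandwidth()` gives the equivalent rectangular bandwidth in
#'   Hz at centre frequency `f`.
#' @export
hz_to_erb_rate <- function(f) 21.4 * log10(4.37 * f / 1000 + 1)

#' @rdname hz_to_erb_rate
#' @export
erb_rate_to_hz <- function(e) (10^(e / 21.4) - 1) * 1000 / 4.37

#' @rdname hz_to_erb_rate
#' @export
erb_bandwidth <- function(f) 24.7 * (4.37 * f / 1000 + 1)

#' Gammatone filterbank with ERB-spaced centre frequencies
#'
#' Builds descriptors for `n_channels` fourth-order gammatone bandpass
#' filters whose centre frequencies are uniformly spaced on the ERB-rate
#' scale between `fmin` and `fmax` (both included), i.e. quasi-logarithmic
#' frequency spacing.
#'
#' @param n_channels Number of channels (>= 2).
#' @param fmin,fmax Frequency bounds in Hz; `fmax` must not exceed Nyquist.
#' @param sample_rate Sampling rate in Hz.
#' @return An `aci_filterbank` tibble with columns `channel`, `cf_hz`
#'   (strictly increasing) and `bw_hz` (1.019 x ERB), carrying
#'   `sample_rate` as an attribute.
#' @export
gammatone_filterbank <- function(n_channels = 54, fmin = 100, fmax = 8000,
                                 sample_rate = 48000) {
  if (n_channels < 2) stop_input("n_channels must be >= 2")
  if (fmin <= 0 || fmin >= fmax) stop_input("need 0 < fmin < fmax")
  if (fmax > sample_rate / 2) {
    stop_input("fmax (%g Hz) above Nyquist (%g Hz)", fmax, sample_rate / 2)
  }
  cf <- erb_rate_to_hz(seq(hz_to_erb_rate(fmin), hz_to_erb_rate(fmax),
                           length.out = n_channels))
  cf[1] <- fmin
  cf[n_channels] <- fmax
  fb <- tibble(channel = seq_len(n_channels), cf_hz = cf,
               bw_hz = 1.019 * erb_bandwidth(cf))
  attr(fb, "sample_rate") <- sample_rate
  class(fb) <- c("aci_filterbank", class(fb))
  fb
}

# Precomputed plan for the spectral cochleogram path: frame boundaries plus
# the channels x FFT-bins weight matrix. Reused across trials.
make_coch_plan <- function(filterbank, n_samples, n_frames,
                           sample_rate = attr(filterbank, "sample_rate")) {
  frame_len <- ceiling(n_samples / n_frames)
  n_pad <- frame_len * n_frames
  nfft <- 2^ceiling(log2(frame_len))
  freqs <- (0:(nfft / 2)) * sample_rate / nfft
  w <- outer(seq_len(nrow(filterbank)), seq_along(freqs), function(i, j) {
    (1 + ((freqs[j] - filterbank$cf_hz[i]) / filterbank$bw_hz[i])^2)^(-4)
  })
  w <- w / rowSums(w)
  frame_times <- ((seq_len(n_frames) - 0.5) * frame_len) / sample_rate * 1000
  list(frame_len = frame_len, n_pad = n_pad, n_frames = n_frames,
       nfft = nfft, weights = w, frame_times = frame_times,
       center_frequencies = filterbank$cf_hz, sample_rate = sample_rate)
}

# Spectral path: frame the padded signal, per-frame FFT power spectrum,
# weight by gammatone power responses. Returns channels x frames energies.
coch_apply <- function(wave, plan) {
  x <- c(wave, numeric(plan$n_pad - length(wave)))
  frames <- matrix(x, nrow = plan$frame_len)
  padded <- rbind(frames, matrix(0, plan$nfft - plan$frame_len,
                                 plan$n_frames))
  spec <- mvfft(padded)[seq_len(plan$nfft / 2 + 1), , drop = FALSE]
  p <- Re(spec)^2 + Im(spec)^2
  plan$weights %*% p
}

#' Compute the cochleogram of a stimulus
#'
#' Converts a waveform into a `n_channels x n_frames` map of log-compressed
#' band energies, the predictors of the classification-image GLM. Two front
#' ends are provided. The default `"spectral"` method frames the signal into
#' `n_frames` contiguous equal windows and weights each frame's FFT power
#' spectrum by the gammatone power responses (a fast gammatonegram). The
#' `"gammatone"` method filters the waveform through each fourth-order
#' gammatone filter in the time domain, extracts envelopes by half-wave
#' rectification and a 2nd-order Butterworth lowpass at 150 Hz, and averages
#' squared envelopes within frames. Both are log-compressed to dB with a
#' floor `floor_db` below the map maximum.
#'
#' @param wave Numeric waveform.
#' @param filterbank An [gammatone_filterbank()] descriptor.
#' @param n_frames Number of time frames.
#' @param method `"spectral"` (default, fast) or `"gammatone"`.
#' @param floor_db Compression floor in dB relative to the map maximum
#'   (negative).
#' @param envelope_cutoff_hz Envelope lowpass cutoff for the gammatone
#'   method.
#' @return A `cochleogram` object: list with `values` (channels x frames
#'   matrix, dB), `center_frequencies` (Hz), `frame_times` (ms, frame
#'   centres), `floor_db`, `method`, `sample_rate`.
#' @export
cochleogram <- function(wave, filterbank = gammatone_filterbank(),
                        n_frames = 81,
                        method = c("spectral", "gammatone"),
                        floor_db = -60, envelope_cutoff_hz = 150) {
  method <- match.arg(method)
  fs <- attr(filterbank, "sample_rate")
  if (method == "spectral") {
    plan <- make_coch_plan(filterbank, length(wave), n_frames)
    e <- coch_apply(wave, plan)
    frame_times <- plan$frame_times
  } else {
    e <- gammatone_energies(wave, filterbank, n_frames, envelope_cutoff_hz)
    frame_len <- ceiling(length(wave) / n_frames)
    frame_times <- ((seq_len(n_frames) - 0.5) * frame_len) / fs * 1000
  }
  vals <- 10 * log10(e)
  if (!any(is.finite(vals))) {
    vals <- matrix(floor_db, nrow(e), ncol(e))
  } else {
    vals <- pmax(vals, max(vals[is.finite(vals)]) + floor_db)
  }
  structure(
    list(values = vals, center_frequencies = filterbank$cf_hz,
         frame_times = frame_times, floor_db = floor_db, method = method,
         sample_rate = fs),
    class = "cochleogram"
  )
}

# time-domain gammatone filtering + rectify/lowpass envelope, framed means
gammatone_energies <- function(wave, filterbank, n_frames, cutoff_hz) {
  fs <- attr(filterbank, "sample_rate")
  n <- length(wave)
  frame_len <- ceiling(n / n_frames)
  x <- c(wave, numeric(frame_len * n_frames - n))
  frame_id <- rep(seq_len(n_frames), each = frame_len)
  lp <- signal::butter(2, cutoff_hz / (fs / 2), type = "low")
  ir_len <- min(length(x), round(0.050 * fs))
  t_ir <- (0:(ir_len - 1)) / fs
  nfft <- stats::nextn(length(x) + ir_len - 1, 2)
  xf <- fft(c(x, numeric(nfft - length(x))))
  e <- matrix(0, nrow(filterbank), n_frames)
  for (i in seq_len(nrow(filterbank))) {
    cf <- filterbank$cf_hz[i]
    bw <- filterbank$bw_hz[i]
    g <- t_ir^3 * exp(-2 * pi * bw * t_ir) * cos(2 * pi * cf * t_ir)
    g <- g / Mod(sum(g * exp(-2i * pi * cf * t_ir)))  # unit gain at cf
    gf <- fft(c(g, numeric(nfft - ir_len)))
    y <- Re(fft(xf * gf, inverse = TRUE))[seq_along(x)] / nfft
    env <- signal::filter(lp, pmax(y, 0))
    e[i, ] <- tapply(as.numeric(env)^2, frame_id, mean)
  }
  e
}

#' Flatten a cochleogram into the GLM predictor vector
#'
#' The ordering is channel-major: the frequency (channel) index varies
#' slowest, so element `(channel 1, frame 1)` maps to vector position 1 and
#' position `k` holds channel `(k - 1) %/% n_frames + 1`, frame
#' `(k - 1) %% n_frames + 1`. `unflatten_cochleogram()` inverts it.
#'
#' @param x A `cochleogram` or a channels x frames matrix.
#' @return Numeric vector of length `n_channels * n_frames`.
#' @export
flatten_cochleogram <- function(x) {
  m <- if (inherits(x, "cochleogram")) x$values else x
  as.vector(t(m))
}

#' @rdname flatten_cochleogram
#' @param v Flattened predictor vector.
#' @param n_channels,n_frames Lattice dimensions.
#' @return `unflatten_cochleogram()`: a channels x frames matrix.
#' @export
unflatten_cochleogram <- function(v, n_channels = 54, n_frames = 81) {
  matrix(v, n_channels, n_frames, byrow = TRUE)
}

#' Serialize a cochleogram to plain-text files
#'
#' Writes `<stem>_values.csv` (channels x frames energy matrix, dB) and
#' `<stem>.json` (centre frequencies, frame times, floor, method, sample
#' rate, bin ordering), so cochleograms can be exchanged without binary
#' serialization. `read_cochleogram()` rebuilds the object.
#'
#' @param x A `cochleogram`.
#' @param stem Output path stem (no extension).
#' @return `stem` (write) or the `cochleogram` (read).
#' @export
write_cochleogram <- function(x, stem) {
  utils::write.csv(x$values, paste0(stem, "_values.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(center_frequencies = x$center_frequencies,
         frame_times = x$frame_times, floor_db = x$floor_db,
         method = x$method, sample_rate = x$sample_rate,
         ordering = "channel-major (frequency index slowest)"),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(stem)
}

#' @rdname write_cochleogram
#' @export
read_cochleogram <- function(stem) {
  values <- as.matrix(utils::read.csv(paste0(stem, "_values.csv")))
  dimnames(values) <- NULL
  meta <- jsonlite::read_json(paste0(stem, ".json"),
                              simplifyVector = TRUE)
  structure(
    list(values = values, center_frequencies = meta$center_frequencies,
         frame_times = meta$frame_times, floor_db = meta$floor_db,
         method = meta$method, sample_rate = meta$sample_rate),
    class = "cochleogram"
  )
}

#' @export
print.cochleogram <- function(x, ...) {
  cat(sprintf("<cochleogram> %d channels x %d frames (%s method)\n",
              nrow(x$values), ncol(x$values), x$method))
  cat(sprintf("  %.0f-%.0f Hz, frames %.1f-%.1f ms, floor %g dB\n",
              min(x$center_frequencies), max(x$center_frequencies),
              min(x$frame_times), max(x$frame_times), x$floor_db))
  invisible(x)
}

#' @export
autoplot.cochleogram <- function(object, ...) {
  df <- tidy_map(object$values, object$frame_times,
                 object$center_frequencies)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$freq_hz,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c(name = "dB") +
    ggplot2::labs(x = "time (ms)", y = "frequency (Hz)")
}

# long-format tibble for a channels x frames map
tidy_map <- function(values, frame_times, center_frequencies) {
  tibble(
    channel = rep(seq_len(nrow(values)), times = ncol(values)),
    frame = rep(seq_len(ncol(values)), each = nrow(values)),
    time_ms = rep(frame_times, each = nrow(values)),
    freq_hz = rep(center_frequencies, times = ncol(values)),
    value = as.vector(values)
  )
}
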