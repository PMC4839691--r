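#' Root-mean-square amplitude
#'
#' @param x Numeric waveform.
#' @return RMS of `x` as a scalar.
#' @export
rms <- function(x) {
  sqrt(mean(x^2))
}

# binomial deviance contribution, numerically stable in the linear predictor
# dev(eta, y) = 2 * [log(1 + exp(eta)) - y * eta]
log1pexp <- function(x) {
  out <- numeric(length(x))
  big <- x > 35
  out[big] <- x[big]
  out[!big] <- log1p(exp(x[!big]))
  out
}

clip01 <- function(p, eps = 1e-12) {
  pmin(pmax(p, eps), 1 - eps)
}

stop_input <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "aclimage_error")
}

# draw k sub-seeds reproducibly from one master seed without touching the
# caller's RNG state; values stay below 2^31 so they are valid R seeds
derive_seeds <- function(seed, k) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}
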