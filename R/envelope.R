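# Wavelet power envelope: complex Morlet transform across the detection
# band, power averaged over scales, then smoothed.

# Frequency-domain Morlet power for one channel across center frequencies.
# Analytic wavelet (positive frequencies only), unit peak response, so a
# pure sinusoid of amplitude A at a center frequency contributes |w|^2 =
# A^2 at that scale.
morlet_power_matrix <- function(x, rate, freqs, cycles) {
  n <- length(x)
  pad <- min(n - 1L, 2L * as.integer(round(2 * rate)))
  xp <- c(2 * x[1L] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  np <- length(xp)
  nfft <- stats::nextn(np, c(2, 3, 5))
  xp <- c(xp, numeric(nfft - np))
  X <- stats::fft(xp)
  w <- c(seq(0, floor(nfft / 2)), seq(-ceiling(nfft / 2) + 1L, -1L)) *
    rate / nfft
  acc <- numeric(n)
  for (f0 in freqs) {
    sig_t <- cycles / (2 * pi * f0)
    G <- numeric(nfft)
    pos <- w > 0
    G[pos] <- 2 * exp(-0.5 * (2 * pi * (w[pos] - f0) * sig_t)^2)
    y <- stats::fft(X * G, inverse = TRUE) / nfft
    acc <- acc + Mod(y[(pad + 1L):(pad + n)])^2
  }
  acc / length(freqs)
}

#' Wavelet band power envelope
#'
#' Computes, per channel, the mean power of a complex Morlet wavelet
#' transform across center frequencies spanning the detection band (default
#' 5-16 Hz in 0.5 Hz steps), then smooths with a short moving average. The
#' result is the quantity that is thresholded to find candidate spindles:
#' it is non-negative, sample-aligned with the recording, and scales with
#' the square of the signal amplitude.
#'
#' @param rec A recording.
#' @param config A [detection_config()].
#' @return A tibble of class `eeg_envelope` with `time` and one power
#'   column per channel; attributes `rate` and `band`.
#' @examples
#' rec <- as_recording(matrix(sin(2 * pi * 12 * (0:999) / 250)), rate = 250)
#' env <- band_power_envelope(rec, detection_config())
#' @export
band_power_envelope <- function(rec, config = detection_config()) {
  rate <- eeg_rate(rec)
  if (rate < 2 * config$detect_band[2]) {
    stop("sampling rate ", rate, " Hz is too low for the ",
         config$detect_band[2], " Hz band edge", call. = FALSE)
  }
  freqs <- seq(config$detect_band[1], config$detect_band[2],
               by = config$wavelet_step)
  m <- recording_matrix(rec)
  smooth_n <- max(1L, round(config$envelope_smooth * rate))
  env <- apply(m, 2L, function(x) {
    moving_average(morlet_power_matrix(x, rate, freqs, config$wavelet_cycles),
                   smooth_n)
  })
  out <- tibble::as_tibble(env)
  out <- tibble::add_column(out, time = rec$time, .before = 1L)
  attr(out, "rate") <- rate
  attr(out, "band") <- config$detect_band
  class(out) <- c("eeg_envelope", class(out))
  out
}
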