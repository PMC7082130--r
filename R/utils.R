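# Internal numeric helpers shared across modules.

# Centered moving average with shrinking windows at the edges, so that a
# constant input maps to itself exactly.
moving_average <- function(x, n) {
  n <- max(1L, as.integer(n))
  if (n == 1L || length(x) < 2L) return(x)
  cs <- cumsum(c(0, x))
  half <- (n - 1L) %/% 2L
  i <- seq_along(x)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + (n - 1L - half), length(x))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Indices of local maxima. Plateaus count once, at their first sample;
# endpoints are never maxima.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  r <- rle(x)
  k <- length(r$values)
  if (k < 3L) return(integer(0))
  starts <- cumsum(c(1L, r$lengths[-k]))
  is_max <- c(FALSE, r$values[2:(k - 1L)] > r$values[1:(k - 2L)] &
                r$values[2:(k - 1L)] > r$values[3:k], FALSE)
  starts[is_max]
}

local_minima <- function(x) local_maxima(-x)

# Zero-phase IIR filtering: forward-backward with reflection padding to
# suppress edge transients (signal::filtfilt pads with zeros).
zero_phase_filter <- function(x, filt) {
  n <- length(x)
  np <- min(n - 1L, max(3L * (length(filt$a) + length(filt$b)), 100L))
  if (np < 1L) return(as.numeric(signal::filter(filt, x)))
  pre <- 2 * x[1L] - x[(np + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - np)]
  y <- c(pre, x, post)
  y <- as.numeric(signal::filter(filt, y))
  y <- rev(as.numeric(signal::filter(filt, rev(y))))
  y[(np + 1L):(np + n)]
}

butter_bandpass <- function(band, rate, order = 4L) {
  nyq <- rate / 2
  if (band[2] >= nyq) {
    stop("band edge ", band[2], " Hz is not below the Nyquist frequency (",
         nyq, " Hz)", call. = FALSE)
  }
  signal::butter(order, band / nyq, type = "pass")
}

bandpass_filter <- function(x, band, rate, order = 4L) {
  zero_phase_filter(x, butter_bandpass(band, rate, order))
}

# Zero-phase FIR filtering for a symmetric odd-length kernel: single
# convolution with group-delay compensation and reflection padding.
fir_zero_phase <- function(x, b) {
  nb <- length(b)
  half <- (nb - 1L) %/% 2L
  n <- length(x)
  np <- min(n - 1L, nb)
  pre <- 2 * x[1L] - x[(np + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - np)]
  y <- stats::filter(c(pre, x, post, rep(0, nb)), b, method = "convolution",
                     sides = 1L)
  as.numeric(y[(np + half + 1L):(np + half + n)])
}

# Analytic signal via the frequency-domain Hilbert construction.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# One-sided Hanning-windowed power spectrum. Returns freq (Hz) and power,
# normalized as power spectral density so that band sums are comparable
# across segment lengths.
psd_hann <- function(x, rate, nfft = NULL) {
  n <- length(x)
  w <- hann_window(n)
  xw <- x * w
  if (is.null(nfft)) nfft <- n
  if (nfft > n) xw <- c(xw, numeric(nfft - n))
  X <- stats::fft(xw)
  half <- floor(nfft / 2) + 1L
  p <- (Mod(X[seq_len(half)])^2) / (rate * sum(w^2))
  scale <- rep(2, half)
  scale[1L] <- 1
  if (nfft %% 2 == 0) scale[half] <- 1
  tibble::tibble(freq = (seq_len(half) - 1L) * rate / nfft, power = p * scale)
}

hann_window <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))
}

# Sum of PSD bins whose centers fall in [low, high).
band_power <- function(spec, band) {
  sel <- spec$freq >= band[1] & spec$freq < band[2]
  sum(spec$power[sel])
}

circular_mean <- function(theta) {
  theta <- theta[is.finite(theta)]
  if (length(theta) == 0L) return(NA_real_)
  atan2(mean(sin(theta)), mean(cos(theta)))
}

check_band <- function(band, what = "band") {
  if (!is.numeric(band) || length(band) != 2L || band[1] >= band[2] ||
      band[1] < 0) {
    stop(what, " must be an increasing pair of non-negative frequencies",
         call. = FALSE)
  }
  invisible(band)
}
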