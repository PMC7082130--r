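# Recording container: a tibble with a `time` column (seconds) and one
# numeric column per channel, tagged with the sampling rate.

#' Build an EEG recording tibble
#'
#' A recording is an ordinary tibble with a `time` column in seconds and one
#' numeric column per channel, so the full dplyr/tidyr vocabulary applies.
#' The sampling rate is carried in the `"rate"` attribute; helpers such as
#' [eeg_rate()] fall back to the median `time` step when the attribute has
#' been stripped by data-frame operations.
#'
#' Time is 0-based and intervals throughout the package are half-open
#' `[start, end)`. Values are treated as millivolts by default; nothing in
#' the detection pipeline depends on the unit as long as it is consistent.
#'
#' @param data A numeric matrix or data frame, samples in rows and one
#'   column per channel.
#' @param rate Sampling rate in samples per second.
#' @param labels Channel names. Defaults to the column names of `data`, or
#'   `ch1`, `ch2`, ... when absent.
#' @param start_time Time of the first sample in seconds.
#' @return A tibble of class `eeg_recording` with columns `time` and one per
#'   channel.
#' @examples
#' rec <- as_recording(matrix(rnorm(500 * 2), ncol = 2), rate = 250)
#' eeg_rate(rec)
#' channel_names(rec)
#' @export
as_recording <- function(data, rate, labels = NULL, start_time = 0) {
  if (is.data.frame(data)) data <- as.matrix(data)
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("`data` must be a numeric matrix or data frame", call. = FALSE)
  }
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("`rate` must be a single positive number", call. = FALSE)
  }
  labels <- labels %||% colnames(data) %||%
    paste0("ch", seq_len(ncol(data)))
  if (anyDuplicated(labels)) stop("channel labels must be unique", call. = FALSE)
  if (length(labels) != ncol(data)) {
    stop("`labels` length must match the number of channels", call. = FALSE)
  }
  colnames(data) <- labels
  out <- tibble::as_tibble(data)
  out <- tibble::add_column(
    out, time = start_time + (seq_len(nrow(data)) - 1L) / rate, .before = 1L)
  attr(out, "rate") <- rate
  class(out) <- c("eeg_recording", class(out))
  out
}

#' Sampling rate of a recording
#'
#' Reads the `"rate"` attribute, falling back to the reciprocal median time
#' step when the attribute has been dropped.
#'
#' @param rec A recording tibble (see [as_recording()]).
#' @return Sampling rate in samples per second.
#' @export
eeg_rate <- function(rec) {
  r <- attr(rec, "rate")
  if (!is.null(r)) return(r)
  if (!"time" %in% names(rec) || nrow(rec) < 2L) {
    stop("cannot infer sampling rate: no `rate` attribute and no usable ",
         "`time` column", call. = FALSE)
  }
  1 / stats::median(diff(rec$time))
}

#' @rdname eeg_rate
#' @export
channel_names <- function(rec) setdiff(names(rec), "time")

#' @rdname eeg_rate
#' @export
recording_matrix <- function(rec) {
  as.matrix(rec[channel_names(rec)])
}

#' @export
print.eeg_recording <- function(x, ...) {
  nch <- length(channel_names(x))
  cat(sprintf("# EEG recording: %d channel%s x %d samples at %g Hz (%.1f s)\n",
              nch, if (nch == 1L) "" else "s", nrow(x), eeg_rate(x),
              nrow(x) / eeg_rate(x)))
  NextMethod()
}

#' Common average reference
#'
#' Subtracts the instantaneous mean across channels from every channel, so
#' the per-sample channel mean of the output is zero.
#'
#' @param rec A recording with at least two channels.
#' @return A recording of the same shape.
#' @examples
#' rec <- as_recording(cbind(a = c(1, 1, 1), b = c(3, 3, 3)), rate = 1)
#' rereference_car(rec)
#' @export
rereference_car <- function(rec) {
  chans <- channel_names(rec)
  if (length(chans) < 2L) {
    stop("common average reference needs at least two channels", call. = FALSE)
  }
  m <- recording_matrix(rec)
  m <- m - rowMeans(m)
  as_recording(m, rate = eeg_rate(rec), labels = chans,
               start_time = rec$time[1L])
}

#' Downsample a recording with anti-alias filtering
#'
#' Applies a zero-phase FIR low-pass (Hamming-window design, cut-off at 90%
#' of the target Nyquist frequency) before decimating. Integer rate ratios
#' are decimated by sample picking; non-integer ratios are linearly
#' interpolated onto the new time grid after filtering. Duration is
#' preserved to within one output sample.
#'
#' @param rec A recording.
#' @param target_rate New sampling rate; must not exceed the current rate.
#' @return A recording at `target_rate`.
#' @examples
#' rec <- as_recording(matrix(sin(2 * pi * 10 * (0:999) / 1000)), rate = 1000)
#' down <- downsample_recording(rec, 250)
#' eeg_rate(down)
#' @export
downsample_recording <- function(rec, target_rate) {
  rate <- eeg_rate(rec)
  if (!is.numeric(target_rate) || length(target_rate) != 1L ||
      target_rate <= 0) {
    stop("`target_rate` must be a single positive number", call. = FALSE)
  }
  if (target_rate > rate + 1e-9) {
    stop("`target_rate` (", target_rate, ") exceeds the recording rate (",
         rate, ")", call. = FALSE)
  }
  if (abs(target_rate - rate) < 1e-9) return(rec)

  ratio <- rate / target_rate
  ord <- max(32L, 2L * ceiling(8 * ratio))
  b <- signal::fir1(ord, 0.9 * target_rate / rate)
  b <- b / sum(b)  # exact unity DC gain
  m <- recording_matrix(rec)
  filt <- apply(m, 2L, fir_zero_phase, b = b)

  t0 <- rec$time[1L]
  if (abs(ratio - round(ratio)) < 1e-9) {
    idx <- seq(1L, nrow(m), by = round(ratio))
    out <- filt[idx, , drop = FALSE]
  } else {
    dur <- (nrow(m) - 1L) / rate
    new_t <- seq(0, dur, by = 1 / target_rate)
    old_t <- (seq_len(nrow(m)) - 1L) / rate
    out <- apply(filt, 2L, function(x) {
      stats::approx(old_t, x, xout = new_t, rule = 2)$y
    })
  }
  as_recording(out, rate = target_rate, labels = channel_names(rec),
               start_time = t0)
}

#' Extract a time slice of a recording
#'
#' @param rec A recording.
#' @param start,end Half-open interval `[start, end)` in seconds (absolute,
#'   i.e. on the recording's `time` axis).
#' @return A recording covering the requested interval.
#' @export
slice_recording <- function(rec, start, end) {
  sel <- rec$time >= start & rec$time < end
  if (!any(sel)) stop("interval [", start, ", ", end, ") is empty", call. = FALSE)
  out <- rec[sel, ]
  attr(out, "rate") <- eeg_rate(rec)
  class(out) <- unique(c("eeg_recording", class(out)))
  out
}
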