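# Spindle detection: thresholding, candidate runs, prominence-based
# boundary refinement, spectral features, and the acceptance filters.

#' Per-channel detection thresholds from a baseline envelope
#'
#' The detection threshold is `threshold_factor` (180% by default) times
#' the mean band-power envelope of the designated baseline recording,
#' computed separately for each channel.
#'
#' @param envelope A band power envelope (see [band_power_envelope()]) of
#'   the baseline recording.
#' @param config A [detection_config()].
#' @return A tibble with columns `channel`, `mean_power`, `threshold`.
#' @export
baseline_threshold <- function(envelope, config = detection_config()) {
  chans <- setdiff(names(envelope), "time")
  if (nrow(envelope) == 0L) stop("empty envelope", call. = FALSE)
  mp <- vapply(chans, function(ch) mean(envelope[[ch]]), numeric(1))
  tibble::tibble(channel = chans, mean_power = unname(mp),
                 threshold = config$threshold_factor * unname(mp))
}

#' Threshold crossings as candidate spindle intervals
#'
#' Maximal runs of consecutive samples whose envelope exceeds the channel
#' threshold, one candidate per run.
#'
#' @param envelope A band power envelope.
#' @param thresholds Output of [baseline_threshold()].
#' @return A tibble with columns `channel`, `start`, `end` (seconds,
#'   half-open) and `start_idx`, `end_idx` (1-based inclusive samples).
#' @export
detect_candidates <- function(envelope, thresholds) {
  rate <- attr(envelope, "rate") %||% (1 / stats::median(diff(envelope$time)))
  t0 <- envelope$time[1L]
  chans <- setdiff(names(envelope), "time")
  out <- lapply(chans, function(ch) {
    thr <- thresholds$threshold[match(ch, thresholds$channel)]
    if (is.na(thr)) stop("no threshold for channel ", ch, call. = FALSE)
    above <- envelope[[ch]] > thr
    if (!any(above)) return(NULL)
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    tibble::tibble(channel = ch, start_idx = starts[keep],
                   end_idx = ends[keep])
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0L) {
    return(tibble::tibble(channel = character(0), start = numeric(0),
                          end = numeric(0), start_idx = integer(0),
                          end_idx = integer(0)))
  }
  out$start <- t0 + (out$start_idx - 1L) / rate
  out$end <- t0 + out$end_idx / rate
  out[, c("channel", "start", "end", "start_idx", "end_idx")]
}

# Boundary cutoff level for one peak under the configured rule.
boundary_cutoff <- function(peak_value, prominence, channel_mean, config) {
  prom_level <- switch(config$boundary_rule,
    prominence_fraction = config$boundary_prominence_frac * prominence,
    prominence_drop = peak_value - config$boundary_prominence_frac * prominence)
  max(prom_level, config$boundary_mean_frac * channel_mean)
}

#' Refine candidate boundaries around the envelope peak
#'
#' For each candidate the envelope peak inside the run is located and its
#' prominence computed as the height above the higher of the two minima
#' between this peak and the neighboring candidates' peaks (bounded by a
#' search window of twice the maximum spindle duration). The start and end
#' are then the first samples walking outward from the peak at which the
#' envelope falls below the boundary cutoff (see [detection_config()] for
#' the two cutoff readings). Boundaries never cross a neighboring
#' candidate's peak, so adjacent spindles are split rather than merged.
#'
#' @param envelope A band power envelope.
#' @param candidates Output of [detect_candidates()].
#' @param channel_means Tibble with `channel`, `mean_power` (typically the
#'   [baseline_threshold()] output).
#' @param config A [detection_config()].
#' @return The candidates tibble with refined `start`, `end`,
#'   `start_idx`, `end_idx`, plus `peak_idx` and `flat` (zero-prominence
#'   flag; such candidates are returned unrefined).
#' @export
refine_boundaries <- function(envelope, candidates, channel_means,
                              config = detection_config()) {
  rate <- attr(envelope, "rate") %||% (1 / stats::median(diff(envelope$time)))
  t0 <- envelope$time[1L]
  n <- nrow(envelope)
  win <- as.integer(round(2 * config$max_dur * rate))
  out <- lapply(split(candidates, candidates$channel), function(cand) {
    ch <- cand$channel[1L]
    env <- envelope[[ch]]
    ch_mean <- channel_means$mean_power[match(ch, channel_means$channel)]
    cand <- cand[order(cand$start_idx), ]
    peaks <- vapply(seq_len(nrow(cand)), function(i) {
      seg <- env[cand$start_idx[i]:cand$end_idx[i]]
      cand$start_idx[i] + which.max(seg) - 1L
    }, integer(1))
    res <- cand
    res$peak_idx <- peaks
    res$flat <- FALSE
    for (i in seq_len(nrow(cand))) {
      p <- peaks[i]
      lo <- max(1L, p - win, if (i > 1L) peaks[i - 1L] + 1L else 1L)
      hi <- min(n, p + win, if (i < nrow(cand)) peaks[i + 1L] - 1L else n)
      left_min <- min(env[lo:p])
      right_min <- min(env[p:hi])
      prom <- env[p] - max(left_min, right_min)
      if (prom <= 0) {
        res$flat[i] <- TRUE
        next
      }
      cutoff <- boundary_cutoff(env[p], prom, ch_mean, config)
      left <- env[lo:p]
      below <- which(left < cutoff)
      s_idx <- if (length(below) > 0L) lo + max(below) else lo
      right <- env[p:hi]
      below <- which(right < cutoff)
      e_idx <- if (length(below) > 0L) p + min(below) - 2L else hi
      res$start_idx[i] <- s_idx
      res$end_idx[i] <- e_idx
    }
    res
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0L) {
    return(tibble::add_column(candidates, peak_idx = integer(0),
                              flat = logical(0)))
  }
  out$start <- t0 + (out$start_idx - 1L) / rate
  out$end <- t0 + out$end_idx / rate
  dplyr::arrange(out, .data$channel, .data$start_idx)
}

# Merge overlapping refined intervals on the same channel (can arise when
# two candidate runs refine into touching spans).
merge_overlaps <- function(refined) {
  merged_any <- FALSE
  out <- lapply(split(refined, refined$channel), function(d) {
    d <- d[order(d$start_idx), ]
    keep <- rep(TRUE, nrow(d))
    i <- 1L
    for (j in seq_len(nrow(d))[-1L]) {
      if (d$start_idx[j] <= d$end_idx[i]) {
        d$end_idx[i] <- max(d$end_idx[i], d$end_idx[j])
        d$end[i] <- max(d$end[i], d$end[j])
        if (d[[which(names(d) == "peak_idx")]][j] > 0) {
          merged_any <<- TRUE
        }
        keep[j] <- FALSE
      } else {
        i <- j
      }
    }
    d[keep, ]
  })
  if (merged_any) {
    warning("overlapping refined intervals on the same channel were merged",
            call. = FALSE)
  }
  dplyr::bind_rows(out)
}

#' Spindle spectral features
#'
#' Hanning-windowed power spectrum of the segment, zero padded to
#' `fft_bins` frequency bins (or the next power of two above the segment
#' length for unusually long candidates), giving a frequency resolution of
#' `rate / fft_bins`. The peak frequency is the maximum-power bin within
#' the detection band; ties resolve to the lowest frequency.
#'
#' Within [detect_spindles()] the segment is taken from a zero-phase
#' high-pass of the channel at the detection-band low edge: sub-second
#' segments cannot spectrally resolve the slow oscillation, whose power
#' would otherwise leak through the window mainlobe across the whole
#' search band and displace the spindle's own peak.
#'
#' @param x Signal segment (numeric vector, at least 2 samples).
#' @param rate Sampling rate in Hz.
#' @param config A [detection_config()].
#' @return A list with `peak_freq`, `peak_power` and the `spectrum` tibble
#'   (`freq`, `power`).
#' @export
spindle_spectrum <- function(x, rate, config = detection_config()) {
  if (length(x) < 2L) stop("segment must contain at least 2 samples",
                           call. = FALSE)
  nfft <- config$fft_bins
  if (length(x) > nfft) nfft <- 2L^ceiling(log2(length(x)))
  spec <- psd_hann(x, rate, nfft = nfft)
  sel <- which(spec$freq >= config$detect_band[1] &
                 spec$freq <= config$detect_band[2])
  if (length(sel) == 0L) {
    return(list(peak_freq = NA_real_, peak_power = NA_real_, spectrum = spec))
  }
  best <- sel[which.max(spec$power[sel])]
  list(peak_freq = spec$freq[best], peak_power = spec$power[best],
       spectrum = spec)
}

#' Noise-spike test
#'
#' A segment is a noise spike when its largest absolute sample-to-sample
#' voltage step exceeds `spike_factor` (10 by default) times the mean
#' absolute step within the segment. A constant segment is never a spike.
#'
#' @param x Raw signal segment (at least 3 samples).
#' @param spike_factor Rejection factor.
#' @return `TRUE` if the segment contains a noise spike.
#' @examples
#' is_noise_spike(sin(seq(0, 6, by = 0.01)))
#' @export
is_noise_spike <- function(x, spike_factor = 10) {
  if (length(x) < 3L) return(FALSE)
  d <- abs(diff(x))
  max(d) > spike_factor * mean(d)
}

#' Count positive peaks in a band-pass filtered segment
#'
#' Local maxima with positive value in the zero-phase 4th-order
#' Butterworth band-pass (classical 10-16 Hz band by default) of the
#' segment. Used as the spindle shape filter: accepted spindles need at
#' least `min_pos_peaks` of them.
#'
#' @param x Signal segment, either raw (then `band` and `rate` are used to
#'   filter) or already filtered (set `band = NULL`).
#' @param rate Sampling rate in Hz.
#' @param band Band-pass edges in Hz, or `NULL` if `x` is pre-filtered.
#' @return Integer count of positive local maxima.
#' @export
count_positive_peaks <- function(x, rate = NULL, band = c(10, 16)) {
  if (!is.null(band)) {
    if (is.null(rate)) stop("`rate` is required when filtering", call. = FALSE)
    x <- bandpass_filter(x, band, rate)
  }
  idx <- local_maxima(x)
  sum(x[idx] > 0)
}

#' Detect sleep spindles
#'
#' The full detection pipeline: wavelet band-power envelope, per-channel
#' threshold from the baseline recording, threshold-crossing candidates,
#' prominence-based boundary refinement, Hanning/1024-bin spectral
#' features, and the acceptance filters (duration within 0.3-3 s, peak
#' frequency inside the detection band, no noise spike, at least three
#' positive peaks in the classical-band filtered trace). Rejected events
#' are retained with their rejection reasons.
#'
#' @param rec The recording to analyze.
#' @param baseline The designated baseline recording from which thresholds
#'   and channel mean powers are computed (the "night 2" role). When
#'   `NULL`, `rec` itself is used, with a warning.
#' @param config A [detection_config()].
#' @return A tibble of class `spindle_events` with one row per detected
#'   event: `channel`, `start`, `end`, `duration`, `peak_freq`,
#'   `peak_power`, `mean_power`, `n_pos_peaks`, `accepted`,
#'   `reject_reason`, `flat_boundary`. The configuration and sampling rate
#'   travel in attributes.
#' @examples
#' study <- generate_study(sim_config(
#'   n_channels = 4,
#'   stage_sequence = data.frame(stage = "S2", duration = 60), seed = 3))
#' ev <- detect_spindles(study$recording)
#' dplyr::count(ev, accepted)
#' @export
detect_spindles <- function(rec, baseline = NULL,
                            config = detection_config()) {
  rate <- eeg_rate(rec)
  env <- band_power_envelope(rec, config)
  if (is.null(baseline)) {
    warning("no baseline recording supplied; using the analysis recording ",
            "itself as its own baseline", call. = FALSE)
    thr <- baseline_threshold(env, config)
  } else {
    if (!identical(sort(channel_names(baseline)), sort(channel_names(rec)))) {
      stop("baseline and recording channel sets differ", call. = FALSE)
    }
    if (abs(eeg_rate(baseline) - rate) > 1e-9) {
      stop("baseline and recording sampling rates differ", call. = FALSE)
    }
    thr <- baseline_threshold(band_power_envelope(baseline, config), config)
  }
  cand <- detect_candidates(env, thr)
  empty <- tibble::tibble(
    channel = character(0), start = numeric(0), end = numeric(0),
    duration = numeric(0), peak_freq = numeric(0), peak_power = numeric(0),
    mean_power = numeric(0), n_pos_peaks = integer(0), accepted = logical(0),
    reject_reason = character(0), flat_boundary = logical(0))
  if (nrow(cand) == 0L) {
    return(new_spindle_events(empty, config, rate))
  }
  ref <- refine_boundaries(env, cand, thr, config)
  ref <- merge_overlaps(ref)

  m <- recording_matrix(rec)
  filt <- apply(m, 2L, bandpass_filter, band = config$classical_band,
                rate = rate)
  colnames(filt) <- colnames(m)
  hp_filt <- signal::butter(4, config$detect_band[1] / (rate / 2),
                            type = "high")
  hp <- apply(m, 2L, zero_phase_filter, filt = hp_filt)
  colnames(hp) <- colnames(m)

  rows <- lapply(seq_len(nrow(ref)), function(i) {
    ch <- ref$channel[i]
    idx <- ref$start_idx[i]:ref$end_idx[i]
    seg <- m[idx, ch]
    spec <- if (length(seg) >= 2L) {
      spindle_spectrum(hp[idx, ch], rate, config)
    } else {
      list(peak_freq = NA_real_, peak_power = NA_real_)
    }
    tibble::tibble(
      channel = ch, start = ref$start[i], end = ref$end[i],
      duration = ref$end[i] - ref$start[i],
      peak_freq = spec$peak_freq, peak_power = spec$peak_power,
      mean_power = mean(env[[ch]][idx]),
      n_pos_peaks = count_positive_peaks(filt[idx, ch], band = NULL),
      spike = is_noise_spike(seg, config$spike_factor),
      flat_boundary = ref$flat[i])
  })
  ev <- dplyr::bind_rows(rows)

  reasons <- cbind(
    duration = ev$duration < config$min_dur | ev$duration > config$max_dur,
    peak_freq = is.na(ev$peak_freq) |
      ev$peak_freq < config$detect_band[1] |
      ev$peak_freq > config$detect_band[2],
    noise_spike = ev$spike,
    pos_peaks = ev$n_pos_peaks < config$min_pos_peaks)
  ev$accepted <- rowSums(reasons) == 0L
  ev$reject_reason <- apply(reasons, 1L, function(r) {
    paste(colnames(reasons)[r], collapse = ";")
  })
  ev$spike <- NULL
  ev <- dplyr::arrange(ev, .data$start, .data$channel)
  new_spindle_events(ev[, names(empty)], config, rate)
}

new_spindle_events <- function(ev, config, rate) {
  attr(ev, "config") <- config
  attr(ev, "rate") <- rate
  class(ev) <- unique(c("spindle_events", class(ev)))
  ev
}

#' Accepted spindles in the classical band
#'
#' Filters accepted events to peak frequencies within the classical
#' spindle band (10-16 Hz by default), the view used for all downstream
#' characterization.
#'
#' @param events A `spindle_events` tibble.
#' @param band Classical band in Hz; defaults to the detection
#'   configuration the events were produced with.
#' @return The filtered events tibble.
#' @export
classical_spindles <- function(events, band = NULL) {
  band <- band %||% attr(events, "config")$classical_band %||% c(10, 16)
  out <- events[events$accepted & !is.na(events$peak_freq) &
                  events$peak_freq >= band[1] & events$peak_freq <= band[2], ]
  attributes(out)[c("config", "rate")] <- attributes(events)[c("config", "rate")]
  class(out) <- unique(c("spindle_events", class(out)))
  out
}

#' Read or write a spindle event table
#'
#' CSV columns: `channel,start_s,end_s,duration_s,peak_freq_hz,peak_power,
#' mean_power,n_pos_peaks,accepted,reject_reason`.
#'
#' @param events A `spindle_events` tibble.
#' @param path File path.
#' @return [read_events()] returns a `spindle_events` tibble;
#'   [write_events()] returns `path` invisibly.
#' @export
write_events <- function(events, path) {
  out <- tibble::tibble(
    channel = events$channel, start_s = events$start, end_s = events$end,
    duration_s = events$duration, peak_freq_hz = events$peak_freq,
    peak_power = events$peak_power, mean_power = events$mean_power,
    n_pos_peaks = events$n_pos_peaks,
    accepted = as.integer(events$accepted),
    reject_reason = events$reject_reason)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  tab <- readr::read_csv(path, col_types = readr::cols(
    channel = readr::col_character(),
    reject_reason = readr::col_character(),
    .default = readr::col_double()), progress = FALSE)
  ev <- tibble::tibble(
    channel = tab$channel, start = tab$start_s, end = tab$end_s,
    duration = tab$duration_s, peak_freq = tab$peak_freq_hz,
    peak_power = tab$peak_power, mean_power = tab$mean_power,
    n_pos_peaks = as.integer(tab$n_pos_peaks),
    accepted = tab$accepted != 0,
    reject_reason = dplyr::coalesce(tab$reject_reason, ""),
    flat_boundary = FALSE)
  new_spindle_events(ev, NULL, NA_real_)
}
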