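# Synthetic polysomnography generator: 1/f background with stage-dependent
# slow-wave activity, injected waxing-waning spindle bursts with a
# ground-truth event table, low-voltage fast wake activity, and occasional
# voltage spikes.

#' Stage timeline of a simulation configuration
#'
#' @param config An [sim_config()] object.
#' @return A tibble with columns `stage`, `start`, `end` (seconds,
#'   half-open).
#' @export
stage_timeline <- function(config) {
  ends <- cumsum(config$stage_sequence$duration)
  tibble::tibble(stage = config$stage_sequence$stage,
                 start = c(0, utils::head(ends, -1L)), end = ends)
}

#' Colored (1/f^alpha) noise
#'
#' Spectrally shaped Gaussian noise, normalized to unit variance; the
#' default exponent gives the pink (1/f) background characteristic of
#' cortical EEG.
#'
#' @param n Number of samples.
#' @param alpha Spectral exponent (power ~ 1/f^alpha).
#' @return A numeric vector of length `n`.
#' @export
colored_noise <- function(n, alpha = 1) {
  w <- stats::fft(stats::rnorm(n))
  idx <- c(0, pmin(seq_len(n - 1L), n - seq_len(n - 1L)))
  s <- c(0, idx[-1L]^(-alpha / 2))
  x <- Re(stats::fft(w * s, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Cosine-tapered gate over [start, end) with `ramp`-second edges, evaluated
# on the whole sample grid.
segment_gate <- function(time, start, end, ramp = 1) {
  g <- numeric(length(time))
  inside <- time >= start & time < end
  g[inside] <- 1
  if (ramp > 0) {
    up <- inside & time < start + ramp
    g[up] <- 0.5 - 0.5 * cos(pi * (time[up] - start) / ramp)
    down <- inside & time >= end - ramp
    g[down] <- 0.5 - 0.5 * cos(pi * (end - time[down]) / ramp)
  }
  g
}

#' Generate the stage-dependent background EEG
#'
#' Produces per-channel pink (1/f) noise; NREM segments additionally carry
#' band-limited 0.5-2 Hz slow-wave activity (higher amplitude in deep than
#' in light NREM, which is what the delta-power substaging recovers), wake
#' segments carry extra low-voltage fast (20-45 Hz) activity emulating
#' desynchronized wake EEG, and single-sample
#' voltage spikes of 20 standard deviations are sprinkled at
#' `config$spike_rate` per minute. The realization is fully determined by
#' `config$seed`.
#'
#' @param config An [sim_config()] object.
#' @return A recording tibble; the spike table is attached as the
#'   `"spikes"` attribute (columns `channel`, `time`).
#' @export
generate_background <- function(config) {
  timeline <- stage_timeline(config)
  total <- max(timeline$end)
  n <- round(total * config$rate)
  if (n < 2L) stop("stage sequence has (near) zero total duration",
                   call. = FALSE)
  withr::with_seed(config$seed, {
    time <- (seq_len(n) - 1L) / config$rate
    m <- matrix(0, n, config$n_channels)
    for (ch in seq_len(config$n_channels)) {
      m[, ch] <- config$bg_sd * colored_noise(n)
    }
    for (k in seq_len(nrow(timeline))) {
      st <- timeline$stage[k]
      gate <- NULL
      if (st %in% stages_nrem()) {
        amp <- if (st %in% c("S2", "U2")) config$sw_bg_amp[["deep"]] else
          config$sw_bg_amp[["light"]]
        gate <- segment_gate(time, timeline$start[k], timeline$end[k])
        for (ch in seq_len(config$n_channels)) {
          sw <- bandpass_filter(stats::rnorm(n), c(0.5, 2), config$rate)
          sw <- sw / stats::sd(sw) * amp / sqrt(2)
          m[, ch] <- m[, ch] + gate * sw
        }
      } else if (st %in% stages_wake()) {
        gate <- segment_gate(time, timeline$start[k], timeline$end[k])
        hi_edge <- min(45, config$rate / 2 * 0.9)
        att <- config$wake_attenuation
        for (ch in seq_len(config$n_channels)) {
          m[, ch] <- m[, ch] * (1 - (1 - att) * gate)
          if (config$wake_broadband_sd > 0) {
            fast <- bandpass_filter(stats::rnorm(n), c(20, hi_edge),
                                    config$rate)
            m[, ch] <- m[, ch] +
              gate * fast / stats::sd(fast) * config$wake_broadband_sd
          }
        }
      }
    }
    n_spikes <- stats::rpois(1L, config$spike_rate * total / 60)
    spikes <- tibble::tibble(channel = character(0), time = numeric(0))
    if (n_spikes > 0L) {
      idx <- sample.int(n - 2L * config$rate, n_spikes) + config$rate
      ch <- sample.int(config$n_channels, n_spikes, replace = TRUE)
      sign <- sample(c(-1, 1), n_spikes, replace = TRUE)
      for (j in seq_len(n_spikes)) {
        m[idx[j], ch[j]] <- m[idx[j], ch[j]] +
          sign[j] * 20 * stats::sd(m[, ch[j]])
      }
      spikes <- tibble::tibble(channel = config$labels[ch],
                               time = (idx - 1L) / config$rate)
    }
    rec <- as_recording(m, rate = config$rate, labels = config$labels)
    attr(rec, "spikes") <- spikes
    rec
  })
}

# Mean analytic-envelope amplitude of the classical-band background, per
# channel; the reference against which spindle SNR is defined.
background_envelope_reference <- function(rec, band = c(10, 16)) {
  m <- recording_matrix(rec)
  rate <- eeg_rate(rec)
  vapply(seq_len(ncol(m)), function(ch) {
    mean(Mod(analytic_signal(bandpass_filter(m[, ch], band, rate))))
  }, numeric(1))
}

#' Draw a ground-truth spindle event table
#'
#' Event counts per stage segment are Poisson with the configured per-stage
#' rates; onsets are uniform within the segment (1 s margins), frequencies
#' and durations uniform over their configured ranges. A
#' `config$global_fraction` share of events is placed on >= 4 channels
#' (when the montage allows) and coupled to an injected slow wave whose
#' positive peak is centered on the spindle. Spindle amplitudes are
#' `config$amplitude_snr` times the mean classical-band envelope of the
#' background on the event's channels. Events overlapping an earlier event
#' on a shared channel are dropped. Seeded with `config$seed + 1`, so the
#' table is reproducible independently of the background realization's
#' internal draws.
#'
#' @param config An [sim_config()] object.
#' @param background The background recording (for SNR referencing).
#' @return A tibble with columns `event`, `channels`
#'   (semicolon-separated labels), `n_channels`, `start`, `duration`,
#'   `freq`, `amplitude`, `sw_amp`, `sw_freq`.
#' @export
draw_ground_truth <- function(config, background) {
  timeline <- stage_timeline(config)
  ref <- background_envelope_reference(background)
  names(ref) <- config$labels
  withr::with_seed(config$seed + 1L, {
    rows <- list()
    for (k in seq_len(nrow(timeline))) {
      rate_min <- config$spindle_rate[[timeline$stage[k]]] %||% 0
      if (is.na(rate_min) || rate_min <= 0) next
      seg_len <- timeline$end[k] - timeline$start[k]
      n_ev <- stats::rpois(1L, rate_min * seg_len / 60)
      if (n_ev == 0L) next
      dur <- stats::runif(n_ev, config$duration_range[1],
                          config$duration_range[2])
      margin <- 1
      lo <- timeline$start[k] + margin
      hi <- pmax(lo, timeline$end[k] - margin - dur)
      start <- lo + (hi - lo) * stats::runif(n_ev)
      freq <- stats::runif(n_ev, config$freq_range[1], config$freq_range[2])
      glob <- stats::runif(n_ev) < config$global_fraction &
        config$n_channels >= 4L
      chans <- lapply(seq_len(n_ev), function(j) {
        if (glob[j]) {
          k_ch <- sample(4:config$n_channels, 1L)
          sort(sample(config$labels, k_ch))
        } else {
          sample(config$labels, 1L)
        }
      })
      sw_amp <- ifelse(glob, stats::runif(n_ev, config$sw_amplitude_range[1],
                                          config$sw_amplitude_range[2]), 0)
      sw_freq <- ifelse(glob, stats::runif(n_ev, 0.8, 1.2), 0)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        channels = vapply(chans, paste, "", collapse = ";"),
        n_channels = lengths(chans), start = start, duration = dur,
        freq = freq,
        amplitude = config$amplitude_snr *
          vapply(chans, function(cc) mean(ref[cc]), numeric(1)),
        sw_amp = sw_amp, sw_freq = sw_freq)
    }
    if (length(rows) == 0L) {
      return(tibble::tibble(event = integer(0), channels = character(0),
                            n_channels = integer(0), start = numeric(0),
                            duration = numeric(0), freq = numeric(0),
                            amplitude = numeric(0), sw_amp = numeric(0),
                            sw_freq = numeric(0)))
    }
    truth <- dplyr::arrange(dplyr::bind_rows(rows), .data$start)
    keep <- rep(TRUE, nrow(truth))
    ch_list <- strsplit(truth$channels, ";", fixed = TRUE)
    last_end <- stats::setNames(rep(-Inf, length(config$labels)),
                                config$labels)
    for (i in seq_len(nrow(truth))) {
      cc <- ch_list[[i]]
      if (any(truth$start[i] < last_end[cc] + 0.25)) {
        keep[i] <- FALSE
      } else {
        last_end[cc] <- truth$start[i] + truth$duration[i]
      }
    }
    truth <- truth[keep, ]
    tibble::add_column(truth, event = seq_len(nrow(truth)), .before = 1L)
  })
}

#' Inject ground-truth events into a recording
#'
#' Adds, for every event, a sinusoid at the event frequency under a Hann
#' (waxing-waning) envelope of the stated duration to all listed channels,
#' plus - when `sw_amp > 0` - a two-cycle Hann-windowed slow wave whose
#' positive peak coincides with the spindle center. Purely deterministic:
#' the same truth table always produces the same waveforms, and the
#' injected energy is exactly additive on top of the input recording.
#'
#' @param rec The background recording.
#' @param truth A ground-truth table as from [draw_ground_truth()].
#' @param config The [sim_config()] used (for channel labels).
#' @return The recording with events added; events truncated at the
#'   recording end are flagged in the returned `"truncated"` attribute.
#' @export
inject_events <- function(rec, truth, config = NULL) {
  m <- recording_matrix(rec)
  rate <- eeg_rate(rec)
  n <- nrow(m)
  truncated <- logical(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    cc <- strsplit(truth$channels[i], ";", fixed = TRUE)[[1L]]
    i0 <- round(truth$start[i] * rate) + 1L
    len <- max(2L, round(truth$duration[i] * rate))
    i1 <- i0 + len - 1L
    if (i1 > n) {
      truncated[i] <- TRUE
      i1 <- n
      len <- i1 - i0 + 1L
      if (len < 2L) next
    }
    t_rel <- (seq_len(len) - 1L) / rate
    wave <- truth$amplitude[i] * sin(2 * pi * truth$freq[i] * t_rel) *
      hann_window(len)
    m[i0:i1, cc] <- m[i0:i1, cc] + wave
    if (truth$sw_amp[i] > 0 && truth$sw_freq[i] > 0) {
      center <- truth$start[i] + truth$duration[i] / 2
      half <- 1 / truth$sw_freq[i]
      j0 <- max(1L, round((center - half) * rate) + 1L)
      j1 <- min(n, round((center + half) * rate) + 1L)
      t_sw <- (seq(j0, j1) - 1L) / rate
      sw <- truth$sw_amp[i] * cos(2 * pi * truth$sw_freq[i] * (t_sw - center)) *
        hann_window(j1 - j0 + 1L)
      m[j0:j1, cc] <- m[j0:j1, cc] + sw
    }
  }
  out <- as_recording(m, rate = rate, labels = channel_names(rec),
                      start_time = rec$time[1L])
  attr(out, "spikes") <- attr(rec, "spikes")
  attr(out, "truncated") <- truth$event[truncated]
  out
}

#' Generate a complete synthetic study
#'
#' Bundles [generate_background()], [draw_ground_truth()] and
#' [inject_events()] with a stage-accurate 10 s-epoch hypnogram. Epochs are
#' labelled by the stage at their midpoint; epochs containing an injected
#' voltage spike are flagged as artifacts.
#'
#' @param config An [sim_config()] object.
#' @param epoch_len Hypnogram epoch length in seconds.
#' @return A list of class `eeg_study` with elements `recording`,
#'   `hypnogram`, `truth`, `background` and `spikes`.
#' @examples
#' study <- generate_study(sim_config(
#'   n_channels = 4,
#'   stage_sequence = data.frame(stage = c("W", "S2"), duration = c(40, 120)),
#'   seed = 7))
#' nrow(study$truth)
#' @export
generate_study <- function(config, epoch_len = 10) {
  background <- generate_background(config)
  truth <- draw_ground_truth(config, background)
  rec <- inject_events(background, truth, config)
  total <- nrow(background) / config$rate
  n_ep <- floor(total / epoch_len)
  timeline <- stage_timeline(config)
  mid <- (seq_len(n_ep) - 0.5) * epoch_len
  stage <- timeline$stage[findInterval(mid, timeline$start)]
  spikes <- attr(background, "spikes")
  artifact <- rep(FALSE, n_ep)
  if (nrow(spikes) > 0L) {
    ep <- floor(spikes$time / epoch_len) + 1L
    artifact[ep[ep <= n_ep]] <- TRUE
  }
  structure(list(recording = rec,
                 hypnogram = as_hypnogram(stage, artifact, epoch_len),
                 truth = truth, background = background, spikes = spikes),
            class = "eeg_study")
}

#' @export
print.eeg_study <- function(x, ...) {
  cat(sprintf(paste0("# Synthetic EEG study: %d channels, %.1f min, ",
                     "%d ground-truth spindles (%d global)\n"),
              length(channel_names(x$recording)),
              nrow(x$recording) / eeg_rate(x$recording) / 60,
              nrow(x$truth), sum(x$truth$n_channels >= 4)))
  invisible(x)
}

#' Write the ground-truth table of a study
#'
#' Columns `channels;start;duration;freq;amplitude;sw_amp`, semicolon
#' separated to keep the channel list readable.
#'
#' @param truth A ground-truth tibble.
#' @param path Output path.
#' @export
write_truth <- function(truth, path) {
  out <- truth[, c("channels", "start", "duration", "freq", "amplitude",
                   "sw_amp")]
  readr::write_delim(out, path, delim = ";", progress = FALSE)
  invisible(path)
}
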