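# Configuration objects for detection and simulation.

#' Spindle detection configuration
#'
#' Bundles the detector's tunable parameters. The defaults reproduce the
#' published ovine pipeline: wavelet power envelope over 5-16 Hz, detection
#' threshold at 180% of the baseline mean band power, boundary refinement
#' against 80% of the envelope peak's prominence or 120% of the channel
#' mean power (whichever is crossed first walking outward from the peak),
#' a 0.3-3 s duration filter, Hanning-windowed 1024-bin FFT features, a
#' 10x voltage-step noise-spike rejection, and a minimum of three positive
#' peaks in the 10-16 Hz filtered trace.
#'
#' @param detect_band Detection band in Hz (envelope, threshold and
#'   peak-frequency gate).
#' @param classical_band Classical spindle band in Hz; used for the
#'   positive-peak shape filter and the classical event view.
#' @param threshold_factor Detection threshold as a multiple of the
#'   per-channel baseline mean envelope power.
#' @param boundary_prominence_frac Fraction of the envelope peak prominence
#'   used by the boundary rule.
#' @param boundary_mean_frac Multiple of the channel mean envelope power
#'   used as the floor of the boundary cutoff.
#' @param boundary_rule `"prominence_drop"` places the boundary cutoff at
#'   `peak - frac * prominence` (the power has dropped by the stated
#'   fraction of the prominence); `"prominence_fraction"` reads the cutoff
#'   as the absolute level `frac * prominence`. Both are floored at
#'   `boundary_mean_frac * channel mean`. See the methods vignette for why
#'   `"prominence_drop"` is the default.
#' @param min_dur,max_dur Accepted duration range in seconds.
#' @param fft_bins FFT length for spindle spectral features.
#' @param spike_factor Noise-spike rejection factor: a segment is rejected
#'   when its largest absolute sample-to-sample step exceeds `spike_factor`
#'   times its mean absolute step.
#' @param min_pos_peaks Minimum number of positive peaks in the band-pass
#'   filtered spindle.
#' @param wavelet_step Spacing of wavelet center frequencies in Hz.
#' @param wavelet_cycles Morlet wavelet width in cycles.
#' @param envelope_smooth Moving-average smoothing of the power envelope,
#'   in seconds.
#' @return A list of class `spindle_detection_config`.
#' @examples
#' cfg <- detection_config()
#' cfg$threshold_factor
#' @export
detection_config <- function(detect_band = c(5, 16),
                             classical_band = c(10, 16),
                             threshold_factor = 1.8,
                             boundary_prominence_frac = 0.8,
                             boundary_mean_frac = 1.2,
                             boundary_rule = c("prominence_drop",
                                               "prominence_fraction"),
                             min_dur = 0.3,
                             max_dur = 3,
                             fft_bins = 1024L,
                             spike_factor = 10,
                             min_pos_peaks = 3L,
                             wavelet_step = 0.5,
                             wavelet_cycles = 7,
                             envelope_smooth = 0.1) {
  check_band(detect_band, "detect_band")
  check_band(classical_band, "classical_band")
  stopifnot(threshold_factor > 0, boundary_prominence_frac > 0,
            boundary_mean_frac > 0, min_dur > 0, min_dur < max_dur,
            fft_bins >= 8, spike_factor > 0, min_pos_peaks >= 0,
            wavelet_step > 0, wavelet_cycles > 0, envelope_smooth >= 0)
  structure(list(
    detect_band = as.numeric(detect_band),
    classical_band = as.numeric(classical_band),
    threshold_factor = threshold_factor,
    boundary_prominence_frac = boundary_prominence_frac,
    boundary_mean_frac = boundary_mean_frac,
    boundary_rule = match.arg(boundary_rule),
    min_dur = min_dur, max_dur = max_dur,
    fft_bins = as.integer(fft_bins),
    spike_factor = spike_factor,
    min_pos_peaks = as.integer(min_pos_peaks),
    wavelet_step = wavelet_step,
    wavelet_cycles = wavelet_cycles,
    envelope_smooth = envelope_smooth),
    class = "spindle_detection_config")
}

#' @export
print.spindle_detection_config <- function(x, ...) {
  cat("Spindle detection configuration\n")
  cat(sprintf("  detection band     %g-%g Hz (classical %g-%g Hz)\n",
              x$detect_band[1], x$detect_band[2], x$classical_band[1],
              x$classical_band[2]))
  cat(sprintf("  threshold          %g x baseline mean power\n",
              x$threshold_factor))
  cat(sprintf("  boundaries         %s (%g prominence, %g x mean floor)\n",
              x$boundary_rule, x$boundary_prominence_frac,
              x$boundary_mean_frac))
  cat(sprintf("  duration filter    %g-%g s; >=%d positive peaks; %gx spike rule\n",
              x$min_dur, x$max_dur, x$min_pos_peaks, x$spike_factor))
  invisible(x)
}

#' Synthetic polysomnography configuration
#'
#' Parameters of the synthetic multichannel EEG generator used to validate
#' the pipeline against known ground truth. The defaults emulate an ovine
#' polysomnography segment: eight cortical channels at 250 Hz, pink (1/f)
#' background, stage-dependent slow-wave activity in NREM epochs, spindle
#' bursts injected mainly in NREM stages at a few events per minute, a
#' quarter of events global (>= 4 channels) and coupled to an injected
#' slow wave, plus occasional single-sample voltage spikes.
#'
#' @param n_channels Number of channels (default 8; labels follow the
#'   ovine montage `A1-L ... P-R`).
#' @param rate Sampling rate in Hz.
#' @param stage_sequence Data frame with columns `stage`, `duration`
#'   (seconds) describing the vigilance-state timeline.
#' @param spindle_rate Named numeric vector, spindle events per minute per
#'   stage label.
#' @param freq_range Spindle frequency range in Hz.
#' @param duration_range Spindle duration range in seconds.
#' @param amplitude_snr Spindle sine amplitude as a multiple of the mean
#'   background envelope amplitude in the classical band.
#' @param sw_amplitude_range Amplitude range (signal units) of the slow
#'   wave injected under global events.
#' @param global_fraction Fraction of events placed on >= 4 channels.
#' @param spike_rate Single-sample voltage spikes per minute.
#' @param bg_sd Standard deviation of the 1/f background, signal units
#'   (millivolts by convention).
#' @param sw_bg_amp Named amplitudes of the stage-dependent background
#'   slow-wave component for light and deep NREM.
#' @param wake_broadband_sd Standard deviation of the extra low-voltage
#'   fast (20-45 Hz) activity added in wake epochs.
#' @param wake_attenuation Multiplier applied to the 1/f background in
#'   wake epochs; wake EEG is desynchronized and low voltage, so its
#'   slow-frequency background is weaker than in sleep.
#' @param seed Integer seed fixing the whole realization.
#' @return A list of class `eeg_sim_config`.
#' @examples
#' cfg <- sim_config(seed = 42)
#' cfg$spindle_rate
#' @export
sim_config <- function(n_channels = 8,
                       rate = 250,
                       stage_sequence = default_stage_sequence(),
                       spindle_rate = c(W = 0.3, WU = 0.3, S1 = 2, S2 = 4,
                                        U1 = 2, U2 = 4, R = 0),
                       freq_range = c(10, 16),
                       duration_range = c(0.5, 1.5),
                       amplitude_snr = 5,
                       sw_amplitude_range = c(0.05, 0.15),
                       global_fraction = 0.25,
                       spike_rate = 0.1,
                       bg_sd = 0.02,
                       sw_bg_amp = c(light = 0.03, deep = 0.08),
                       wake_broadband_sd = 0.01,
                       wake_attenuation = 0.6,
                       seed = 1L) {
  stopifnot(n_channels >= 1, rate > 0,
            all(c("stage", "duration") %in% names(stage_sequence)),
            all(stage_sequence$duration > 0),
            all(spindle_rate >= 0), global_fraction >= 0,
            global_fraction <= 1, spike_rate >= 0, amplitude_snr >= 0,
            bg_sd > 0)
  bad <- setdiff(unique(stage_sequence$stage), stages_all())
  if (length(bad) > 0L) {
    stop("unknown stage(s) in stage_sequence: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  labels <- default_channel_labels(n_channels)
  structure(list(
    n_channels = as.integer(n_channels), rate = rate, labels = labels,
    stage_sequence = tibble::as_tibble(stage_sequence),
    spindle_rate = spindle_rate, freq_range = as.numeric(freq_range),
    duration_range = as.numeric(duration_range),
    amplitude_snr = amplitude_snr,
    sw_amplitude_range = as.numeric(sw_amplitude_range),
    global_fraction = global_fraction, spike_rate = spike_rate,
    bg_sd = bg_sd, sw_bg_amp = sw_bg_amp,
    wake_broadband_sd = wake_broadband_sd,
    wake_attenuation = wake_attenuation,
    seed = as.integer(seed)),
    class = "eeg_sim_config")
}

#' @rdname sim_config
#' @export
default_stage_sequence <- function() {
  tibble::tibble(
    stage = c("W", "S1", "S2", "S1", "R", "W", "S1", "S2", "R"),
    duration = c(90, 60, 300, 60, 90, 60, 60, 300, 60))
}

default_channel_labels <- function(n) {
  std <- c("A1-L", "A1-R", "A2-L", "A2-R", "C-L", "C-R", "P-L", "P-R")
  if (n <= length(std)) std[seq_len(n)] else c(std, paste0("X", seq_len(n - 8L)))
}
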