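# Spindle-slow-wave relationship: nearest-extremum peak-to-peak amplitude
# within +/- 3 s of the spindle center, and an analytic-signal phase.

#' Slow-wave filtered recording
#'
#' Zero-phase 4th-order Butterworth band-pass of every channel between 0.5
#' and 2 Hz, the slow-wave band.
#'
#' @param rec A recording with rate of at least 4 Hz.
#' @param band Band edges in Hz.
#' @return A recording-shaped tibble of filtered traces.
#' @export
filter_slow_wave <- function(rec, band = c(0.5, 2)) {
  rate <- eeg_rate(rec)
  check_band(band, "slow-wave band")
  m <- recording_matrix(rec)
  f <- apply(m, 2L, bandpass_filter, band = band, rate = rate)
  as_recording(f, rate = rate, labels = channel_names(rec),
               start_time = rec$time[1L])
}

# Nearest positive and negative peak to `center` within +/- window, on one
# filtered trace. Extrema are local extrema of the whole trace that fall
# inside the window. Returns NA p2p when either extremum class is absent.
nearest_extrema_p2p <- function(x, time, center, window) {
  n <- length(x)
  sel <- which(time >= center - window & time <= center + window)
  truncated <- (center - window) < time[1L] - 1e-9 ||
    (center + window) > time[n] + 1e-9
  if (length(sel) == 0L) {
    return(list(p2p = NA_real_, pos_t = NA_real_, neg_t = NA_real_,
                truncated = truncated))
  }
  lo <- max(1L, sel[1L] - 1L)
  hi <- min(n, sel[length(sel)] + 1L)
  seg <- x[lo:hi]
  imax <- local_maxima(seg) + lo - 1L
  imin <- local_minima(seg) + lo - 1L
  imax <- imax[imax >= sel[1L] & imax <= sel[length(sel)]]
  imin <- imin[imin >= sel[1L] & imin <= sel[length(sel)]]
  if (length(imax) == 0L || length(imin) == 0L) {
    return(list(p2p = NA_real_, pos_t = NA_real_, neg_t = NA_real_,
                truncated = truncated))
  }
  best_max <- imax[which.min(abs(time[imax] - center))]
  best_min <- imin[which.min(abs(time[imin] - center))]
  list(p2p = x[best_max] - x[best_min], pos_t = time[best_max],
       neg_t = time[best_min], truncated = truncated)
}

#' Slow-wave coupling of detected spindles
#'
#' For every accepted event, the slow-wave (0.5-2 Hz) trace of the event's
#' own channel is examined in a window of `window` seconds either side of
#' the spindle center. The positive and negative peaks nearest in time to
#' the center give the slow-wave peak-to-peak amplitude; the instantaneous
#' phase of the analytic representation at the center sample gives the
#' spindle-slow-wave phase angle (0 at the slow-wave positive peak,
#' +/- pi at the trough, -pi/2 on the ascending zero crossing).
#'
#' Windows are clipped at the recording bounds and flagged `truncated`;
#' events with less than `min_side` seconds of usable window on either
#' side are marked unusable and should be dropped from coupling summaries.
#'
#' @param rec The raw recording.
#' @param events A `spindle_events` or `spindle_catalog` tibble.
#' @param window Half-window in seconds (default 3).
#' @param band Slow-wave band in Hz.
#' @param min_side Minimum usable window on each side in seconds.
#' @return A tibble of class `sw_coupling` with `channel`, `center`,
#'   `sw_p2p`, `sw_phase`, `truncated`, `usable` (plus `id` when the
#'   input is a catalog).
#' @export
sw_coupling <- function(rec, events, window = 3, band = c(0.5, 2),
                        min_side = 1) {
  rate <- eeg_rate(rec)
  sw <- filter_slow_wave(rec, band)
  m <- recording_matrix(sw)
  phase <- apply(m, 2L, function(x) Arg(analytic_signal(x)))
  colnames(phase) <- colnames(m)
  t0 <- rec$time[1L]
  t_end <- rec$time[nrow(rec)]
  ev <- tibble::as_tibble(events)
  if ("accepted" %in% names(ev)) ev <- ev[ev$accepted, , drop = FALSE]
  out <- purrr::map_dfr(seq_len(nrow(ev)), function(i) {
    ch <- ev$channel[i]
    center <- (ev$start[i] + ev$end[i]) / 2
    ex <- nearest_extrema_p2p(m[, ch], rec$time, center, window)
    c_idx <- round((center - t0) * rate) + 1L
    c_idx <- min(max(c_idx, 1L), nrow(m))
    tibble::tibble(
      channel = ch, center = center, sw_p2p = ex$p2p,
      sw_phase = phase[c_idx, ch], truncated = ex$truncated,
      usable = (center - t0) >= min_side & (t_end - center) >= min_side &
        !is.na(ex$p2p))
  })
  if ("id" %in% names(ev)) out <- tibble::add_column(out, id = ev$id,
                                                     .before = 1L)
  class(out) <- unique(c("sw_coupling", class(out)))
  out
}

#' Compare slow-wave amplitude under local vs simultaneous spindles
#'
#' Group means of the slow-wave peak-to-peak amplitude (and circular mean
#' phase) for local versus simultaneous spindles. Purely descriptive; no
#' hypothesis test is performed.
#'
#' @param catalog A [annotate_simultaneity()] catalog.
#' @param couplings The [sw_coupling()] table for the same catalog (must
#'   carry `id`).
#' @return A tibble with `group` (`"local"`/`"simultaneous"`), `n`,
#'   `mean_p2p`, `mean_phase`. Empty groups report `NA` means.
#' @export
compare_local_simultaneous <- function(catalog, couplings) {
  if (!"id" %in% names(couplings)) {
    stop("`couplings` must be computed from the annotated catalog ",
         "(missing `id`)", call. = FALSE)
  }
  d <- dplyr::inner_join(
    tibble::as_tibble(catalog)[, c("id", "is_local")],
    tibble::as_tibble(couplings)[, c("id", "sw_p2p", "sw_phase", "usable")],
    by = "id")
  d <- d[d$usable, , drop = FALSE]
  purrr::map_dfr(c(local = TRUE, simultaneous = FALSE), function(loc) {
    s <- d[d$is_local == loc, , drop = FALSE]
    tibble::tibble(n = nrow(s),
                   mean_p2p = if (nrow(s) > 0) mean(s$sw_p2p) else NA_real_,
                   mean_phase = circular_mean(s$sw_phase))
  }, .id = "group")
}
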