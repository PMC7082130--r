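# Sleep macrostructure: delta-power NREM substaging, sleep-cycle
# identification, within-cycle and hourly spindle-density profiles.

#' Per-epoch delta power
#'
#' Hanning-windowed full-epoch power spectra, band power summed over the
#' delta band and averaged across channels.
#'
#' @param rec A recording.
#' @param hypnogram A hypnogram aligned to the recording.
#' @param delta_band Delta band in Hz (default 0.5-4).
#' @return A tibble with `epoch`, `delta_power` (`NA` for epochs not fully
#'   inside the recording).
#' @export
epoch_delta_power <- function(rec, hypnogram, delta_band = c(0.5, 4)) {
  rate <- eeg_rate(rec)
  epoch_len <- hypnogram_epoch_len(hypnogram)
  m <- recording_matrix(rec)
  spp <- round(epoch_len * rate)
  purrr::map_dfr(hypnogram$epoch, function(ep) {
    i0 <- (ep - 1L) * spp + 1L
    i1 <- ep * spp
    if (i1 > nrow(m)) {
      return(tibble::tibble(epoch = ep, delta_power = NA_real_))
    }
    dp <- mean(vapply(seq_len(ncol(m)), function(ch) {
      band_power(psd_hann(m[i0:i1, ch], rate), delta_band)
    }, numeric(1)))
    tibble::tibble(epoch = ep, delta_power = dp)
  })
}

#' Split NREM epochs into light and deep by delta power
#'
#' NREM epochs whose mean delta power reaches at least 50% of the
#' recording's maximum epoch delta power are labelled deep (`S2`, or `U2`
#' when the input carried rumination), the rest light (`S1`/`U1`).
#' Non-NREM epochs are untouched. The threshold is taken over non-artifact
#' epochs of the whole recording; epochs exactly at threshold are deep.
#'
#' @param rec A recording.
#' @param hypnogram A hypnogram whose NREM epochs may be unresolved
#'   (any of `S1`, `S2`, `U1`, `U2`).
#' @param delta_band Delta band in Hz.
#' @param threshold_frac Fraction of the maximum delta power (default 0.5).
#' @return The hypnogram with stages re-labelled and columns
#'   `delta_power`, `deep` added; the threshold is in the
#'   `"delta_threshold"` attribute.
#' @export
substage_nrem <- function(rec, hypnogram, delta_band = c(0.5, 4),
                          threshold_frac = 0.5) {
  is_nrem <- hypnogram$stage %in% stages_nrem()
  if (!any(is_nrem)) stop("hypnogram contains no NREM epochs", call. = FALSE)
  dp <- epoch_delta_power(rec, hypnogram, delta_band)
  ref <- dp$delta_power[!hypnogram$artifact]
  ref <- ref[is.finite(ref)]
  if (length(ref) == 0L) stop("no usable epochs for the delta threshold",
                              call. = FALSE)
  thr <- threshold_frac * max(ref)
  deep <- dp$delta_power >= thr
  out <- hypnogram
  ruminating <- out$stage %in% c("U1", "U2")
  out$stage[is_nrem] <- ifelse(deep[is_nrem],
                               ifelse(ruminating[is_nrem], "U2", "S2"),
                               ifelse(ruminating[is_nrem], "U1", "S1"))
  out$delta_power <- dp$delta_power
  out$deep <- is_nrem & deep
  attr(out, "delta_threshold") <- thr
  attr(out, "epoch_len") <- hypnogram_epoch_len(hypnogram)
  class(out) <- unique(c("eeg_hypnogram", class(out)))
  out
}

#' Identify sleep cycles
#'
#' A sleep cycle starts after at least 30 s of contiguous wake (`W`/`WU`),
#' followed by a contiguous NREM run of at least 2 min (any interior
#' non-NREM epoch breaks the run), and terminates at the first epoch of
#' wake or of a REM run lasting at least 1 min. The cycle spans the NREM
#' onset to the terminator onset.
#'
#' @param hypnogram A hypnogram.
#' @param min_wake Minimum preceding wake in seconds.
#' @param min_nrem Minimum NREM run in seconds.
#' @param min_rem Minimum REM run for a REM terminator, in seconds.
#' @return A tibble of class `sleep_cycles` with `start`, `end` (seconds)
#'   and `terminator` (`"wake"` or `"rem"`); zero rows when no cycle
#'   qualifies.
#' @examples
#' hyp <- as_hypnogram(c(rep("W", 4), rep("S2", 18), rep("R", 9), "W"))
#' find_sleep_cycles(hyp)
#' @export
find_sleep_cycles <- function(hypnogram, min_wake = 30, min_nrem = 120,
                              min_rem = 60) {
  epoch_len <- hypnogram_epoch_len(hypnogram)
  grp <- function(st) {
    ifelse(st %in% stages_wake(), "wake",
           ifelse(st %in% stages_nrem(), "nrem",
                  ifelse(st %in% stages_rem(), "rem", "other")))
  }
  g <- grp(hypnogram$stage)
  r <- rle(g)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  secs <- r$lengths * epoch_len
  cycles <- list()
  for (k in seq_along(r$values)) {
    if (r$values[k] != "wake" || secs[k] < min_wake) next
    if (k + 1L > length(r$values)) break
    if (r$values[k + 1L] != "nrem" || secs[k + 1L] < min_nrem) next
    if (k + 2L > length(r$values)) next
    term <- r$values[k + 2L]
    ok <- (term == "wake") || (term == "rem" && secs[k + 2L] >= min_rem)
    if (!ok) next
    cycles[[length(cycles) + 1L]] <- tibble::tibble(
      start = (starts[k + 1L] - 1L) * epoch_len,
      end = (starts[k + 2L] - 1L) * epoch_len,
      terminator = if (term == "wake") "wake" else "rem")
  }
  out <- if (length(cycles) > 0L) dplyr::bind_rows(cycles) else
    tibble::tibble(start = numeric(0), end = numeric(0),
                   terminator = character(0))
  class(out) <- unique(c("sleep_cycles", class(out)))
  out
}

#' Within-cycle spindle density profile
#'
#' Takes the first `n_cycles` sleep cycles lasting at least `min_cycle`
#' seconds, splits each into consecutive `window`-second periods, counts
#' accepted spindles (all channels pooled, midpoint rule) per period, and
#' normalizes the counts to proportions of the total over all included
#' periods (so the proportions sum to 1 per subject).
#'
#' @param catalog A spindle catalog or accepted events.
#' @param cycles Output of [find_sleep_cycles()].
#' @param window Period length in seconds (default 180).
#' @param min_cycle Minimum qualifying cycle length in seconds (default
#'   1080, i.e. 18 min).
#' @param n_cycles Number of qualifying cycles to use (default 3).
#' @return A tibble with `cycle`, `period`, `t_start`, `t_end`, `count`,
#'   `proportion`; the number of qualifying cycles actually used is in the
#'   `"n_cycles_used"` attribute (fewer than requested is flagged with a
#'   warning).
#' @export
cycle_density_profile <- function(catalog, cycles, window = 180,
                                  min_cycle = 1080, n_cycles = 3) {
  qual <- cycles[cycles$end - cycles$start >= min_cycle, , drop = FALSE]
  if (nrow(qual) == 0L) stop("no sleep cycle reaches the minimum length",
                             call. = FALSE)
  if (nrow(qual) < n_cycles) {
    warning("only ", nrow(qual), " qualifying cycle(s) available (",
            n_cycles, " requested)", call. = FALSE)
  }
  qual <- utils::head(qual[order(qual$start), ], n_cycles)
  ev <- tibble::as_tibble(catalog)
  if ("accepted" %in% names(ev)) ev <- ev[ev$accepted, , drop = FALSE]
  mid <- (ev$start + ev$end) / 2
  out <- purrr::map_dfr(seq_len(nrow(qual)), function(k) {
    n_per <- floor((qual$end[k] - qual$start[k]) / window)
    t_start <- qual$start[k] + (seq_len(n_per) - 1L) * window
    counts <- vapply(t_start, function(ts) {
      sum(mid >= ts & mid < ts + window)
    }, numeric(1))
    tibble::tibble(cycle = k, period = seq_len(n_per), t_start = t_start,
                   t_end = t_start + window, count = counts)
  })
  tot <- sum(out$count)
  out$proportion <- if (tot > 0) out$count / tot else
    rep(NA_real_, nrow(out))
  attr(out, "n_cycles_used") <- nrow(qual)
  out
}

#' Hourly NREM-normalized spindle density
#'
#' Accepted spindles whose midpoint lies in a non-artifact NREM epoch,
#' counted per clock hour of the recording and divided by the minutes of
#' non-artifact NREM in that hour. Hours without NREM are reported as
#' missing, not zero.
#'
#' @param catalog A spindle catalog or accepted events.
#' @param hypnogram A hypnogram.
#' @param by_channel Report per channel rather than pooled.
#' @return A tibble with `hour` (1-based), optionally `channel`,
#'   `n_events`, `nrem_minutes`, `density`.
#' @export
hourly_density <- function(catalog, hypnogram, by_channel = FALSE) {
  epoch_len <- hypnogram_epoch_len(hypnogram)
  hyp <- hypnogram
  hyp$hour <- floor((hyp$epoch - 1L) * epoch_len / 3600) + 1L
  hyp$nrem_ok <- hyp$stage %in% stages_nrem() & !hyp$artifact
  ev <- tibble::as_tibble(catalog)
  if ("accepted" %in% names(ev)) ev <- ev[ev$accepted, , drop = FALSE]
  ep <- event_epochs(ev, epoch_len)
  ev <- ev[ep %in% hyp$epoch[hyp$nrem_ok], , drop = FALSE]
  ev$hour <- floor((ev$start + ev$end) / 2 / 3600) + 1L
  hours <- sort(unique(hyp$hour))
  base <- purrr::map_dfr(hours, function(h) {
    nm <- sum(hyp$nrem_ok[hyp$hour == h]) * epoch_len / 60
    tibble::tibble(hour = h, nrem_minutes = nm)
  })
  if (by_channel) {
    chans <- sort(unique(catalog$channel))
    out <- tidyr::crossing(base, channel = chans)
    out$n_events <- purrr::map2_dbl(out$hour, out$channel, function(h, ch) {
      sum(ev$hour == h & ev$channel == ch)
    })
  } else {
    out <- base
    out$n_events <- purrr::map_dbl(out$hour, function(h) sum(ev$hour == h))
  }
  out$density <- ifelse(out$nrem_minutes > 0,
                        out$n_events / out$nrem_minutes, NA_real_)
  out
}
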