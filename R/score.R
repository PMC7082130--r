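# Ground-truth scoring of the detector on synthetic studies.

#' Score detected spindles against ground truth
#'
#' Expands multi-channel ground-truth events to one expected detection per
#' listed channel, then matches detections to truth greedily, per channel,
#' by midpoint distance (1-to-1, closest pairs first, up to
#' `midpoint_tol` seconds apart). Recall is the fraction of expected
#' channel-events matched; precision the fraction of accepted detections
#' matched. Boundary errors compare detected onset/offset with the
#' injected envelope's extent; frequency error compares the detected peak
#' frequency with the injected one.
#'
#' @param events A `spindle_events` tibble (accepted events are scored).
#' @param truth A ground-truth table from [draw_ground_truth()].
#' @param midpoint_tol Maximum midpoint distance for a match, in seconds.
#' @return A list of class `spindle_score`: `matches` (tibble with one row
#'   per matched pair, including `onset_error`, `offset_error`,
#'   `freq_error`), `n_truth`, `n_detected`, `recall`, `precision`,
#'   `mean_onset_error`, `mean_offset_error`, `mean_abs_freq_error`.
#' @export
score_detection <- function(events, truth, midpoint_tol = 0.5) {
  ev <- tibble::as_tibble(events)
  if ("accepted" %in% names(ev)) ev <- ev[ev$accepted, , drop = FALSE]
  tr <- tidyr::separate_rows(truth, "channels", sep = ";")
  tr <- dplyr::rename(tr, channel = "channels")
  tr$mid <- tr$start + tr$duration / 2
  ev$mid <- (ev$start + ev$end) / 2
  matches <- list()
  for (ch in unique(tr$channel)) {
    t_ch <- tr[tr$channel == ch, , drop = FALSE]
    e_ch <- ev[ev$channel == ch, , drop = FALSE]
    if (nrow(t_ch) == 0L || nrow(e_ch) == 0L) next
    d <- abs(outer(t_ch$mid, e_ch$mid, "-"))
    cand <- which(d <= midpoint_tol, arr.ind = TRUE)
    if (nrow(cand) == 0L) next
    cand <- cand[order(d[cand]), , drop = FALSE]
    used_t <- logical(nrow(t_ch))
    used_e <- logical(nrow(e_ch))
    for (k in seq_len(nrow(cand))) {
      i <- cand[k, 1L]
      j <- cand[k, 2L]
      if (used_t[i] || used_e[j]) next
      used_t[i] <- used_e[j] <- TRUE
      matches[[length(matches) + 1L]] <- tibble::tibble(
        event = t_ch$event[i], channel = ch,
        truth_start = t_ch$start[i],
        truth_end = t_ch$start[i] + t_ch$duration[i],
        det_start = e_ch$start[j], det_end = e_ch$end[j],
        onset_error = abs(e_ch$start[j] - t_ch$start[i]),
        offset_error = abs(e_ch$end[j] -
                             (t_ch$start[i] + t_ch$duration[i])),
        freq_error = e_ch$peak_freq[j] - t_ch$freq[i])
    }
  }
  matches <- if (length(matches) > 0L) dplyr::bind_rows(matches) else
    tibble::tibble(event = integer(0), channel = character(0),
                   truth_start = numeric(0), truth_end = numeric(0),
                   det_start = numeric(0), det_end = numeric(0),
                   onset_error = numeric(0), offset_error = numeric(0),
                   freq_error = numeric(0))
  n_truth <- nrow(tr)
  n_det <- nrow(ev)
  structure(list(
    matches = matches, n_truth = n_truth, n_detected = n_det,
    recall = if (n_truth > 0) nrow(matches) / n_truth else NA_real_,
    precision = if (n_det > 0) nrow(matches) / n_det else NA_real_,
    mean_onset_error = mean(matches$onset_error),
    mean_offset_error = mean(matches$offset_error),
    mean_abs_freq_error = mean(abs(matches$freq_error))),
    class = "spindle_score")
}

#' @export
print.spindle_score <- function(x, ...) {
  cat(sprintf(paste0("Spindle detection score: recall %.3f (%d/%d), ",
                     "precision %.3f\n"),
              x$recall, nrow(x$matches), x$n_truth, x$precision))
  cat(sprintf("  boundary error %.3f s onset / %.3f s offset; ",
              x$mean_onset_error, x$mean_offset_error))
  cat(sprintf("|freq error| %.3f Hz\n", x$mean_abs_freq_error))
  invisible(x)
}

#' @export
glance.spindle_score <- function(x, ...) {
  tibble::tibble(n_truth = x$n_truth, n_detected = x$n_detected,
                 n_matched = nrow(x$matches), recall = x$recall,
                 precision = x$precision,
                 mean_onset_error = x$mean_onset_error,
                 mean_offset_error = x$mean_offset_error,
                 mean_abs_freq_error = x$mean_abs_freq_error)
}

#' @export
tidy.spindle_score <- function(x, ...) x$matches
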