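# State-space analysis: per-epoch spectral ratios SSR1 = 6.5-9 / 0.5-9 Hz
# and SSR2 = 0.5-20 / 0.5-100 Hz, proportional density grids on a 41 x 41
# lattice of unit 0.025, combined maps and contour thresholds.

ssr_bands <- function() {
  list(ssr1 = list(num = c(6.5, 9), den = c(0.5, 9)),
       ssr2 = list(num = c(0.5, 20), den = c(0.5, 100)))
}

# Ratios from one set of per-channel epoch spectra (list of psd tibbles).
ssr_from_spectra <- function(specs) {
  freq <- specs[[1L]]$freq
  power <- rowMeans(vapply(specs, function(s) s$power,
                           numeric(length(freq))))
  spec <- tibble::tibble(freq = freq, power = power)
  b <- ssr_bands()
  d1 <- band_power(spec, b$ssr1$den)
  d2 <- band_power(spec, b$ssr2$den)
  if (d1 <= 0 || d2 <= 0) {
    return(c(ssr1 = NA_real_, ssr2 = NA_real_))
  }
  c(ssr1 = band_power(spec, b$ssr1$num) / d1,
    ssr2 = band_power(spec, b$ssr2$num) / d2)
}

#' Per-epoch state-space ratios
#'
#' For every non-artifact hypnogram epoch, a Hanning-windowed full-epoch
#' power spectrum is computed per channel; spectra are averaged across
#' channels (`source = "all_channels_mean"`) or taken from a single
#' channel (`source = "spindle_channel"`), and the two band-power ratios
#' are formed. Band sums use bins whose centers fall in `[low, high)`, so
#' both ratios are guaranteed to lie in `[0, 1]` by band nesting. Epochs
#' with zero denominator power are flagged undefined and excluded from
#' maps.
#'
#' @param rec A recording with a sampling rate of at least 200 Hz (the
#'   100 Hz band edge must be below Nyquist).
#' @param hypnogram A hypnogram; epochs flagged as artifact are skipped.
#' @param stages Stage labels to include (default wake plus NREM).
#' @param source `"all_channels_mean"` or `"spindle_channel"`.
#' @param spindle_channel Channel label, required when
#'   `source = "spindle_channel"`.
#' @return A tibble of class `state_space_epochs` with `epoch`, `stage`,
#'   `ssr1`, `ssr2`.
#' @export
epoch_ssr <- function(rec, hypnogram,
                      stages = c(stages_wake(), stages_nrem()),
                      source = c("all_channels_mean", "spindle_channel"),
                      spindle_channel = NULL) {
  source <- match.arg(source)
  rate <- eeg_rate(rec)
  if (rate < 200) {
    stop("state-space analysis needs a rate of at least 200 Hz for the ",
         "100 Hz band edge", call. = FALSE)
  }
  epoch_len <- hypnogram_epoch_len(hypnogram)
  m <- recording_matrix(rec)
  if (source == "spindle_channel") {
    if (is.null(spindle_channel) || !spindle_channel %in% colnames(m)) {
      stop("`spindle_channel` must name a channel of the recording",
           call. = FALSE)
    }
    m <- m[, spindle_channel, drop = FALSE]
  }
  spp <- round(epoch_len * rate)
  keep <- hypnogram[hypnogram$stage %in% stages & !hypnogram$artifact, ]
  out <- purrr::map_dfr(seq_len(nrow(keep)), function(k) {
    ep <- keep$epoch[k]
    i0 <- (ep - 1L) * spp + 1L
    i1 <- ep * spp
    if (i1 > nrow(m)) return(NULL)
    specs <- lapply(seq_len(ncol(m)), function(ch) {
      psd_hann(m[i0:i1, ch], rate)
    })
    r <- ssr_from_spectra(specs)
    tibble::tibble(epoch = ep, stage = keep$stage[k], ssr1 = r[["ssr1"]],
                   ssr2 = r[["ssr2"]])
  })
  class(out) <- unique(c("state_space_epochs", class(out)))
  out
}

#' Proportional density map over state space
#'
#' Bins `(ssr1, ssr2)` pairs into a 41 x 41 grid of unit 0.025 (cells
#' `[k * 0.025, (k + 1) * 0.025)`, `k = 0 ... 40`, so the closed upper
#' boundary at ratio 1 lands in the 41st cell) and divides by the number
#' of epochs: the per-subject map is a proportional density totalling 1
#' over its 1681 cells.
#'
#' @param epochs A `state_space_epochs` tibble; rows with undefined ratios
#'   are dropped.
#' @param unit Grid unit (default 0.025).
#' @param n_bins Cells per axis (default 41).
#' @return A tibble of class `state_space_map` in long format (`ssr1_bin`,
#'   `ssr2_bin` 0-based, `weight`), with attributes `unit`, `n_bins`,
#'   `n_subjects = 1` and `n_epochs`.
#' @export
build_density_map <- function(epochs, unit = 0.025, n_bins = 41L) {
  ok <- is.finite(epochs$ssr1) & is.finite(epochs$ssr2)
  e <- epochs[ok, , drop = FALSE]
  if (nrow(e) == 0L) stop("no epochs with defined ratios", call. = FALSE)
  b1 <- pmin(floor(e$ssr1 / unit), n_bins - 1L)
  b2 <- pmin(floor(e$ssr2 / unit), n_bins - 1L)
  grid <- tidyr::crossing(ssr1_bin = seq_len(n_bins) - 1L,
                          ssr2_bin = seq_len(n_bins) - 1L)
  counts <- table(factor(b1 * n_bins + b2,
                         levels = 0:(n_bins * n_bins - 1L)))
  grid <- dplyr::arrange(grid, .data$ssr1_bin, .data$ssr2_bin)
  grid$weight <- as.numeric(counts) / nrow(e)
  attr(grid, "unit") <- unit
  attr(grid, "n_bins") <- as.integer(n_bins)
  attr(grid, "n_subjects") <- 1L
  attr(grid, "n_epochs") <- nrow(e)
  class(grid) <- unique(c("state_space_map", class(grid)))
  grid
}

#' Combine per-subject density maps
#'
#' Cellwise sum of per-subject proportional maps, so the combined total
#' equals the number of subjects.
#'
#' @param maps A list of `state_space_map` objects on identical grids.
#' @return A `state_space_map` whose `n_subjects` attribute is the sum of
#'   the inputs'.
#' @export
combine_maps <- function(maps) {
  if (length(maps) == 0L) stop("no maps to combine", call. = FALSE)
  ref <- maps[[1L]]
  for (m in maps[-1L]) {
    if (!identical(attr(m, "n_bins"), attr(ref, "n_bins")) ||
        !identical(attr(m, "unit"), attr(ref, "unit"))) {
      stop("maps are on different grids", call. = FALSE)
    }
  }
  out <- ref
  out$weight <- Reduce(`+`, lapply(maps, function(m) m$weight))
  attr(out, "n_subjects") <-
    sum(vapply(maps, function(m) attr(m, "n_subjects"), integer(1)))
  attr(out, "n_epochs") <-
    sum(vapply(maps, function(m) attr(m, "n_epochs"), numeric(1)))
  out
}

#' Contour thresholds for combined density maps
#'
#' With an even density spread every cell of a combined map would hold
#' `n_subjects / n_cells`; the display contours are set at multiples of
#' that baseline (2.5x and 5x by default).
#'
#' @param n_subjects Number of subjects summed into the map.
#' @param n_cells Number of grid cells (default 1681 = 41 x 41).
#' @param low_mult,high_mult Contour multipliers.
#' @return Named numeric vector `c(low = ..., high = ...)`.
#' @examples
#' contour_levels(6)
#' @export
contour_levels <- function(n_subjects, n_cells = 1681L, low_mult = 2.5,
                           high_mult = 5) {
  stopifnot(n_subjects > 0, n_cells > 0, low_mult > 0, high_mult > 0)
  c(low = low_mult * n_subjects / n_cells,
    high = high_mult * n_subjects / n_cells)
}

#' Spindle-centered state-space map
#'
#' Builds the density map from 10 s epochs centered on every local
#' accepted spindle midpoint. Ratios are computed either from the
#' channel-mean spectra or, per event, from the channel that carried the
#' spindle. Spindles whose centered epoch would extend past the recording
#' bounds are skipped (count in the `"n_skipped"` attribute).
#'
#' @param rec The recording.
#' @param catalog An annotated catalog ([annotate_simultaneity()]).
#' @param source `"all_channels_mean"` or `"spindle_channel"`.
#' @param epoch_len Epoch length in seconds (default 10).
#' @param unit,n_bins Grid parameters, as in [build_density_map()].
#' @return A `state_space_map`.
#' @export
spindle_epoch_map <- function(rec, catalog,
                              source = c("all_channels_mean",
                                         "spindle_channel"),
                              epoch_len = 10, unit = 0.025, n_bins = 41L) {
  source <- match.arg(source)
  rate <- eeg_rate(rec)
  if (rate < 200) stop("state-space analysis needs a rate of at least 200 Hz",
                       call. = FALSE)
  m <- recording_matrix(rec)
  t0 <- rec$time[1L]
  loc <- catalog[catalog$is_local, , drop = FALSE]
  if (nrow(loc) == 0L) stop("catalog contains no local spindles",
                            call. = FALSE)
  spp <- round(epoch_len * rate)
  half <- spp %/% 2L
  n_skipped <- 0L
  rows <- purrr::map_dfr(seq_len(nrow(loc)), function(k) {
    c_idx <- round(((loc$start[k] + loc$end[k]) / 2 - t0) * rate) + 1L
    i0 <- c_idx - half
    i1 <- i0 + spp - 1L
    if (i0 < 1L || i1 > nrow(m)) {
      n_skipped <<- n_skipped + 1L
      return(NULL)
    }
    cols <- if (source == "spindle_channel") loc$channel[k] else colnames(m)
    specs <- lapply(cols, function(ch) psd_hann(m[i0:i1, ch], rate))
    r <- ssr_from_spectra(specs)
    tibble::tibble(epoch = k, stage = NA_character_, ssr1 = r[["ssr1"]],
                   ssr2 = r[["ssr2"]])
  })
  if (nrow(rows) == 0L) stop("all local spindles are too close to the ",
                             "recording edge", call. = FALSE)
  map <- build_density_map(rows, unit = unit, n_bins = n_bins)
  attr(map, "n_skipped") <- n_skipped
  map
}

#' Cells above a density threshold
#'
#' @param map A `state_space_map`.
#' @param level Density threshold (e.g. one of [contour_levels()]).
#' @return The map rows whose weight is at least `level`.
#' @export
map_cells_above <- function(map, level) {
  tibble::as_tibble(map)[map$weight >= level, , drop = FALSE]
}

#' Write a state-space map
#'
#' Long format `ssr1_bin,ssr2_bin,weight`.
#'
#' @param map A `state_space_map`.
#' @param path Output path.
#' @export
write_density_map <- function(map, path) {
  readr::write_csv(tibble::as_tibble(map), path, progress = FALSE)
  invisible(path)
}
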