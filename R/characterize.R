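# Local vs simultaneous spindle topography, connectivity matrices, and
# per-stage densities and summaries.

#' Annotate temporal simultaneity across channels
#'
#' Classifies every accepted event as local (no temporally overlapping
#' event on any other channel) or simultaneous, by pairwise half-open
#' interval overlap. No transitive closure is applied: overlapping is a
#' pairwise relation, so a chain A-B, B-C does not link A and C.
#'
#' @param events A `spindle_events` tibble; only accepted events are
#'   annotated (others are dropped from the catalog).
#' @return A tibble of class `spindle_catalog`: the accepted events plus
#'   `id`, `partners` (list-column of overlapping events' channels),
#'   `multiplicity` (1 + number of distinct partner channels) and
#'   `is_local`.
#' @examples
#' ev <- tibble::tibble(channel = c("a", "b"), start = c(1, 1.5),
#'                      end = c(2, 2.5), accepted = TRUE)
#' annotate_simultaneity(ev)$multiplicity
#' @export
annotate_simultaneity <- function(events) {
  ev <- tibble::as_tibble(events)
  if ("accepted" %in% names(ev)) ev <- ev[ev$accepted, , drop = FALSE]
  n <- nrow(ev)
  ev$id <- seq_len(n)
  partners <- vector("list", n)
  partner_ids <- vector("list", n)
  if (n > 1L) {
    ord <- order(ev$start)
    for (a in seq_len(n - 1L)) {
      i <- ord[a]
      for (b in seq((a + 1L), n)) {
        j <- ord[b]
        if (ev$start[j] >= ev$end[i]) break
        if (ev$channel[i] != ev$channel[j]) {
          partners[[i]] <- c(partners[[i]], ev$channel[j])
          partners[[j]] <- c(partners[[j]], ev$channel[i])
          partner_ids[[i]] <- c(partner_ids[[i]], ev$id[j])
          partner_ids[[j]] <- c(partner_ids[[j]], ev$id[i])
        }
      }
    }
  }
  ev$partners <- lapply(partners, function(p) sort(unique(p %||% character(0))))
  ev$partner_ids <- lapply(partner_ids, function(p) sort(p %||% integer(0)))
  ev$multiplicity <- 1L + lengths(ev$partners)
  ev$is_local <- ev$multiplicity == 1L
  attr(ev, "config") <- attr(events, "config")
  attr(ev, "rate") <- attr(events, "rate")
  class(ev) <- unique(c("spindle_catalog", class(ev)))
  ev
}

connectivity_from_pairs <- function(pairs, channels,
                                    normalization = c("global",
                                                      "per_channel_row")) {
  normalization <- match.arg(normalization)
  m <- matrix(0, length(channels), length(channels),
              dimnames = list(channels, channels))
  if (nrow(pairs) > 0L) {
    for (k in seq_len(nrow(pairs))) {
      a <- pairs$a[k]
      b <- pairs$b[k]
      m[a, b] <- m[a, b] + 1
      m[b, a] <- m[b, a] + 1
    }
  }
  w <- m
  if (normalization == "global") {
    tot <- sum(m[upper.tri(m)])
    if (tot > 0) w <- m / tot
  } else {
    rs <- rowSums(m)
    nz <- rs > 0
    w[nz, ] <- m[nz, , drop = FALSE] / rs[nz]
  }
  out <- tibble::as_tibble(as.data.frame.table(m, stringsAsFactors = FALSE))
  names(out) <- c("channel_a", "channel_b", "count")
  out$weight <- as.vector(w)
  attr(out, "normalization") <- normalization
  attr(out, "channels") <- channels
  class(out) <- unique(c("spindle_connectivity", class(out)))
  out
}

#' Pairwise and global spindle connectivity
#'
#' `pair_connectivity()` tallies simultaneous occurrences restricted to
#' events of multiplicity exactly 2 (a spindle seen on exactly two
#' channels), per unordered channel pair; `global_connectivity()` does the
#' same over widespread events of multiplicity at least `min_channels`
#' (4 by default). Two normalizations are offered: `"global"` divides by
#' the total number of tallied co-occurrences (unordered pair weights sum
#' to 1), `"per_channel_row"` divides each channel's row by its own total
#' (each non-empty row sums to 1).
#'
#' @param catalog A [annotate_simultaneity()] catalog.
#' @param normalization `"global"` or `"per_channel_row"`.
#' @param channels Channel universe for the matrix; defaults to the
#'   channels present in the catalog.
#' @return A long-format tibble of class `spindle_connectivity` with
#'   `channel_a`, `channel_b`, `count`, `weight`; convert with
#'   [connectivity_matrix()].
#' @export
pair_connectivity <- function(catalog, normalization = c("global",
                                                         "per_channel_row"),
                              channels = NULL) {
  channels <- channels %||% sort(unique(catalog$channel))
  sel <- catalog$multiplicity == 2L
  pairs <- overlap_pairs(catalog, sel)
  connectivity_from_pairs(pairs, channels, match.arg(normalization))
}

#' @rdname pair_connectivity
#' @param min_channels Minimum multiplicity of a widespread event.
#' @export
global_connectivity <- function(catalog, min_channels = 4L,
                                normalization = c("global",
                                                  "per_channel_row"),
                                channels = NULL) {
  channels <- channels %||% sort(unique(catalog$channel))
  sel <- catalog$multiplicity >= min_channels
  pairs <- overlap_pairs(catalog, sel)
  connectivity_from_pairs(pairs, channels, match.arg(normalization))
}

# Unordered channel pairs of overlapping event pairs, both members of which
# satisfy `sel`.
overlap_pairs <- function(catalog, sel) {
  rows <- list()
  ids <- catalog$id[sel]
  idset <- catalog$id %in% ids
  for (i in which(idset)) {
    pid <- catalog$partner_ids[[i]]
    pid <- pid[pid > catalog$id[i] & pid %in% ids]
    if (length(pid) > 0L) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        a = catalog$channel[i],
        b = catalog$channel[match(pid, catalog$id)])
    }
  }
  if (length(rows) == 0L) return(tibble::tibble(a = character(0),
                                                b = character(0)))
  dplyr::bind_rows(rows)
}

#' Connectivity tibble as a symmetric matrix
#'
#' @param conn A `spindle_connectivity` tibble.
#' @param value `"weight"` or `"count"`.
#' @return A symmetric numeric matrix with channel dimnames.
#' @export
connectivity_matrix <- function(conn, value = c("weight", "count")) {
  value <- match.arg(value)
  channels <- attr(conn, "channels")
  m <- matrix(0, length(channels), length(channels),
              dimnames = list(channels, channels))
  m[cbind(match(conn$channel_a, channels), match(conn$channel_b, channels))] <-
    conn[[value]]
  m
}

# Midpoint-based epoch assignment shared by the density functions.
event_epochs <- function(events, epoch_len) {
  floor((events$start + events$end) / 2 / epoch_len) + 1L
}

#' Spindle density per vigilance stage
#'
#' Counts accepted spindles whose midpoint lies in a non-artifact epoch of
#' the requested stage set, divided by the minutes spent in those epochs.
#' When no time was spent in the stage set the density is undefined and
#' reported as `NA`, not 0.
#'
#' @param catalog A spindle catalog (or accepted `spindle_events`).
#' @param hypnogram A hypnogram covering the events.
#' @param stages Character vector of stage labels (e.g. [stages_nrem()]).
#' @param by_channel Report one density per channel (default) or pooled
#'   over channels.
#' @return A tibble with `channel` (unless pooled), `n_events`, `minutes`,
#'   `density` (spindles per minute).
#' @export
stage_density <- function(catalog, hypnogram, stages = stages_nrem(),
                          by_channel = TRUE) {
  epoch_len <- hypnogram_epoch_len(hypnogram)
  good <- hypnogram$epoch[hypnogram$stage %in% stages & !hypnogram$artifact]
  minutes <- length(good) * epoch_len / 60
  ev <- catalog
  if ("accepted" %in% names(ev)) ev <- ev[ev$accepted, , drop = FALSE]
  ev_in <- ev[event_epochs(ev, epoch_len) %in% good, , drop = FALSE]
  if (by_channel) {
    chans <- sort(unique(catalog$channel))
    counts <- vapply(chans, function(ch) sum(ev_in$channel == ch), numeric(1))
    dens <- if (minutes > 0) unname(counts) / minutes else
      rep(NA_real_, length(chans))
    tibble::tibble(channel = chans, n_events = unname(counts),
                   minutes = minutes, density = dens)
  } else {
    dens <- if (minutes > 0) nrow(ev_in) / minutes else NA_real_
    tibble::tibble(n_events = nrow(ev_in), minutes = minutes,
                   density = dens)
  }
}

#' Per-channel, per-stage spindle summary
#'
#' Spindle density plus mean peak frequency, duration and peak power for
#' every channel x stage combination present in the hypnogram, with
#' optional higher-level grouping (e.g. sleep vs wake) via `stage_groups`.
#' Artifact epochs are excluded from both numerator and denominator.
#' Empty groups yield `NA` means and are kept in the table.
#'
#' @param catalog A spindle catalog.
#' @param hypnogram A hypnogram.
#' @param stage_groups Optional named list mapping group labels to stage
#'   sets, e.g. `list(sleep = stages_nrem(), wake = stages_wake())`.
#'   Defaults to one group per stage present.
#' @return A tibble with `group`, `channel`, `n_events`, `minutes`,
#'   `density`, `mean_freq`, `mean_duration`, `mean_power`.
#' @export
stage_summary <- function(catalog, hypnogram, stage_groups = NULL) {
  if (is.null(stage_groups)) {
    present <- intersect(stages_all(), unique(hypnogram$stage))
    stage_groups <- stats::setNames(as.list(present), present)
  }
  epoch_len <- hypnogram_epoch_len(hypnogram)
  ev <- catalog
  if ("accepted" %in% names(ev)) ev <- ev[ev$accepted, , drop = FALSE]
  ep <- event_epochs(ev, epoch_len)
  chans <- sort(unique(catalog$channel))
  purrr::map_dfr(names(stage_groups), function(g) {
    good <- hypnogram$epoch[hypnogram$stage %in% stage_groups[[g]] &
                              !hypnogram$artifact]
    minutes <- length(good) * epoch_len / 60
    sub <- ev[ep %in% good, , drop = FALSE]
    purrr::map_dfr(chans, function(ch) {
      s <- sub[sub$channel == ch, , drop = FALSE]
      tibble::tibble(
        group = g, channel = ch, n_events = nrow(s), minutes = minutes,
        density = if (minutes > 0) nrow(s) / minutes else NA_real_,
        mean_freq = if (nrow(s) > 0) mean(s$peak_freq) else NA_real_,
        mean_duration = if (nrow(s) > 0) mean(s$duration) else NA_real_,
        mean_power = if (nrow(s) > 0) mean(s$peak_power) else NA_real_)
    })
  })
}
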