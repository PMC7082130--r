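# Run manifests and the aggregate analysis report.

#' Build a run manifest
#'
#' Records what produced a set of outputs: the configuration snapshot, the
#' seed, input file hashes, the package version and a timestamp. Every CLI
#' subcommand writes one next to its outputs.
#'
#' @param config A configuration object (or list) to snapshot.
#' @param inputs Character vector of input file paths to hash.
#' @param seed The seed used, if any.
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(config = NULL, inputs = character(0), seed = NULL) {
  hashes <- if (length(inputs) > 0L) {
    as.list(tools::md5sum(inputs[file.exists(inputs)]))
  } else {
    list()
  }
  structure(list(
    package = "ovispindle",
    version = as.character(utils::packageVersion("ovispindle")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    inputs = hashes,
    config = unclass(config)),
    class = "run_manifest")
}

#' @rdname run_manifest
#' @param manifest A `run_manifest`.
#' @param path Output path for the JSON snapshot.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       pretty = TRUE, force = TRUE, digits = NA)
  invisible(path)
}

fmt_num <- function(x, digits = 3) formatC(x, format = "g", digits = digits)

#' Aggregate analysis report
#'
#' Produces a human-readable markdown summary from whichever analysis
#' products are supplied: detection counts, per-stage densities,
#' local/simultaneous topography, slow-wave coupling, sleep cycles and
#' state-space contours, plus recall/precision against ground truth when a
#' truth table is available. Sections for missing inputs are omitted.
#'
#' @param events A `spindle_events` tibble (optional).
#' @param catalog An annotated catalog (optional).
#' @param hypnogram A hypnogram (optional; enables density sections).
#' @param coupling An [sw_coupling()] table (optional).
#' @param cycles A [find_sleep_cycles()] table (optional).
#' @param map A combined `state_space_map` (optional).
#' @param truth A ground-truth table (optional).
#' @return A character vector of markdown lines, invisibly printable with
#'   `cat(..., sep = "\n")`.
#' @export
run_report <- function(events = NULL, catalog = NULL, hypnogram = NULL,
                       coupling = NULL, cycles = NULL, map = NULL,
                       truth = NULL) {
  if (is.null(events) && is.null(catalog) && is.null(map) &&
      is.null(cycles)) {
    stop("no analysis outputs supplied", call. = FALSE)
  }
  lines <- c("# Spindle analysis report", "")
  if (!is.null(events)) {
    g <- glance.spindle_events(events)
    lines <- c(lines, "## Detection", sprintf(
      "- %d events detected on %d channels; %d accepted, %d rejected",
      g$n_events, g$n_channels, g$n_accepted, g$n_rejected))
    if (g$n_accepted > 0) {
      lines <- c(lines, sprintf(
        "- accepted spindles: mean peak frequency %s Hz, mean duration %s s",
        fmt_num(g$mean_freq), fmt_num(g$mean_duration)))
    }
    lines <- c(lines, "")
  }
  if (!is.null(truth) && !is.null(events)) {
    sc <- score_detection(events, truth)
    lines <- c(lines, "## Ground-truth recovery", sprintf(
      "- recall %s (%d/%d channel-events), precision %s",
      fmt_num(sc$recall), nrow(sc$matches), sc$n_truth,
      fmt_num(sc$precision)), sprintf(
      "- mean boundary error %s s (onset) / %s s (offset); mean |freq error| %s Hz",
      fmt_num(sc$mean_onset_error), fmt_num(sc$mean_offset_error),
      fmt_num(sc$mean_abs_freq_error)), "")
  }
  if (!is.null(catalog)) {
    g <- glance.spindle_catalog(catalog)
    lines <- c(lines, "## Topography", sprintf(
      "- %d accepted spindles: %d local, %d simultaneous (%d on >= 4 channels)",
      g$n_events, g$n_local, g$n_simultaneous, g$n_global), "")
    if (!is.null(hypnogram)) {
      dens <- stage_density(catalog, hypnogram, stages_nrem(),
                            by_channel = FALSE)
      lines <- c(lines, sprintf(
        "- NREM spindle density (pooled): %s per minute over %s min",
        fmt_num(dens$density), fmt_num(dens$minutes)), "")
    }
  }
  if (!is.null(coupling) && !is.null(catalog)) {
    cmp <- compare_local_simultaneous(catalog, coupling)
    lines <- c(lines, "## Slow-wave coupling", sprintf(
      "- local spindles: n = %d, mean SW peak-to-peak %s",
      cmp$n[cmp$group == "local"], fmt_num(cmp$mean_p2p[cmp$group == "local"])),
      sprintf(
      "- simultaneous spindles: n = %d, mean SW peak-to-peak %s",
      cmp$n[cmp$group == "simultaneous"],
      fmt_num(cmp$mean_p2p[cmp$group == "simultaneous"])), "")
  }
  if (!is.null(cycles)) {
    lines <- c(lines, "## Sleep cycles", sprintf(
      "- %d cycle(s); terminators: %s", nrow(cycles),
      if (nrow(cycles) > 0) paste(cycles$terminator, collapse = ", ")
      else "none"), "")
  }
  if (!is.null(map)) {
    g <- glance.state_space_map(map)
    lev <- contour_levels(g$n_subjects, g$n_cells)
    lines <- c(lines, "## State space", sprintf(
      "- %d-cell map from %d epochs (%d subject(s)); total weight %s",
      g$n_cells, g$n_epochs, g$n_subjects, fmt_num(g$total_weight)),
      sprintf("- contour thresholds: low %s, high %s; %d cell(s) above high",
              fmt_num(lev["low"]), fmt_num(lev["high"]),
              nrow(map_cells_above(map, lev["high"]))), "")
  }
  invisible(structure(lines, class = c("spindle_report", "character")))
}

#' @export
print.spindle_report <- function(x, ...) {
  cat(x, sep = "\n")
  invisible(x)
}
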