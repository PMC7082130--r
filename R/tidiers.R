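# broom-style tidiers for the package's result containers.

#' Tidy and glance methods
#'
#' `tidy()` returns the underlying observations as a plain tibble;
#' `glance()` returns a one-row summary.
#'
#' @param x A package result object.
#' @param ... Unused.
#' @return A tibble.
#' @name ovispindle-tidiers
NULL

#' @rdname ovispindle-tidiers
#' @export
tidy.spindle_events <- function(x, ...) {
  out <- x
  attr(out, "config") <- NULL
  attr(out, "rate") <- NULL
  class(out) <- setdiff(class(out), c("spindle_events", "spindle_catalog"))
  tibble::as_tibble(out)
}

#' @rdname ovispindle-tidiers
#' @export
glance.spindle_events <- function(x, ...) {
  acc <- x[x$accepted, , drop = FALSE]
  tibble::tibble(
    n_events = nrow(x), n_accepted = nrow(acc),
    n_rejected = nrow(x) - nrow(acc),
    n_channels = length(unique(x$channel)),
    mean_freq = if (nrow(acc) > 0) mean(acc$peak_freq) else NA_real_,
    mean_duration = if (nrow(acc) > 0) mean(acc$duration) else NA_real_)
}

#' @rdname ovispindle-tidiers
#' @export
tidy.spindle_catalog <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$partners <- vapply(out$partners, paste, "", collapse = ";")
  out$partner_ids <- NULL
  out
}

#' @rdname ovispindle-tidiers
#' @export
glance.spindle_catalog <- function(x, ...) {
  tibble::tibble(
    n_events = nrow(x), n_local = sum(x$is_local),
    n_simultaneous = sum(!x$is_local),
    n_global = sum(x$multiplicity >= 4L),
    max_multiplicity = if (nrow(x) > 0) max(x$multiplicity) else NA_integer_)
}

#' @rdname ovispindle-tidiers
#' @export
tidy.state_space_map <- function(x, ...) {
  out <- tibble::as_tibble(x)
  unit <- attr(x, "unit") %||% 0.025
  out$ssr1 <- (out$ssr1_bin + 0.5) * unit
  out$ssr2 <- (out$ssr2_bin + 0.5) * unit
  out
}

#' @rdname ovispindle-tidiers
#' @export
glance.state_space_map <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x), total_weight = sum(x$weight),
    occupied_cells = sum(x$weight > 0),
    n_subjects = attr(x, "n_subjects") %||% NA_integer_,
    n_epochs = attr(x, "n_epochs") %||% NA_integer_,
    unit = attr(x, "unit") %||% NA_real_)
}
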