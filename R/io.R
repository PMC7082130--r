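# Recording and hypnogram I/O: delimited text, 16-bit EDF, hypnogram CSV.

#' Read a multichannel recording
#'
#' Delimited text files must be rectangular numeric tables, one column per
#' channel, with a header row of channel labels; comma and tab delimiters
#' are autodetected. Text files carry no rate metadata, so `rate` is
#' mandatory for them. EDF files carry their own rate.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"text"` or `"edf"`.
#' @param rate Sampling rate in Hz; required for text input, ignored for EDF.
#' @param units Scale factor applied to the sample values on read, e.g.
#'   `1e-3` to convert microvolt files to the package's default millivolts.
#' @return A recording tibble (see [as_recording()]).
#' @seealso [write_recording()], [read_hypnogram()]
#' @export
read_recording <- function(path, format = c("auto", "text", "edf"),
                           rate = NULL, units = 1) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "text"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "edf") {
    rec <- read_edf(path)
  } else {
    if (is.null(rate)) {
      stop("text recordings carry no rate metadata; supply `rate`",
           call. = FALSE)
    }
    first <- readLines(path, n = 1L)
    if (length(first) == 0L) stop("empty recording file: ", path, call. = FALSE)
    delim <- if (grepl("\t", first)) "\t" else ","
    tab <- readr::read_delim(path, delim = delim, col_types = readr::cols(
      .default = readr::col_double()), progress = FALSE)
    if (nrow(tab) == 0L) stop("recording file has no samples: ", path,
                              call. = FALSE)
    if (anyNA(tab)) {
      stop("non-numeric or ragged values in recording file: ", path,
           call. = FALSE)
    }
    rec <- as_recording(as.matrix(tab), rate = rate, labels = names(tab))
  }
  if (units != 1) {
    m <- recording_matrix(rec) * units
    rec <- as_recording(m, rate = eeg_rate(rec), labels = channel_names(rec),
                        start_time = rec$time[1L])
  }
  rec
}

#' Write a multichannel recording
#'
#' Text output is a delimited numeric table with a header of channel labels
#' (no time column). EDF output uses 16-bit encoding with per-channel
#' physical scaling over the observed value range; the sampling rate must
#' be a whole number and recordings are padded with zeros to a whole number
#' of 1 s data records.
#'
#' @param rec A recording.
#' @param path Output path.
#' @param format `"auto"` (by extension), `"text"` or `"edf"`.
#' @param delim Delimiter for text output.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("auto", "text", "edf"),
                            delim = ",") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "text"
  }
  if (format == "edf") {
    write_edf(rec, path)
  } else {
    readr::write_delim(tibble::as_tibble(recording_matrix(rec)), path,
                       delim = delim, progress = FALSE)
  }
  invisible(path)
}

# EDF (European Data Format, 16-bit) ---------------------------------------
# Minimal continuous-EDF subset: 1 s data records, identical rate on all
# channels, physical scaling over each channel's observed range.

pad_ascii <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

write_edf <- function(rec, path) {
  rate <- eeg_rate(rec)
  if (abs(rate - round(rate)) > 1e-9) {
    stop("EDF writer requires an integer sampling rate", call. = FALSE)
  }
  rate <- as.integer(round(rate))
  m <- recording_matrix(rec)
  ns <- ncol(m)
  n_rec <- ceiling(nrow(m) / rate)
  if (n_rec * rate > nrow(m)) {
    m <- rbind(m, matrix(0, n_rec * rate - nrow(m), ns))
  }
  pmin <- apply(m, 2L, min)
  pmax <- apply(m, 2L, max)
  flat <- pmax - pmin < .Machine$double.eps
  pmin[flat] <- pmin[flat] - 1
  pmax[flat] <- pmax[flat] + 1
  # widen the physical range outward by a hair, format it to fit the
  # 8-character ASCII header fields, and scale against the values exactly
  # as written, so reader and writer agree
  fmt8 <- function(x) {
    vapply(x, function(v) {
      for (d in 6:1) {
        s <- formatC(v, format = "g", digits = d)
        if (nchar(s) <= 8L) return(s)
      }
      stop("physical range not representable in an EDF header field",
           call. = FALSE)
    }, "")
  }
  span <- pmax - pmin
  margin <- pmax(span * 1e-4, abs(pmin) * 2e-5, abs(pmax) * 2e-5)
  pmin_s <- fmt8(pmin - margin)
  pmax_s <- fmt8(pmax + margin)
  pmin <- as.numeric(pmin_s)
  pmax <- as.numeric(pmax_s)
  dmin <- -32768
  dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_ascii("0", 8L), pad_ascii("synthetic subject", 80L),
    pad_ascii("ovispindle export", 80L), pad_ascii("01.01.00", 8L),
    pad_ascii("00.00.00", 8L), pad_ascii(256L * (ns + 1L), 8L),
    pad_ascii("", 44L), pad_ascii(n_rec, 8L), pad_ascii(1L, 8L),
    pad_ascii(ns, 4L))
  sig <- paste0(
    paste0(pad_ascii(colnames(m), 16L), collapse = ""),
    paste0(pad_ascii(rep("", ns), 80L), collapse = ""),
    paste0(pad_ascii(rep("mV", ns), 8L), collapse = ""),
    paste0(pad_ascii(pmin_s, 8L), collapse = ""),
    paste0(pad_ascii(pmax_s, 8L), collapse = ""),
    paste0(pad_ascii(rep(dmin, ns), 8L), collapse = ""),
    paste0(pad_ascii(rep(dmax, ns), 8L), collapse = ""),
    paste0(pad_ascii(rep("", ns), 80L), collapse = ""),
    paste0(pad_ascii(rep(rate, ns), 8L), collapse = ""),
    paste0(pad_ascii(rep("", ns), 32L), collapse = ""))
  writeChar(paste0(hdr, sig), con, eos = NULL)

  gain <- (dmax - dmin) / (pmax - pmin)
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1L) * rate + 1L):(r * rate)
    for (ch in seq_len(ns)) {
      dig <- round((m[rows, ch] - pmin[ch]) * gain[ch] + dmin)
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2L,
               endian = "little")
    }
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rd(8L); rd(80L); rd(80L); rd(8L); rd(8L)
  rd(8L); rd(44L)
  n_rec <- as.integer(rd(8L))
  rec_dur <- as.numeric(rd(8L))
  ns <- as.integer(rd(4L))
  labels <- vapply(seq_len(ns), function(i) rd(16L), "")
  for (i in seq_len(ns)) rd(80L)
  for (i in seq_len(ns)) rd(8L)
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), ""))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), ""))
  for (i in seq_len(ns)) rd(80L)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8L), ""))
  for (i in seq_len(ns)) rd(32L)
  if (length(unique(spr)) != 1L) {
    stop("EDF reader supports a single common sampling rate only",
         call. = FALSE)
  }
  rate <- spr[1L] / rec_dur
  out <- matrix(0, n_rec * spr[1L], ns, dimnames = list(NULL, labels))
  gain <- (pmax - pmin) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2L, signed = TRUE,
                     endian = "little")
      out[((r - 1L) * spr[ch] + 1L):(r * spr[ch]), ch] <-
        (dig - dmin[ch]) * gain[ch] + pmin[ch]
    }
  }
  as_recording(out, rate = rate, labels = labels)
}

# Hypnograms ----------------------------------------------------------------

#' Build a hypnogram tibble
#'
#' A hypnogram scores consecutive fixed-length epochs with one of the seven
#' vigilance stages (see [stages_all()]) and an artifact flag. Epochs are
#' 1-based: epoch `k` covers `[(k-1) * epoch_len, k * epoch_len)` seconds.
#'
#' @param stages Character vector of per-epoch stage labels.
#' @param artifact Logical vector of artifact flags (recycled).
#' @param epoch_len Epoch length in seconds (default 10).
#' @return A tibble of class `eeg_hypnogram` with columns `epoch`, `stage`,
#'   `artifact`.
#' @examples
#' as_hypnogram(c("W", "W", "S1", "S2", "S2", "R"))
#' @export
as_hypnogram <- function(stages, artifact = FALSE, epoch_len = 10) {
  bad <- setdiff(unique(stages), stages_all())
  if (length(bad) > 0L) {
    stop("unknown stage label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::tibble(
    epoch = seq_along(stages),
    stage = as.character(stages),
    artifact = rep_len(as.logical(artifact), length(stages)))
  attr(out, "epoch_len") <- epoch_len
  class(out) <- c("eeg_hypnogram", class(out))
  out
}

#' @rdname as_hypnogram
#' @param hyp A hypnogram.
#' @export
hypnogram_epoch_len <- function(hyp) attr(hyp, "epoch_len") %||% 10

#' Read or write a hypnogram CSV
#'
#' The on-disk format is `epoch,stage,artifact` with 0/1 artifact flags.
#'
#' @param path File path.
#' @param epoch_len Epoch length in seconds.
#' @return [read_hypnogram()] returns a hypnogram tibble;
#'   [write_hypnogram()] returns `path` invisibly.
#' @export
read_hypnogram <- function(path, epoch_len = 10) {
  tab <- readr::read_csv(path, col_types = readr::cols(
    epoch = readr::col_integer(), stage = readr::col_character(),
    artifact = readr::col_integer()), progress = FALSE)
  tab <- tab[order(tab$epoch), ]
  as_hypnogram(tab$stage, artifact = tab$artifact != 0L,
               epoch_len = epoch_len)
}

#' @rdname read_hypnogram
#' @param hyp A hypnogram tibble.
#' @export
write_hypnogram <- function(hyp, path) {
  out <- tibble::tibble(epoch = hyp$epoch, stage = hyp$stage,
                        artifact = as.integer(hyp$artifact))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
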