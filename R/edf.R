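# Minimal EDF (European Data Format) I/O: fixed-layout ASCII header
# (256 bytes + 256 per signal) followed by data records of 16-bit
# little-endian integers, one record per second here. Covers exactly what
# the pipeline needs -- continuous equal-rate signals with physical
# calibration -- not the full EDF+ annotation standard.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (length(x) != 1 || is.na(x)) x <- ""
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

edf_num <- function(x, width) {
  s <- formatC(x, format = "fg", width = 1, digits = width)
  if (nchar(s) > width) s <- substr(s, 1, width)
  edf_pad(s, width)
}

#' Write an EEG recording to an EDF file
#'
#' Serializes a recording as standard EDF: 16-bit samples, physical units
#' microvolts, one data record per second. The signal is trimmed to a whole
#' number of seconds if necessary (with a message).
#'
#' @param rec An [eeg_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_edf()]
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) {
    abort("EDF writer requires an integer sampling rate.",
          class = "sleepfbn_invalid_argument")
  }
  fs <- as.integer(round(fs))
  x <- rec$signal
  n_rec <- ncol(x) %/% fs
  if (n_rec * fs < ncol(x)) {
    inform(sprintf("write_edf: trimming %d trailing samples to whole seconds.",
                   ncol(x) - n_rec * fs))
    x <- x[, seq_len(n_rec * fs), drop = FALSE]
  }
  ns <- nrow(x)
  pmin <- apply(x, 1, min)
  pmax <- apply(x, 1, max)
  flat <- pmax - pmin < 1e-9
  pmin[flat] <- pmin[flat] - 1
  pmax[flat] <- pmax[flat] + 1
  dmin <- -32768L; dmax <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad(rec$subject_id %||% "X", 80),
    edf_pad(paste0("Startdate 01-JAN-2020 ref ", rec$reference_label), 80),
    edf_pad("01.01.20", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (ns + 1), 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad(1, 8), edf_pad(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)
  fields <- c(
    vapply(rec$channel_labels, function(l) edf_pad(paste("EEG", l), 16), ""),
    rep(edf_pad("", 80), ns),
    rep(edf_pad("uV", 8), ns),
    vapply(pmin, edf_num, "", width = 8),
    vapply(pmax, edf_num, "", width = 8),
    rep(edf_pad(dmin, 8), ns),
    rep(edf_pad(dmax, 8), ns),
    rep(edf_pad("HP:0.3Hz LP:30Hz", 80), ns),
    rep(edf_pad(fs, 8), ns),
    rep(edf_pad("", 32), ns)
  )
  writeChar(paste(fields, collapse = ""), con, eos = NULL)
  scale <- (dmax - dmin) / (pmax - pmin)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    dig <- round((x[, idx, drop = FALSE] - pmin) * scale + dmin)
    writeBin(as.integer(t(dig)), con, size = 2, endian = "little")
  }
  invisible(path)
}

read_edf_header <- function(con) {
  rd <- function(w) {
    out <- readChar(con, w, useBytes = TRUE)
    if (length(out) != 1 || nchar(out) < w) {
      abort("malformed EDF header (truncated).", class = "sleepfbn_format")
    }
    out
  }
  version <- rd(8); patient <- rd(80); recording <- rd(80)
  rd(8); rd(8)  # date, time
  rd(8); rd(44)  # header bytes, reserved
  n_rec <- suppressWarnings(as.integer(rd(8)))
  rec_dur <- suppressWarnings(as.numeric(rd(8)))
  ns <- suppressWarnings(as.integer(rd(4)))
  if (is.na(ns) || ns < 1 || is.na(n_rec) || is.na(rec_dur) || rec_dur <= 0) {
    abort("malformed EDF header.", class = "sleepfbn_format")
  }
  per <- function(w, fn = identity) vapply(seq_len(ns), function(i) fn(rd(w)), fn(""))
  labels <- trimws(per(16))
  per(80); units <- trimws(per(8))
  pmin <- suppressWarnings(as.numeric(per(8)))
  pmax <- suppressWarnings(as.numeric(per(8)))
  dmin <- suppressWarnings(as.numeric(per(8)))
  dmax <- suppressWarnings(as.numeric(per(8)))
  per(80)
  spr <- suppressWarnings(as.integer(per(8)))
  per(32)
  if (any(is.na(c(pmin, pmax, dmin, dmax, spr)))) {
    abort("malformed EDF signal headers.", class = "sleepfbn_format")
  }
  list(patient = trimws(patient), recording = trimws(recording),
       n_rec = n_rec, rec_dur = rec_dur, ns = ns, labels = labels,
       units = units, pmin = pmin, pmax = pmax, dmin = dmin, dmax = dmax,
       spr = spr)
}

#' Read an EDF file as an EEG recording
#'
#' Parses the EDF header and data records, rescales samples to physical
#' units, keeps the requested EEG channels and reorders them to canonical
#' order. Extra channels (for example an ECG recorded alongside) are
#' dropped with a message; a missing required channel is an error naming
#' it. EDF channel labels like `"EEG C3"` match the bare label `"C3"`.
#'
#' @param path Path to an EDF file.
#' @param channels Required channel labels in the order they should appear;
#'   default [fbn_channels()]. `NULL` keeps every channel as stored.
#' @param subject_id,timepoint Provenance identifiers; `subject_id`
#'   defaults to the EDF patient field.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path, channels = fbn_channels(),
                     subject_id = NULL, timepoint = NA_character_) {
  if (!file.exists(path)) {
    abort(sprintf("EDF file not found: %s", path), class = "sleepfbn_format")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  h <- read_edf_header(con)
  if (length(unique(h$spr)) != 1) {
    abort("EDF files with mixed per-signal sampling rates are not supported.",
          class = "sleepfbn_format")
  }
  fs <- h$spr[1] / h$rec_dur
  n_samp <- h$n_rec * h$spr[1]
  x <- matrix(0, h$ns, n_samp)
  for (r in seq_len(h$n_rec)) {
    raw <- readBin(con, integer(), n = h$ns * h$spr[1], size = 2,
                   endian = "little")
    if (length(raw) < h$ns * h$spr[1]) {
      abort("EDF data records truncated.", class = "sleepfbn_format")
    }
    x[, ((r - 1) * h$spr[1] + 1):(r * h$spr[1])] <-
      matrix(raw, h$ns, h$spr[1], byrow = TRUE)
  }
  gain <- (h$pmax - h$pmin) / (h$dmax - h$dmin)
  x <- (x - h$dmin) * gain + h$pmin
  bare <- sub("^EEG[ .]*", "", h$labels)
  if (!is.null(channels)) {
    missing <- setdiff(channels, bare)
    if (length(missing) > 0) {
      abort(paste0("required channel(s) missing from EDF: ",
                   paste(missing, collapse = ", ")),
            class = "sleepfbn_channel_missing")
    }
    dropped <- setdiff(bare, channels)
    if (length(dropped) > 0) {
      inform(paste0("read_edf: dropping non-EEG/extra channel(s): ",
                    paste(dropped, collapse = ", ")))
    }
    keep <- match(channels, bare)
    x <- x[keep, , drop = FALSE]
    bare <- channels
  }
  eeg_recording(x, fs = fs, channel_labels = bare,
                reference_label = "Cz",
                subject_id = subject_id %||% h$patient,
                timepoint = timepoint)
}
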