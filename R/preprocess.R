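#' EEG recording container
#'
#' A continuous multichannel recording: a `channels x samples` signal matrix
#' in microvolts plus montage and sampling metadata. Channel order is fixed
#' at construction and preserved through the pipeline.
#'
#' @param signal Numeric matrix, channels in rows, samples in columns; all
#'   values finite.
#' @param fs Sampling rate in Hz (> 0).
#' @param channel_labels Unique channel names, one per row of `signal`.
#' @param reference_label Name of the reference electrode (default "Cz").
#' @param subject_id,timepoint Provenance identifiers.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(signal, fs, channel_labels,
                          reference_label = "Cz",
                          subject_id = NA_character_,
                          timepoint = NA_character_) {
  signal <- as.matrix(signal)
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    abort("`fs` must be a single positive number.", class = "sleepfbn_invalid_argument")
  }
  if (ncol(signal) < 1) {
    abort("`signal` must contain at least one sample.",
          class = "sleepfbn_invalid_argument")
  }
  if (any(!is.finite(signal))) {
    abort("`signal` must be finite everywhere.", class = "sleepfbn_invalid_argument")
  }
  if (length(channel_labels) != nrow(signal) || anyDuplicated(channel_labels)) {
    abort("`channel_labels` must be unique, one per signal row.",
          class = "sleepfbn_invalid_argument")
  }
  rownames(signal) <- channel_labels
  structure(
    list(signal = signal, fs = fs, channel_labels = as.character(channel_labels),
         reference_label = reference_label, subject_id = subject_id,
         timepoint = timepoint),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> ", nrow(x$signal), " channels x ", ncol(x$signal),
      " samples @ ", x$fs, " Hz (", round(ncol(x$signal) / x$fs, 1), " s), ref ",
      x$reference_label, "\n  channels: ", paste(x$channel_labels, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Zero-phase band-pass filter an EEG recording
#'
#' Applies two cascaded 4th-order Butterworth sections (a 0.30 Hz high-pass
#' and a 30 Hz low-pass by default, the clinical sleep-EEG analysis band)
#' forward and backward with `signal::filtfilt`, giving zero phase
#' distortion -- phase shifts would bias the downstream Pearson-correlation
#' edge weights. Each channel is demeaned first; DC is removed by the
#' high-pass. Residual start-up transients are confined to the recording
#' edges, well away from the analysis segments.
#'
#' @param rec An [eeg_recording()].
#' @param low,high Corner frequencies in Hz, `0 < low < high < fs/2`.
#' @param order Order of each Butterworth section (default 4).
#' @return The filtered [eeg_recording()], same shape and metadata.
#' @export
bandpass_filter <- function(rec, low = 0.30, high = 30, order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$fs / 2
  if (!(low > 0 && low < high && high < nyq)) {
    abort(sprintf("invalid band: need 0 < low < high < fs/2 = %g Hz.", nyq),
          class = "sleepfbn_invalid_band")
  }
  hp <- signal::butter(order, low / nyq, type = "high")
  lp <- signal::butter(order, high / nyq, type = "low")
  filt <- rec$signal
  for (i in seq_len(nrow(filt))) {
    x <- filt[i, ] - mean(filt[i, ])
    filt[i, ] <- signal::filtfilt(lp, signal::filtfilt(hp, x))
  }
  out <- rec
  out$signal <- filt
  out
}

#' Segment set container
#'
#' The non-overlapping analysis windows extracted from one recording:
#' by default ten 15-s windows, i.e. 1920 samples each at 128 Hz.
#'
#' @param segments List of `channels x samples` matrices.
#' @param fs Sampling rate in Hz.
#' @param starts Integer vector of 0-based start offsets (samples) of each
#'   segment in the source recording.
#' @param channel_labels Channel names shared by all segments.
#' @param subject_id,timepoint Provenance identifiers.
#' @return An object of class `segment_set`.
#' @export
segment_set <- function(segments, fs, starts, channel_labels,
                        subject_id = NA_character_, timepoint = NA_character_) {
  len <- unique(vapply(segments, ncol, integer(1)))
  stopifnot(length(len) == 1, length(starts) == length(segments))
  structure(
    list(segments = segments, n_segments = length(segments),
         segment_duration = len / fs, fs = fs, starts = as.integer(starts),
         channel_labels = channel_labels, subject_id = subject_id,
         timepoint = timepoint),
    class = "segment_set"
  )
}

#' @export
print.segment_set <- function(x, ...) {
  cat("<segment_set> ", x$n_segments, " segments x ", x$segment_duration,
      " s (", x$segment_duration * x$fs, " samples) @ ", x$fs, " Hz\n", sep = "")
  invisible(x)
}

#' Extract non-overlapping analysis segments
#'
#' Cuts `n` non-overlapping windows of `dur` seconds from a recording,
#' either tiled from the start (`strategy = "sequential"`) or at seeded
#' random non-overlapping positions (`strategy = "random"`), emulating a
#' technician's manual selection of sleep epochs. Sleep staging itself is
#' outside the pipeline: windows are taken from the supplied recording
#' wherever the strategy places them.
#'
#' @param rec An [eeg_recording()].
#' @param n Number of segments (default 10).
#' @param dur Segment duration in seconds (default 15).
#' @param strategy `"sequential"` or `"random"`.
#' @param seed Seed for the random strategy (ignored for sequential).
#' @return A [segment_set()] whose `starts` field records the 0-based start
#'   sample of each segment, in temporal order.
#' @export
extract_segments <- function(rec, n = 10, dur = 15,
                             strategy = c("sequential", "random"),
                             seed = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  strategy <- match.arg(strategy)
  seg_len <- round(dur * rec$fs)
  total <- ncol(rec$signal)
  need <- n * seg_len
  if (total < need) {
    abort(sprintf(
      "insufficient data: %d segments x %g s need %d samples, recording has %d.",
      n, dur, need, total), class = "sleepfbn_insufficient_data")
  }
  starts <- if (strategy == "sequential") {
    seg_len * (seq_len(n) - 1)
  } else {
    slack <- total - need
    offsets <- with_seed_if(seed, sort(sample.int(slack + 1, n, replace = TRUE) - 1))
    offsets + seg_len * (seq_len(n) - 1)
  }
  segs <- lapply(starts, function(s) rec$signal[, (s + 1):(s + seg_len), drop = FALSE])
  segment_set(segs, fs = rec$fs, starts = starts,
              channel_labels = rec$channel_labels,
              subject_id = rec$subject_id, timepoint = rec$timepoint)
}
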