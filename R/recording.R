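#' Construct an EEG recording object
#'
#' Container for a multichannel scalp EEG recording: a channels x samples
#' signal matrix in microvolts, the sampling rate, the electrode layout and
#' any artifact annotations (onset/duration in seconds from recording
#' start).
#'
#' @param signal Numeric matrix, channels in rows, samples in columns.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param layout A [channel_layout()]; its labels must match `nrow(signal)`.
#' @param annotations A data.frame with columns `onset`, `duration`,
#'   `label`, or `NULL` for none.
#' @param passband Optional length-2 numeric `(hp, lp)` in Hz recording the
#'   band-pass applied during preprocessing.
#' @param subject_id,group_label Optional subject metadata carried through
#'   the pipeline (`group_label` is `"delirium"` or `"control"`).
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(signal, sampling_rate, layout = channel_layout(),
                          annotations = NULL, passband = NULL,
                          subject_id = NA_character_,
                          group_label = NA_character_) {
  signal <- as.matrix(signal)
  if (!is.numeric(signal)) stop("signal must be numeric")
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  if (nrow(signal) != length(layout$labels))
    stop("signal rows (", nrow(signal), ") do not match layout labels (",
         length(layout$labels), ")")
  rownames(signal) <- layout$labels
  annotations <- validate_annotations(annotations)
  if (!is.null(passband)) {
    if (passband[1] >= passband[2]) stop("passband must satisfy hp < lp")
    if (passband[2] >= sampling_rate / 2)
      stop("low-pass corner must lie below the Nyquist frequency")
  }
  structure(list(signal = signal, sampling_rate = sampling_rate,
                 layout = layout, annotations = annotations,
                 passband = passband, subject_id = subject_id,
                 group_label = group_label),
            class = "eeg_recording")
}

validate_annotations <- function(annotations) {
  if (is.null(annotations) || nrow(as.data.frame(annotations)) == 0L)
    return(data.frame(onset = numeric(0), duration = numeric(0),
                      label = character(0), stringsAsFactors = FALSE))
  annotations <- as.data.frame(annotations, stringsAsFactors = FALSE)
  stopifnot(all(c("onset", "duration", "label") %in% names(annotations)))
  if (any(annotations$onset < 0)) stop("annotation onsets must be >= 0")
  if (any(annotations$duration <= 0)) stop("annotation durations must be > 0")
  annotations$label <- as.character(annotations$label)
  annotations[order(annotations$onset), , drop = FALSE]
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> ", nrow(x$signal), " channels x ",
      ncol(x$signal), " samples @ ", x$sampling_rate, " Hz (",
      round(ncol(x$signal) / x$sampling_rate, 2), " s)\n", sep = "")
  if (!is.na(x$subject_id))
    cat("  subject: ", x$subject_id, " [", x$group_label, "]\n", sep = "")
  if (!is.null(x$passband))
    cat("  passband: ", x$passband[1], "-", x$passband[2], " Hz\n", sep = "")
  if (nrow(x$annotations) > 0L)
    cat("  annotations: ", nrow(x$annotations), " artifact span(s)\n", sep = "")
  invisible(x)
}

#' Duration of a recording in seconds
#' @param x An `eeg_recording`.
#' @return Length in seconds.
#' @export
recording_duration <- function(x) ncol(x$signal) / x$sampling_rate

#' Band-pass filter and down-sample a recording
#'
#' Zero-phase (forward-backward) Butterworth band-pass followed by integer
#' stride decimation, reproducing a typical acquisition chain: high pass
#' 0.16 Hz, low pass 52 Hz, output rate 256 Hz. Filtering is applied as a
#' second-order high-pass and a fourth-order low-pass cascade (each run
#' forward and backward, doubling the effective order) which is numerically
#' robust for sub-Hz corners at kHz sampling rates. Because the low-pass
#' corner sits well below the output Nyquist frequency, plain stride
#' decimation after filtering introduces no aliasing.
#'
#' @param raw An [eeg_recording()].
#' @param hp High-pass corner in Hz.
#' @param lp Low-pass corner in Hz; must be below `fs_out / 2`.
#' @param fs_out Output sampling rate in Hz; must divide the input rate.
#' @return A filtered, decimated `eeg_recording` with `passband` set.
#'   Annotations, already in seconds, are unchanged.
#' @export
preprocess <- function(raw, hp = 0.16, lp = 52, fs_out = 256) {
  stopifnot(inherits(raw, "eeg_recording"))
  fs_in <- raw$sampling_rate
  if (lp >= fs_out / 2)
    stop("aliasing risk: low-pass corner ", lp,
         " Hz is not below the output Nyquist frequency ", fs_out / 2, " Hz")
  if (abs(fs_in / fs_out - round(fs_in / fs_out)) > 1e-9)
    stop("fs_out = ", fs_out, " Hz is not an integer divisor of the input rate ",
         fs_in, " Hz")
  stride <- as.integer(round(fs_in / fs_out))
  but_hp <- signal::butter(2, hp / (fs_in / 2), type = "high")
  but_lp <- signal::butter(4, lp / (fs_in / 2), type = "low")
  filt <- t(apply(raw$signal, 1L, function(x) {
    y <- signal::filtfilt(but_hp, x)
    signal::filtfilt(but_lp, y)
  }))
  idx <- seq(1L, ncol(filt), by = stride)
  out <- raw
  out$signal <- filt[, idx, drop = FALSE]
  out$sampling_rate <- fs_out
  out$passband <- c(hp, lp)
  out
}

#' Construct a single analysis epoch
#'
#' @param signal Channels x samples numeric matrix (microvolts).
#' @param sampling_rate Hz.
#' @param start Onset in seconds from recording start.
#' @param subject_id,group_label Subject metadata.
#' @param channels Channel labels (row names).
#' @return Object of class `eeg_epoch`.
#' @export
eeg_epoch <- function(signal, sampling_rate, start = 0,
                      subject_id = NA_character_,
                      group_label = NA_character_,
                      channels = rownames(signal)) {
  signal <- as.matrix(signal)
  if (is.null(channels)) channels <- paste0("ch", seq_len(nrow(signal)))
  rownames(signal) <- channels
  structure(list(signal = signal, sampling_rate = sampling_rate,
                 start = start, duration = ncol(signal) / sampling_rate,
                 subject_id = subject_id, group_label = group_label),
            class = "eeg_epoch")
}

#' @export
print.eeg_epoch <- function(x, ...) {
  cat("<eeg_epoch> ", nrow(x$signal), " channels, ", x$duration,
      " s @ ", x$sampling_rate, " Hz, start ", x$start, " s", sep = "")
  if (!is.na(x$subject_id))
    cat(" [", x$subject_id, "/", x$group_label, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Select artifact-free analysis epochs from a recording
#'
#' Greedy earliest-first placement of `n` non-overlapping epochs of
#' `duration` seconds, none of which intersects any artifact annotation.
#' Deterministic: no seed is involved, so repeated runs of a study select
#' identical data.
#'
#' @param rec A preprocessed [eeg_recording()].
#' @param n Number of epochs required (default 3).
#' @param duration Epoch length in seconds (default 60).
#' @return List of `n` [eeg_epoch()] objects.
#' @export
select_epochs <- function(rec, n = 3, duration = 60) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sampling_rate
  total <- recording_duration(rec)
  ann <- rec$annotations
  epochs <- list()
  t0 <- 0
  while (length(epochs) < n && t0 + duration <= total + 1e-9) {
    hit <- which(ann$onset < t0 + duration & ann$onset + ann$duration > t0)
    if (length(hit) == 0L) {
      i0 <- round(t0 * fs) + 1L
      seg <- rec$signal[, i0:(i0 + duration * fs - 1L), drop = FALSE]
      epochs[[length(epochs) + 1L]] <-
        eeg_epoch(seg, fs, start = t0, subject_id = rec$subject_id,
                  group_label = rec$group_label)
      t0 <- t0 + duration
    } else {
      # jump just past the artifact that blocked this window
      t0 <- max(ann$onset[hit] + ann$duration[hit])
    }
  }
  if (length(epochs) < n)
    stop("insufficient clean data: found ", length(epochs),
         " artifact-free ", duration, " s window(s), need ", n)
  epochs
}
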