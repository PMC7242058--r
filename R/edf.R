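# Minimal EDF (16-bit) / BDF (24-bit) interchange support.
#
# Implements exactly the subset of the European Data Format needed to move
# multichannel microvolt EEG between tools: a single fixed-rate signal
# group, 1-second data records, physical calibration per channel.
# Artifact annotations travel in a sidecar tab-separated file
# (<stem>.annotations.tsv: onset, duration, label; seconds, UTF-8).

EDF_HEADER_FIXED <- 256L

annotation_sidecar_path <- function(path)
  paste0(tools::file_path_sans_ext(path), ".annotations.tsv")

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = -width)
}

# 8-char ascii numeric field; EDF requires plain decimal notation
num_field <- function(x) {
  s <- formatC(x, format = "fg", width = 1, digits = 7)
  if (nchar(s) > 8L) s <- substr(s, 1L, 8L)
  pad_field(s, 8L)
}

#' Write a recording to an EDF or BDF file
#'
#' Emits a minimal standards-conforming file: 1-second data records,
#' per-channel physical calibration spanning the channel's data range
#' (so quantization error is at most half of range / 2^16 for EDF,
#' range / 2^24 for BDF). Any annotations are written to the sidecar file
#' `<stem>.annotations.tsv`.
#'
#' @param rec An [eeg_recording()]; its duration must be a whole number of
#'   seconds and its sampling rate an integer.
#' @param path Output file path.
#' @param format `"edf"` (16-bit) or `"bdf"` (24-bit).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("edf", "bdf")) {
  format <- match.arg(format)
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sampling_rate
  if (abs(fs - round(fs)) > 1e-9) stop("sampling rate must be an integer")
  fs <- as.integer(round(fs))
  nsamp <- ncol(rec$signal)
  if (nsamp %% fs != 0L)
    stop("recording length must be a whole number of seconds")
  n_rec <- nsamp %/% fs
  ns <- nrow(rec$signal)
  dig_max <- if (format == "edf") 32767 else 8388607
  dig_min <- -dig_max - 1

  phys_min <- phys_max <- numeric(ns)
  for (i in seq_len(ns)) {
    lo <- floor(min(rec$signal[i, ]))
    hi <- ceiling(max(rec$signal[i, ]))
    if (hi <= lo) hi <- lo + 1
    phys_min[i] <- lo; phys_max[i] <- hi
  }
  gain <- (phys_max - phys_min) / (dig_max - dig_min)

  con <- file(path, "wb")
  on.exit(close(con))
  version <- if (format == "edf") pad_field("0", 8L) else "BIOSEMI"
  if (format == "bdf") writeBin(as.raw(255L), con)
  writeChar(version, con, nchars = if (format == "edf") 8L else 7L,
            eos = NULL)
  subj <- if (is.na(rec$subject_id)) "" else rec$subject_id
  writeChar(pad_field(subj, 80L), con, 80L, eos = NULL)
  writeChar(pad_field("deleeg recording", 80L), con, 80L, eos = NULL)
  writeChar("01.01.00", con, 8L, eos = NULL)
  writeChar("00.00.00", con, 8L, eos = NULL)
  writeChar(num_field(EDF_HEADER_FIXED + 256L * ns), con, 8L, eos = NULL)
  reserved <- if (format == "bdf") "24BIT" else ""
  writeChar(pad_field(reserved, 44L), con, 44L, eos = NULL)
  writeChar(num_field(n_rec), con, 8L, eos = NULL)
  writeChar(num_field(1), con, 8L, eos = NULL)
  writeChar(pad_field(ns, 4L), con, 4L, eos = NULL)
  for (lab in rec$layout$labels)
    writeChar(pad_field(lab, 16L), con, 16L, eos = NULL)
  for (i in seq_len(ns)) writeChar(pad_field("AgAgCl electrode", 80L), con, 80L, eos = NULL)
  for (i in seq_len(ns)) writeChar(pad_field("uV", 8L), con, 8L, eos = NULL)
  for (i in seq_len(ns)) writeChar(num_field(phys_min[i]), con, 8L, eos = NULL)
  for (i in seq_len(ns)) writeChar(num_field(phys_max[i]), con, 8L, eos = NULL)
  for (i in seq_len(ns)) writeChar(num_field(dig_min), con, 8L, eos = NULL)
  for (i in seq_len(ns)) writeChar(num_field(dig_max), con, 8L, eos = NULL)
  pre <- if (is.null(rec$passband)) "" else
    sprintf("HP:%gHz LP:%gHz", rec$passband[1], rec$passband[2])
  for (i in seq_len(ns)) writeChar(pad_field(pre, 80L), con, 80L, eos = NULL)
  for (i in seq_len(ns)) writeChar(num_field(fs), con, 8L, eos = NULL)
  for (i in seq_len(ns)) writeChar(pad_field("", 32L), con, 32L, eos = NULL)

  # digitize once, then interleave record-major / signal-major
  dig <- matrix(0L, ns, nsamp)
  for (i in seq_len(ns)) {
    d <- round((rec$signal[i, ] - phys_min[i]) / gain[i]) + dig_min
    dig[i, ] <- as.integer(pmin(pmax(d, dig_min), dig_max))
  }
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    block <- t(dig[, cols, drop = FALSE])  # samples x signals
    v <- as.vector(block)
    if (format == "edf") {
      writeBin(v, con, size = 2L, endian = "little")
    } else {
      u <- ifelse(v < 0L, v + 16777216L, v)  # two's complement, 24-bit
      b <- rbind(u %% 256L, (u %/% 256L) %% 256L, u %/% 65536L)
      writeBin(as.raw(b), con)
    }
  }
  if (nrow(rec$annotations) > 0L)
    utils::write.table(rec$annotations, annotation_sidecar_path(path),
                       sep = "\t", row.names = FALSE, quote = FALSE,
                       fileEncoding = "UTF-8")
  invisible(path)
}

read_ascii <- function(con, n) trimws(readChar(con, n, useBytes = TRUE))

#' Read an EDF or BDF recording
#'
#' Reads the subset of EDF/BDF written by [write_recording()]: all signals
#' must share one sampling rate. Amplitudes are returned in the file's
#' physical units (microvolts by this package's convention). If a sidecar
#' annotation file `<stem>.annotations.tsv` exists its spans are attached.
#'
#' @param path File path.
#' @param format `"edf"` or `"bdf"`; defaults to the file extension.
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path, format = c("auto", "edf", "bdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.bdf$", path, ignore.case = TRUE)) "bdf" else "edf"
  fsize <- file.info(path)$size
  if (fsize < EDF_HEADER_FIXED) stop("format error: file too short for an ",
                                     toupper(format), " header")
  con <- file(path, "rb")
  on.exit(close(con))
  if (format == "bdf") {
    magic <- readBin(con, "raw", 1L)
    ver <- readChar(con, 7L, useBytes = TRUE)
    if (magic != as.raw(255L) || ver != "BIOSEMI")
      stop("format error: not a BDF file")
  } else {
    ver <- read_ascii(con, 8L)
    if (ver != "0") stop("format error: not an EDF file")
  }
  subject <- read_ascii(con, 80L)
  read_ascii(con, 80L); read_ascii(con, 8L); read_ascii(con, 8L)
  hdr_bytes <- as.integer(read_ascii(con, 8L))
  read_ascii(con, 44L)
  n_rec <- as.integer(read_ascii(con, 8L))
  rec_dur <- as.numeric(read_ascii(con, 8L))
  ns <- as.integer(read_ascii(con, 4L))
  if (is.na(ns) || ns < 1L) stop("format error: file declares no signals")
  if (is.na(n_rec) || n_rec < 0L)
    stop("format error: unknown record count")
  labels <- vapply(seq_len(ns), function(i) read_ascii(con, 16L), "")
  for (i in seq_len(ns)) read_ascii(con, 80L)   # transducer
  for (i in seq_len(ns)) read_ascii(con, 8L)    # physical dimension
  phys_min <- vapply(seq_len(ns), function(i) as.numeric(read_ascii(con, 8L)), 0)
  phys_max <- vapply(seq_len(ns), function(i) as.numeric(read_ascii(con, 8L)), 0)
  dig_min <- vapply(seq_len(ns), function(i) as.numeric(read_ascii(con, 8L)), 0)
  dig_max <- vapply(seq_len(ns), function(i) as.numeric(read_ascii(con, 8L)), 0)
  for (i in seq_len(ns)) read_ascii(con, 80L)   # prefilter
  spr <- vapply(seq_len(ns), function(i) as.integer(read_ascii(con, 8L)), 0L)
  for (i in seq_len(ns)) read_ascii(con, 32L)
  if (length(unique(spr)) != 1L)
    stop("mixed per-signal sampling rates are not supported")
  bps <- if (format == "edf") 2L else 3L
  expected <- hdr_bytes + as.numeric(n_rec) * sum(spr) * bps
  if (fsize < expected)
    stop("format error: file truncated (", fsize, " bytes, expected ",
         expected, ")")
  fs <- spr[1L] / rec_dur
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  sigmat <- matrix(0, ns, n_rec * spr[1L])
  for (r in seq_len(n_rec)) {
    if (format == "edf") {
      v <- readBin(con, "integer", n = sum(spr), size = 2L, signed = TRUE,
                   endian = "little")
    } else {
      b <- as.integer(readBin(con, "raw", n = sum(spr) * 3L))
      u <- b[c(TRUE, FALSE, FALSE)] + 256L * b[c(FALSE, TRUE, FALSE)] +
        65536L * b[c(FALSE, FALSE, TRUE)]
      v <- u - ifelse(u >= 8388608L, 16777216L, 0L)
    }
    block <- matrix(v, nrow = spr[1L])  # samples x signals
    cols <- ((r - 1L) * spr[1L] + 1L):(r * spr[1L])
    sigmat[, cols] <- t(block * rep(gain, each = spr[1L]) +
                          rep(phys_min - dig_min * gain, each = spr[1L]))
  }
  ann <- NULL
  sp <- annotation_sidecar_path(path)
  if (file.exists(sp))
    ann <- utils::read.table(sp, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  eeg_recording(sigmat, fs, channel_layout(labels),
                annotations = ann,
                subject_id = if (nzchar(subject)) subject else NA_character_)
}
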