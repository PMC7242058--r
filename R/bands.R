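#' Standard 8-channel 10-20 scalp layout
#'
#' The default montage: bilateral frontal (F3, F4), central (C3, C4),
#' parietal (P3, P4) and temporal (T7, T8) electrodes, referenced to a
#' common-mode sense electrode at C2.
#'
#' @param labels Character vector of unique, non-empty electrode names.
#' @param reference_label Name of the reference electrode.
#' @return An object of class `channel_layout`.
#' @export
#' @examples
#' channel_layout()
channel_layout <- function(labels = c("F3", "F4", "C3", "C4",
                                      "P3", "P4", "T7", "T8"),
                           reference_label = "C2") {
  labels <- as.character(labels)
  if (length(labels) < 1L || anyDuplicated(labels) || any(!nzchar(labels)))
    stop("channel labels must be unique and non-empty")
  structure(list(labels = labels, reference_label = reference_label),
            class = "channel_layout")
}

#' @export
print.channel_layout <- function(x, ...) {
  cat("<channel_layout> ", paste(x$labels, collapse = ", "),
      " (ref ", x$reference_label, ")\n", sep = "")
  invisible(x)
}

#' The analysis frequency grid
#'
#' Fixed grid from 0.5 to 45 Hz in 0.5 Hz steps (90 points), shared by all
#' spectral and connectivity estimates in a study.
#'
#' @return Numeric vector of frequencies in Hz.
#' @export
frequency_grid <- function() seq(0.5, 45, by = 0.5)

#' EEG frequency band definitions with split normalization ranges
#'
#' Classical bands on the analysis grid: Delta `[0.5, 4)`, Theta `[4, 8)`,
#' Alpha `[8, 13)`, Beta `[13, 20)` and Gamma `[20, 45]` Hz. Because Delta
#' carries roughly 80% of total signal energy and movement artifacts bleed
#' into the Delta range, relative Delta power is normalized against the
#' whole 0.5-45 Hz range while Theta through Gamma are normalized against
#' 4-45 Hz. Bands are half-open `[lo, hi)` except Gamma, closed at 45 Hz,
#' so each normalization family tiles its range with no double counting.
#'
#' @return A data.frame with one row per band: `band`, `lo`, `hi`,
#'   `hi_inclusive`, `norm_lo`, `norm_hi`.
#' @export
#' @examples
#' eeg_bands()
eeg_bands <- function() {
  data.frame(
    band = c("Delta", "Theta", "Alpha", "Beta", "Gamma"),
    lo   = c(0.5, 4, 8, 13, 20),
    hi   = c(4, 8, 13, 20, 45),
    hi_inclusive = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    norm_lo = c(0.5, 4, 4, 4, 4),
    norm_hi = c(45, 45, 45, 45, 45),
    stringsAsFactors = FALSE
  )
}

# indices of grid points belonging to [lo, hi) (or [lo, hi] when inclusive)
band_index <- function(grid, lo, hi, hi_inclusive = FALSE) {
  if (hi_inclusive) which(grid >= lo & grid <= hi)
  else which(grid >= lo & grid < hi)
}
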