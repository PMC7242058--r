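#' Fit a univariate autoregressive model by the Burg recursion
#'
#' High-order AR modelling is the spectral workhorse of this package: at
#' order `sampling_rate / 4` (64 at 256 Hz) it resolves narrowband EEG
#' rhythms from single 60-second epochs with a much better signal-to-noise
#' ratio than FFT periodograms. Fitting uses the Burg (maximum entropy)
#' recursion, which is standard for high-order AR on short epochs and
#' yields a stable model by construction; stability is nevertheless
#' asserted after the fit.
#'
#' @param x Numeric vector, one channel of one epoch (microvolts).
#' @param sampling_rate Sampling rate in Hz.
#' @param order AR order; defaults to `sampling_rate / 4` (the order rule,
#'   re-evaluated if the rate differs from 256 Hz).
#' @return An object of class `ar_model`: `order`, `coef` (a_1..a_p),
#'   `innovation_variance` (microvolts^2), `sampling_rate`.
#' @seealso [ar_spectrum()] for the implied power spectral density.
#' @export
#' @examples
#' set.seed(1)
#' x <- as.numeric(arima.sim(list(ar = 0.5), 2560))
#' fit_ar(x, sampling_rate = 256, order = 1)
fit_ar <- function(x, sampling_rate, order = round(sampling_rate / 4)) {
  x <- as.numeric(x)
  order <- as.integer(order)
  if (order < 1L) stop("order must be >= 1")
  if (length(x) < 10L * order)
    stop("signal too short: need at least 10 x order = ", 10L * order,
         " samples, got ", length(x))
  if (stats::var(x) == 0)
    stop("degenerate signal: zero variance, cannot fit an AR model")
  fit <- stats::ar.burg(x, aic = FALSE, order.max = order, demean = TRUE)
  a <- as.numeric(fit$ar)
  # Burg is stable iff all reflection coefficients lie inside (-1, 1);
  # this is exact and, unlike polynomial root finding, well conditioned
  # at order 64
  refl <- as.numeric(fit$partialacf)
  if (!all(is.finite(a)) || any(abs(refl) >= 1) ||
      !is.finite(fit$var.pred) || fit$var.pred <= 0)
    stop("numerical failure: fitted AR model is unstable")
  structure(list(order = order, coef = a,
                 innovation_variance = as.numeric(fit$var.pred),
                 sampling_rate = sampling_rate),
            class = "ar_model")
}

#' @export
print.ar_model <- function(x, digits = 4, ...) {
  cat("<ar_model> order ", x$order, " @ ", x$sampling_rate,
      " Hz, innovation variance ",
      format(x$innovation_variance, digits = digits), "\n", sep = "")
  if (x$order <= 8L)
    cat("  coefficients:", format(x$coef, digits = digits), "\n")
  invisible(x)
}

#' Construct an AR model from known coefficients
#'
#' For analytically specified processes (resonators, white noise) used as
#' oracles and simulators.
#'
#' @param coef AR coefficients a_1..a_p.
#' @param innovation_variance Driving noise variance (> 0).
#' @param sampling_rate Hz.
#' @return An `ar_model`.
#' @export
ar_model <- function(coef, innovation_variance = 1, sampling_rate = 256) {
  stopifnot(innovation_variance > 0)
  structure(list(order = length(coef), coef = as.numeric(coef),
                 innovation_variance = innovation_variance,
                 sampling_rate = sampling_rate),
            class = "ar_model")
}

#' AR power spectral density on the analysis grid
#'
#' Evaluates S(f) = sigma^2 * dt / |1 - sum_k a_k exp(-i 2 pi f k dt)|^2
#' with dt = 1 / sampling_rate, at each grid frequency.
#'
#' @param model An [ar_model()] (fitted or analytic).
#' @param grid Frequencies in Hz, strictly inside (0, sampling_rate / 2).
#'   Defaults to [frequency_grid()].
#' @param channel,subject_id Metadata attached to the spectrum.
#' @return A `power_spectrum`: list with `freq` (Hz), `power`
#'   (microvolts^2/Hz), `channel`, `subject_id`.
#' @export
ar_spectrum <- function(model, grid = frequency_grid(),
                        channel = NA_character_,
                        subject_id = NA_character_) {
  stopifnot(inherits(model, "ar_model"))
  if (any(grid <= 0) || any(grid >= model$sampling_rate / 2))
    stop("grid must lie strictly inside (0, sampling_rate/2)")
  dt <- 1 / model$sampling_rate
  k <- seq_len(model$order)
  H <- vapply(grid, function(f)
    abs(1 - sum(model$coef * exp(-2i * pi * f * k * dt)))^2, 0)
  power_spectrum(grid, model$innovation_variance * dt / H,
                 channel = channel, subject_id = subject_id)
}

#' Construct a power spectrum object
#' @param freq Frequency grid in Hz.
#' @param power Nonnegative power density values (microvolts^2/Hz).
#' @param channel,subject_id Metadata.
#' @return A `power_spectrum`.
#' @export
power_spectrum <- function(freq, power, channel = NA_character_,
                           subject_id = NA_character_) {
  stopifnot(length(freq) == length(power))
  if (any(power < 0)) stop("power must be nonnegative")
  structure(list(freq = as.numeric(freq), power = as.numeric(power),
                 channel = channel, subject_id = subject_id),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat("<power_spectrum> ", length(x$freq), " points, ",
      min(x$freq), "-", max(x$freq), " Hz", sep = "")
  if (!is.na(x$channel)) cat(", channel ", x$channel, sep = "")
  if (!is.na(x$subject_id)) cat(", subject ", x$subject_id, sep = "")
  cat("\n  peak ", format(max(x$power), digits = 4), " uV^2/Hz at ",
      x$freq[which.max(x$power)], " Hz\n", sep = "")
  invisible(x)
}

#' @export
plot.power_spectrum <- function(x, log = "y", xlab = "Frequency [Hz]",
                                ylab = expression(Power ~ (mu * V^2 / Hz)),
                                type = "l", ...) {
  graphics::plot(x$freq, x$power, log = log, xlab = xlab, ylab = ylab,
                 type = type, ...)
  invisible(x)
}

#' Average spectra across epochs of one subject and channel
#'
#' Pointwise arithmetic mean; all spectra must share one grid. Averaging
#' per-epoch spectra yields the subject-average spectrum that group
#' statistics operate on.
#'
#' @param spectra List of `power_spectrum` objects with identical grids.
#' @return A `power_spectrum` carrying the first spectrum's metadata.
#' @export
average_spectra <- function(spectra) {
  stopifnot(length(spectra) >= 1L)
  g <- spectra[[1L]]$freq
  for (s in spectra)
    if (length(s$freq) != length(g) || any(s$freq != g))
      stop("frequency grid mismatch between spectra")
  p <- rowMeans(vapply(spectra, function(s) s$power, numeric(length(g))))
  power_spectrum(g, p, channel = spectra[[1L]]$channel,
                 subject_id = spectra[[1L]]$subject_id)
}

#' Band powers under the split normalization
#'
#' Absolute band power is the sum of spectral values at grid points inside
#' the band. Relative power uses two normalization families: Delta is
#' expressed as a percentage of summed power over the full 0.5-45 Hz range
#' (Delta alone carries ~80% of signal energy and is the band most
#' contaminated by movement artifacts), while Theta, Alpha, Beta and Gamma
#' are percentages of summed 4-45 Hz power, so their four relative powers
#' always total 100.
#'
#' @param spectrum A `power_spectrum` on a grid covering all bands.
#' @param bands Band definition table as from [eeg_bands()].
#' @return data.frame rows: `subject_id`, `channel`, `band`,
#'   `absolute_power` (microvolts^2), `relative_power` (%).
#' @export
band_power <- function(spectrum, bands = eeg_bands()) {
  g <- spectrum$freq
  out <- vector("list", nrow(bands))
  for (i in seq_len(nrow(bands))) {
    b <- bands[i, ]
    idx <- band_index(g, b$lo, b$hi, b$hi_inclusive)
    if (length(idx) == 0L)
      stop("band ", b$band, " contains no grid points")
    nidx <- which(g >= b$norm_lo & g <= b$norm_hi)
    absolute <- sum(spectrum$power[idx])
    out[[i]] <- data.frame(
      subject_id = spectrum$subject_id, channel = spectrum$channel,
      band = b$band, absolute_power = absolute,
      relative_power = 100 * absolute / sum(spectrum$power[nidx]),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Slow-to-fast frequency power ratio (SFPR)
#'
#' Summed spectral power at all grid frequencies below the split (13 Hz by
#' default; the Alpha/Beta boundary) divided by the summed power from the
#' split up to 45 Hz. EEG slowing — the classic delirium signature — drives
#' this ratio up.
#'
#' @param spectrum A `power_spectrum`.
#' @param split Split frequency in Hz.
#' @return The ratio; `Inf` when the fast-side power is zero.
#' @export
sfpr <- function(spectrum, split = 13) {
  g <- spectrum$freq
  if (!any(g < split) || !any(g >= split))
    stop("spectrum must cover both sides of the split frequency")
  slow <- sum(spectrum$power[g < split])
  fast <- sum(spectrum$power[g >= split & g <= 45])
  if (fast == 0) return(Inf)
  slow / fast
}

#' SFPR over a reduced electrode panel
#'
#' Computes the per-channel SFPR for a named channel set (default C3, P3,
#' T7 — one central, one parietal, one temporal electrode) and their
#' arithmetic mean, the single-number screening readout.
#'
#' @param spectra Named list of `power_spectrum` objects (names or
#'   `$channel` fields identify electrodes).
#' @param channels Channel labels in the panel.
#' @param split SFPR split frequency in Hz.
#' @return Object of class `sfpr_panel`: `per_channel` (named numeric),
#'   `average`, `channels`, `split`.
#' @export
sfpr_panel <- function(spectra, channels = c("C3", "P3", "T7"), split = 13) {
  labs <- names(spectra)
  if (is.null(labs) || any(!nzchar(labs)))
    labs <- vapply(spectra, function(s) s$channel, "")
  missing <- setdiff(channels, labs)
  if (length(missing) > 0L)
    stop("missing channel(s): ", paste(missing, collapse = ", "))
  v <- vapply(channels, function(ch) sfpr(spectra[[match(ch, labs)]], split), 0)
  structure(list(per_channel = v, average = mean(v),
                 channels = channels, split = split),
            class = "sfpr_panel")
}

#' @export
print.sfpr_panel <- function(x, digits = 3, ...) {
  cat("<sfpr_panel> split ", x$split, " Hz\n", sep = "")
  print(round(c(x$per_channel, average = x$average), digits))
  invisible(x)
}

#' Subject-average spectra for every channel of a set of epochs
#'
#' Fits one AR model per channel per epoch, converts to spectra on the
#' analysis grid and averages within channel across epochs.
#'
#' @param epochs List of [eeg_epoch()] objects from one subject.
#' @param order AR order; default the order rule `sampling_rate / 4`.
#' @param grid Frequency grid.
#' @return Named list (by channel) of subject-average `power_spectrum`s.
#' @export
subject_spectra <- function(epochs, order = NULL, grid = frequency_grid()) {
  stopifnot(length(epochs) >= 1L)
  fs <- epochs[[1L]]$sampling_rate
  if (is.null(order)) order <- round(fs / 4)
  chans <- rownames(epochs[[1L]]$signal)
  out <- lapply(chans, function(ch) {
    per_epoch <- lapply(epochs, function(ep)
      ar_spectrum(fit_ar(ep$signal[ch, ], fs, order), grid,
                  channel = ch, subject_id = ep$subject_id))
    average_spectra(per_epoch)
  })
  names(out) <- chans
  out
}
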