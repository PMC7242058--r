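#' Configure the synthetic EEG cohort generator
#'
#' Builds seeded surrogate cohorts with the statistical structure the
#' analysis pipeline assumes: per-band narrowband oscillators (AR(2)
#' resonators, so spectral peaks have realistic width), a 1/f background,
#' a directed lagged coupling graph creating true Granger-causal
#' structure, and annotated high-amplitude slow artifacts. The delirium
#' condition doubles the slow-band (Delta/Theta/Alpha) oscillator
#' amplitudes, scales the fast bands (Beta/Gamma) by 0.4 and attenuates
#' every coupling gain to 0.3 of its control value — the direction and
#' rough magnitude of the group differences the analysis is designed to
#' detect.
#'
#' @param n_subjects Subjects per group.
#' @param epochs_per_subject Analysis epochs per subject.
#' @param epoch_duration Epoch length in seconds.
#' @param sampling_rate Hz.
#' @param layout A [channel_layout()].
#' @param recording_duration Recording length per subject in seconds.
#' @param band_amplitudes Named control-condition oscillator amplitudes
#'   (microvolts) for Delta..Gamma.
#' @param band_centers Named resonator center frequencies (Hz).
#' @param delirium_band_multipliers Named amplitude multipliers applied in
#'   the delirium condition.
#' @param coupling data.frame (`source`, `sink`, `lag`, `gain`); default:
#'   every ordered pair among the left-hemisphere montage channels present
#'   in the layout, gain 0.3, lags cycling 2..5 samples.
#' @param delirium_coupling_attenuation Coupling gain multiplier in the
#'   delirium condition.
#' @param background_exponent 1/f^exponent background slope.
#' @param background_amplitude Background standard deviation (microvolts).
#' @param resonator_radius AR(2) pole radius (bandwidth control).
#' @param artifact_rate Expected artifacts per minute (Poisson).
#' @param artifact_amplitude Artifact peak amplitude (microvolts).
#' @param artifact_duration Artifact span in seconds.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 5, epochs_per_subject = 3,
                       epoch_duration = 60, sampling_rate = 256,
                       layout = channel_layout(),
                       recording_duration = 600,
                       band_amplitudes = c(Delta = 8, Theta = 2,
                                           Alpha = 2.5, Beta = 2,
                                           Gamma = 1.2),
                       band_centers = c(Delta = 2, Theta = 6, Alpha = 10,
                                        Beta = 16, Gamma = 30),
                       delirium_band_multipliers = c(Delta = 2, Theta = 2,
                                                     Alpha = 2, Beta = 0.4,
                                                     Gamma = 0.4),
                       coupling = NULL,
                       delirium_coupling_attenuation = 0.3,
                       background_exponent = 1,
                       background_amplitude = 1.5,
                       resonator_radius = 0.9,
                       artifact_rate = 0.3,
                       artifact_amplitude = 400,
                       artifact_duration = 1) {
  if (any(band_amplitudes < 0) || any(delirium_band_multipliers < 0))
    stop("band gains must be nonnegative")
  if (recording_duration < epochs_per_subject * epoch_duration)
    stop("recording too short for the requested number of epochs")
  if (is.null(coupling)) {
    left <- intersect(c("F3", "C3", "P3", "T7"), layout$labels)
    if (length(left) >= 2L) {
      pairs <- expand.grid(source = left, sink = left,
                           stringsAsFactors = FALSE)
      pairs <- pairs[pairs$source != pairs$sink, ]
      coupling <- data.frame(source = pairs$source, sink = pairs$sink,
                             lag = rep_len(2:5, nrow(pairs)), gain = 0.3,
                             stringsAsFactors = FALSE)
    } else {
      coupling <- data.frame(source = character(0), sink = character(0),
                             lag = integer(0), gain = numeric(0))
    }
  }
  if (nrow(coupling) > 0L) {
    if (any(!coupling$source %in% layout$labels) ||
        any(!coupling$sink %in% layout$labels))
      stop("coupling edges reference channels absent from the layout")
    if (any(coupling$gain < 0)) stop("coupling gains must be nonnegative")
    if (any(coupling$lag < 1)) stop("coupling lags must be >= 1 sample")
    # guard: were the graph fed back as a VAR, its gain adjacency must be
    # stable; the generator itself is feed-forward regardless
    n <- length(layout$labels)
    adj <- matrix(0, n, n, dimnames = list(layout$labels, layout$labels))
    for (r in seq_len(nrow(coupling)))
      adj[coupling$sink[r], coupling$source[r]] <-
        adj[coupling$sink[r], coupling$source[r]] + coupling$gain[r]
    if (max(Mod(eigen(adj, only.values = TRUE)$values)) >= 1)
      stop("unstable generator: coupling gain adjacency has spectral ",
           "radius >= 1")
  }
  structure(list(n_subjects = n_subjects,
                 epochs_per_subject = epochs_per_subject,
                 epoch_duration = epoch_duration,
                 sampling_rate = sampling_rate, layout = layout,
                 recording_duration = recording_duration,
                 band_amplitudes = band_amplitudes,
                 band_centers = band_centers,
                 delirium_band_multipliers = delirium_band_multipliers,
                 coupling = coupling,
                 delirium_coupling_attenuation = delirium_coupling_attenuation,
                 background_exponent = background_exponent,
                 background_amplitude = background_amplitude,
                 resonator_radius = resonator_radius,
                 artifact_rate = artifact_rate,
                 artifact_amplitude = artifact_amplitude,
                 artifact_duration = artifact_duration),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_subjects, " subjects/group x ",
      x$epochs_per_subject, " epochs x ", x$epoch_duration, " s @ ",
      x$sampling_rate, " Hz, ", length(x$layout$labels), " channels, ",
      nrow(x$coupling), " coupling edge(s)\n", sep = "")
  invisible(x)
}

condition_multipliers <- function(config, group) {
  group <- match.arg(group, c("delirium", "control"))
  if (group == "delirium")
    list(bands = config$delirium_band_multipliers,
         coupling = config$delirium_coupling_attenuation)
  else
    list(bands = stats::setNames(rep(1, length(config$band_amplitudes)),
                                 names(config$band_amplitudes)),
         coupling = 1)
}

# AR(2) resonator at center frequency f0, pole radius r, unit variance
resonator_series <- function(nsamp, f0, r, fs, burn = 512L) {
  theta <- 2 * pi * f0 / fs
  a <- c(2 * r * cos(theta), -r^2)
  x <- as.numeric(stats::filter(stats::rnorm(nsamp + burn), a,
                                method = "recursive"))
  x <- x[(burn + 1L):(burn + nsamp)]
  x / stats::sd(x)
}

# 1/f^exponent background, unit variance, via spectral shaping
one_over_f_series <- function(nsamp, exponent, fs, floor_hz = 0.5) {
  w <- stats::rnorm(nsamp)
  f <- (seq_len(nsamp) - 1) / nsamp * fs
  fold <- pmin(f, fs - f)
  scale <- 1 / pmax(fold, floor_hz)^(exponent / 2)
  x <- Re(stats::fft(stats::fft(w) * scale, inverse = TRUE)) / nsamp
  x / stats::sd(x)
}

#' Simulate one subject's recording with ground truth
#'
#' Each channel is the sum of five unit-variance AR(2) resonators (one per
#' EEG band) scaled by condition-dependent amplitudes, a 1/f background,
#' lagged contributions from the *intrinsic* signal of each coupled source
#' channel (feed-forward mixing: unconditionally stable, yet genuinely
#' Granger-causal), and Poisson-placed high-amplitude slow transients that
#' are recorded exactly in the annotation table.
#'
#' @param config A [sim_config()].
#' @param group `"delirium"` or `"control"`.
#' @param seed Integer seed; output is fully determined by
#'   (config, group, seed).
#' @param subject_id Identifier stored in the recording.
#' @return List: `recording` (an [eeg_recording()]) and `truth` (band
#'   multipliers, effective coupling, artifact spans, seed).
#' @export
simulate_subject <- function(config, group, seed,
                             subject_id = paste0(substr(group, 1, 1), seed)) {
  stopifnot(inherits(config, "sim_config"))
  mult <- condition_multipliers(config, group)
  fs <- config$sampling_rate
  nsamp <- as.integer(round(config$recording_duration * fs))
  labels <- config$layout$labels
  set.seed(seed)
  intrinsic <- matrix(0, length(labels), nsamp,
                      dimnames = list(labels, NULL))
  for (ch in labels) {
    x <- numeric(nsamp)
    for (b in names(config$band_amplitudes)) {
      amp <- config$band_amplitudes[[b]] * mult$bands[[b]]
      if (amp > 0)
        x <- x + amp * resonator_series(nsamp, config$band_centers[[b]],
                                        config$resonator_radius, fs)
    }
    x <- x + config$background_amplitude *
      one_over_f_series(nsamp, config$background_exponent, fs)
    intrinsic[ch, ] <- x
  }
  observed <- intrinsic
  cp <- config$coupling
  if (nrow(cp) > 0L) for (r in seq_len(nrow(cp))) {
    g <- cp$gain[r] * mult$coupling
    lag <- cp$lag[r]
    src <- intrinsic[cp$source[r], ]
    observed[cp$sink[r], ] <- observed[cp$sink[r], ] +
      g * c(rep(0, lag), src[seq_len(nsamp - lag)])
  }
  # artifacts: slow (< 2 Hz content) raised-cosine pulses on all channels
  minutes <- config$recording_duration / 60
  n_art <- if (config$artifact_rate > 0)
    stats::rpois(1L, config$artifact_rate * minutes) else 0L
  ann <- NULL
  if (n_art > 0L) {
    alen <- as.integer(round(config$artifact_duration * fs))
    pulse <- config$artifact_amplitude *
      (0.5 - 0.5 * cos(2 * pi * seq_len(alen) / (alen + 1)))
    onsets <- sort(stats::runif(n_art, 0,
                                config$recording_duration -
                                  config$artifact_duration))
    for (t0 in onsets) {
      i0 <- as.integer(round(t0 * fs)) + 1L
      idx <- i0:(i0 + alen - 1L)
      observed[, idx] <- observed[, idx] +
        matrix(pulse, length(labels), alen, byrow = TRUE)
    }
    ann <- data.frame(onset = onsets,
                      duration = config$artifact_duration,
                      label = "artifact", stringsAsFactors = FALSE)
  }
  rec <- eeg_recording(observed, fs, config$layout, annotations = ann,
                       passband = NULL, subject_id = subject_id,
                       group_label = group)
  truth <- list(group = group, seed = seed,
                band_amplitudes = config$band_amplitudes * mult$bands,
                coupling = transform(cp, gain = gain * mult$coupling),
                artifacts = if (is.null(ann)) data.frame() else ann)
  list(recording = rec, truth = truth)
}

#' Simulate a two-group cohort
#'
#' One recording per subject, long enough for the configured number of
#' clean epochs; per-subject seeds derive deterministically from the
#' master seed.
#'
#' @param config A [sim_config()].
#' @param seed Master seed.
#' @return Object of class `eeg_cohort`: `subjects` (list of
#'   [simulate_subject()] results), `config`, `seed`.
#' @export
simulate_cohort <- function(config, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n <- config$n_subjects
  subseeds <- sample.int(.Machine$integer.max - 1L, 2L * n)
  groups <- rep(c("delirium", "control"), each = n)
  ids <- c(paste0("d", seq_len(n)), paste0("c", seq_len(n)))
  subjects <- lapply(seq_len(2L * n), function(i)
    simulate_subject(config, groups[i], subseeds[i], subject_id = ids[i]))
  names(subjects) <- ids
  structure(list(subjects = subjects, config = config, seed = seed),
            class = "eeg_cohort")
}

#' @export
print.eeg_cohort <- function(x, ...) {
  cat("<eeg_cohort> ", length(x$subjects), " subjects (",
      sum(vapply(x$subjects, function(s) s$truth$group == "delirium", TRUE)),
      " delirium), master seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Simulate a single artifact-free analysis epoch
#'
#' Convenience for Monte-Carlo studies: an epoch-length recording with
#' artifacts disabled, returned directly as an [eeg_epoch()].
#'
#' @param config A [sim_config()].
#' @param group Condition label.
#' @param seed Seed.
#' @param duration Epoch seconds (default from config).
#' @return An `eeg_epoch`.
#' @export
simulate_epoch <- function(config, group, seed,
                           duration = config$epoch_duration) {
  cfg <- config
  cfg$recording_duration <- duration
  cfg$artifact_rate <- 0
  sub <- simulate_subject(cfg, group, seed)
  eeg_epoch(sub$recording$signal, cfg$sampling_rate, start = 0,
            subject_id = sub$recording$subject_id, group_label = group)
}

#' Expected band-gain profile for a condition
#'
#' The analytic oscillator power gains (amplitude squared) the generator
#' injects per band under a condition — an ordering oracle for recovered
#' band powers (resonators leak across band edges, so exact power
#' fractions are not predicted).
#'
#' @param config A [sim_config()].
#' @param group Condition label.
#' @return data.frame: `band`, `amplitude`, `power_gain`, ordered as in
#'   the config, with attribute `ordering` (bands by decreasing power).
#' @export
expected_band_profile <- function(config, group) {
  mult <- condition_multipliers(config, group)
  amp <- config$band_amplitudes * mult$bands
  out <- data.frame(band = names(amp), amplitude = as.numeric(amp),
                    power_gain = as.numeric(amp)^2,
                    stringsAsFactors = FALSE)
  attr(out, "ordering") <- out$band[order(-out$power_gain)]
  out
}
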