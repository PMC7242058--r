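# Shared fixtures; everything is generated in code at test time.

two_channel_layout <- function() channel_layout(c("C3", "P3"), "C2")
three_channel_layout <- function() channel_layout(c("C3", "P3", "T7"), "C2")

no_coupling <- function()
  data.frame(source = character(0), sink = character(0),
             lag = integer(0), gain = numeric(0))

# bivariate generator with a single directed edge C3 -> P3
bivariate_config <- function(gain = 0.4, lag = 1) {
  sim_config(layout = two_channel_layout(),
             coupling = data.frame(source = "C3", sink = "P3",
                                   lag = lag, gain = gain))
}

# reduced-montage generator for SFPR / reduced-rPDC studies; short
# artifact-free recordings keep Monte-Carlo loops affordable
reduced_config <- function(duration = 180)
  sim_config(layout = three_channel_layout(),
             epochs_per_subject = max(1L, duration %/% 60),
             recording_duration = duration, artifact_rate = 0)

# small full-montage cohort for pipeline shape checks
small_study_config <- function(seed = 1)
  study_config(sim = sim_config(n_subjects = 2, epochs_per_subject = 2,
                                epoch_duration = 20,
                                recording_duration = 60,
                                artifact_rate = 0),
               seed = seed)

# a hand-built power_spectrum on the standard grid
flat_spectrum <- function(value = 1, channel = NA_character_)
  power_spectrum(frequency_grid(), rep(value, 90), channel = channel)

# fabricate an rpdc_set with prescribed values for one or more pairs;
# enough structure for group_rpdc / compare_groups
fake_rpdc_set <- function(values_by_pair, grid = seq(0.5, 5, 0.5),
                          chance = chance_level()) {
  rows <- lapply(names(values_by_pair), function(k) {
    sv <- strsplit(k, "->", fixed = TRUE)[[1]]
    data.frame(source = sv[1], sink = sv[2], freq = grid,
               rpdc = values_by_pair[[k]], stringsAsFactors = FALSE)
  })
  values <- do.call(rbind, rows)
  structure(list(values = values, chance_level = chance, alpha = 0.05,
                 pairs = unique(values[, c("source", "sink")]),
                 grid = grid, N = 1000, channels = NULL),
            class = "rpdc_set")
}

# balanced 2 x 8 x 5 band-power-like table
random_balanced_table <- function(per_cell = 5, channels = 8, sd = 1,
                                  shift = 0) {
  d <- expand.grid(subject = seq_len(per_cell),
                   group = c("delirium", "control"),
                   channel = paste0("ch", seq_len(channels)),
                   stringsAsFactors = FALSE)
  d$value <- stats::rnorm(nrow(d), sd = sd) +
    ifelse(d$group == "delirium", shift, 0)
  d
}
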