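#' Configure an end-to-end study
#'
#' Collects every analysis parameter in one validated, serializable
#' object: input mode, band definitions, the AR order rule (order =
#' sampling rate / 4 unless overridden), VAR order, the connectivity and
#' SFPR electrode subsets, significance and confidence levels, and the
#' master seed. The full configuration is written into every run output
#' for provenance.
#'
#' @param input `"simulate"` or a directory containing recordings and a
#'   `manifest.json` written by [write_cohort()].
#' @param sim A [sim_config()] (used when `input = "simulate"`).
#' @param ar_order AR order; `NULL` applies the rate/4 rule.
#' @param var_order VAR model order for connectivity.
#' @param connectivity_channels Montage for the banded + full-range rPDC
#'   analysis.
#' @param reduced_channels Reduced montage refit for the full-range-only
#'   rPDC analysis and used for SFPR.
#' @param alpha Significance level; `ci` confidence level.
#' @param seed Master seed.
#' @return Object of class `study_config`.
#' @export
study_config <- function(input = "simulate", sim = sim_config(),
                         ar_order = NULL, var_order = 16,
                         connectivity_channels = c("F3", "C3", "P3", "T7"),
                         reduced_channels = c("C3", "P3", "T7"),
                         alpha = 0.05, ci = 0.95, seed = 1) {
  stopifnot(alpha > 0, alpha < 1, ci > 0, ci < 1)
  structure(list(input = input, sim = sim, ar_order = ar_order,
                 var_order = var_order,
                 connectivity_channels = connectivity_channels,
                 reduced_channels = reduced_channels,
                 alpha = alpha, ci = ci, seed = seed),
            class = "study_config")
}

#' @export
print.study_config <- function(x, ...) {
  cat("<study_config> input = ", x$input, ", seed ", x$seed,
      ", alpha ", x$alpha, ", CI ", x$ci, "\n", sep = "")
  invisible(x)
}

#' Run the full screening analysis
#'
#' Sequences every stage: obtain the cohort (simulated or read from
#' files), band-pass preprocess, select artifact-free epochs, fit
#' per-epoch AR spectra and average within subject, tabulate band powers
#' under the split normalization, run per-band two-way ANOVAs with
#' Bonferroni post-tests, compute SFPR panels with exact Mann-Whitney
#' comparisons, and perform the rPDC connectivity analysis on the full
#' montage (per band and full range) and refit on the reduced montage
#' (full range). A failure in any subject aborts with an error naming the
#' subject and stage.
#'
#' @param config A [study_config()].
#' @param verbose Print stage progress.
#' @return Object of class `study_report`; see [print.study_report()].
#' @export
run_study <- function(config = study_config(), verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  say <- function(...) if (verbose) message(...)

  say("stage 1/6: cohort")
  cohort <- if (identical(config$input, "simulate"))
    simulate_cohort(config$sim, config$seed)
  else read_cohort(config$input)

  say("stage 2/6: preprocess + epoch selection")
  n_epochs <- config$sim$epochs_per_subject
  dur <- config$sim$epoch_duration
  epochs <- lapply(names(cohort$subjects), function(id) {
    sub <- cohort$subjects[[id]]
    tryCatch({
      pp <- preprocess(sub$recording, fs_out = 256)
      select_epochs(pp, n = n_epochs, duration = dur)
    }, error = function(e)
      stop("subject ", id, " (preprocess/epochs): ", conditionMessage(e),
           call. = FALSE))
  })
  names(epochs) <- names(cohort$subjects)
  groups <- vapply(cohort$subjects, function(s) s$truth$group, "")

  say("stage 3/6: AR spectra + band powers")
  fs <- epochs[[1L]][[1L]]$sampling_rate
  ar_order_used <- if (is.null(config$ar_order)) round(fs / 4) else
    config$ar_order
  spectra <- lapply(names(epochs), function(id)
    tryCatch(subject_spectra(epochs[[id]], order = config$ar_order),
             error = function(e)
               stop("subject ", id, " (AR spectra): ",
                    conditionMessage(e), call. = FALSE)))
  names(spectra) <- names(epochs)
  bp <- do.call(rbind, lapply(names(spectra), function(id) {
    rows <- do.call(rbind, lapply(spectra[[id]], band_power))
    rows$subject_id <- id
    rows$group <- groups[[id]]
    rows
  }))
  rownames(bp) <- NULL

  say("stage 4/6: ANOVA + post-tests per band")
  anovas <- list(); posttests <- list()
  for (b in eeg_bands()$band) {
    tb <- bp[bp$band == b, c("group", "channel", "relative_power")]
    names(tb)[3] <- "value"
    anovas[[b]] <- two_way_anova(tb)
    posttests[[b]] <- bonferroni_posttests(anovas[[b]])
  }

  say("stage 5/6: SFPR + Mann-Whitney")
  panels <- lapply(names(spectra), function(id)
    sfpr_panel(spectra[[id]], channels = config$reduced_channels))
  names(panels) <- names(spectra)
  sfpr_tab <- do.call(rbind, lapply(names(panels), function(id) {
    p <- panels[[id]]
    data.frame(subject_id = id, group = groups[[id]],
               channel = c(p$channels, "average"),
               sfpr = c(p$per_channel, p$average),
               stringsAsFactors = FALSE)
  }))
  sfpr_tests <- do.call(rbind, lapply(
    c(config$reduced_channels, "average"), function(ch) {
      d <- sfpr_tab$sfpr[sfpr_tab$channel == ch & sfpr_tab$group == "delirium"]
      c0 <- sfpr_tab$sfpr[sfpr_tab$channel == ch & sfpr_tab$group == "control"]
      mw <- mann_whitney_exact(d, c0)
      data.frame(channel = ch, U = mw$U, p = mw$p,
                 median_delirium = unname(mw$medians["x"]),
                 median_control = unname(mw$medians["y"]),
                 stars = significance_stars(mw$p),
                 stringsAsFactors = FALSE)
    }))

  say("stage 6/6: rPDC connectivity")
  by_group <- list(
    delirium = do.call(c, unname(epochs[groups == "delirium"])),
    control  = do.call(c, unname(epochs[groups == "control"])))
  conn_banded <- run_connectivity(by_group,
                                  channels = config$connectivity_channels,
                                  ranges = "bands", order = config$var_order,
                                  ci = config$ci, alpha = config$alpha)
  conn_full <- run_connectivity(by_group,
                                channels = config$connectivity_channels,
                                ranges = "full", order = config$var_order,
                                ci = config$ci, alpha = config$alpha)
  conn_reduced <- run_connectivity(by_group,
                                   channels = config$reduced_channels,
                                   ranges = "full", order = config$var_order,
                                   ci = config$ci, alpha = config$alpha)

  structure(list(config = config, band_power = bp, anovas = anovas,
                 posttests = posttests, sfpr = sfpr_tab,
                 sfpr_tests = sfpr_tests,
                 connectivity = list(banded = conn_banded,
                                     full = conn_full,
                                     reduced = conn_reduced),
                 n_subjects = length(epochs),
                 n_per_group = sum(groups == "delirium"),
                 ar_order = ar_order_used,
                 pooled_per_group = sum(groups == "delirium") * n_epochs),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("=== QEEG delirium screening report ===\n")
  cat(x$n_subjects, " subjects, ", x$pooled_per_group,
      " pooled epochs per group\n\n", sep = "")
  cat("Relative band power, two-way ANOVA (status x channel):\n")
  for (b in names(x$anovas)) {
    e <- x$anovas[[b]]$effects
    st <- e[e$effect == "status", ]
    dmean <- mean(x$band_power$relative_power[
      x$band_power$band == b & x$band_power$group == "delirium"])
    cmean <- mean(x$band_power$relative_power[
      x$band_power$band == b & x$band_power$group == "control"])
    cat(sprintf("  %-6s status F(%d,%d) = %7.2f, p = %-10s %s (delirium %5.1f%% vs control %5.1f%%)\n",
                b, st$df1, st$df2, st$F, format.pval(st$p, digits = 3),
                significance_stars(st$p), dmean, cmean))
  }
  cat("\nSFPR (slow/fast power ratio), exact Mann-Whitney:\n")
  for (r in seq_len(nrow(x$sfpr_tests)))
    cat(sprintf("  %-8s median %6.2f vs %6.2f, p = %-8s %s\n",
                x$sfpr_tests$channel[r], x$sfpr_tests$median_delirium[r],
                x$sfpr_tests$median_control[r],
                format(x$sfpr_tests$p[r], digits = 3),
                x$sfpr_tests$stars[r]))
  dec <- x$connectivity$reduced$decisions
  cat("\nrPDC, reduced montage (",
      paste(x$connectivity$reduced$channels, collapse = ", "),
      "), full 0.5-45 Hz range:\n  ", sum(dec$significant), "/", nrow(dec),
      " directed pairs significantly different (",
      sum(dec$significant & dec$lower_group == "delirium"),
      " with delirium lower)\n", sep = "")
  invisible(x)
}

#' Write a cohort to disk as EDF files plus manifest
#'
#' One EDF per subject with its annotation sidecar, a `manifest.json`
#' naming files and group labels, and the generator ground truth as JSON.
#'
#' @param cohort An `eeg_cohort`.
#' @param dir Output directory (created if needed).
#' @param format `"edf"` or `"bdf"`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = "edf") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(names(cohort$subjects), function(id) {
    f <- paste0(id, ".", format)
    write_recording(cohort$subjects[[id]]$recording, file.path(dir, f),
                    format = format)
    list(file = f, subject_id = id,
         group = cohort$subjects[[id]]$truth$group)
  })
  jsonlite::write_json(entries, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  truth <- lapply(cohort$subjects, function(s) s$truth[
    c("group", "seed", "band_amplitudes")])
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#' @param dir Directory containing `manifest.json` and recordings.
#' @return An `eeg_cohort`-shaped list (without generator config).
#' @export
read_cohort <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf))
    stop("no manifest.json in ", dir, ": not a cohort directory")
  entries <- jsonlite::read_json(mf)
  subjects <- lapply(entries, function(e) {
    rec <- read_recording(file.path(dir, e$file))
    rec$subject_id <- e$subject_id
    rec$group_label <- e$group
    list(recording = rec, truth = list(group = e$group))
  })
  names(subjects) <- vapply(entries, function(e) e$subject_id, "")
  structure(list(subjects = subjects, config = NULL, seed = NA),
            class = "eeg_cohort")
}

#' Write all report tables to a directory
#'
#' Emits tidy CSVs (band powers, ANOVA effects, post-tests, SFPR values
#' and tests, rPDC decisions for each montage/range set), the serialized
#' configuration, and a plain-text report.
#'
#' @param report A `study_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(d, f) utils::write.csv(d, file.path(dir, f),
                                          row.names = FALSE)
  wcsv(report$band_power, "band_power.csv")
  an <- do.call(rbind, lapply(names(report$anovas), function(b) {
    e <- report$anovas[[b]]$effects; e$band <- b; e }))
  wcsv(an, "anova.csv")
  pt <- do.call(rbind, lapply(names(report$posttests), function(b) {
    e <- report$posttests[[b]]; e$band <- b; e }))
  wcsv(pt, "posttests.csv")
  wcsv(report$sfpr, "sfpr.csv")
  wcsv(report$sfpr_tests, "sfpr_tests.csv")
  for (nm in names(report$connectivity))
    wcsv(report$connectivity[[nm]]$decisions,
         paste0("rpdc_decisions_", nm, ".csv"))
  cfg <- report$config
  cfg_list <- unclass(cfg)
  cfg_list$sim <- unclass(cfg_list$sim)
  cfg_list$sim$layout <- unclass(cfg_list$sim$layout)
  jsonlite::write_json(cfg_list, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(dir, "report.txt"))
  invisible(dir)
}
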