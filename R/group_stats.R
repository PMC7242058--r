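#' Balanced between-subjects two-way ANOVA
#'
#' Patient status (delirium vs control) and recording channel as fully
#' crossed between-subjects factors on a balanced, complete design —
#' "non-matching" in the sense that every (status, channel, subject) cell
#' value is treated as an independent observation, which is what the
#' error-df structure (N - g*c, e.g. 80 - 16 = 64) implies. Channels of
#' course share subjects, so p-values carry the usual caveat of this
#' design; effect sizes are the primary readout at pilot scale. Fitting
#' delegates to [stats::aov()].
#'
#' @param table data.frame with columns `group`, `channel`, `value` (one
#'   row per subject x channel cell entry).
#' @return Object of class `anova2w`: `$effects` data.frame (effect, df1,
#'   df2, F, p), `$ms_error`, `$df_error`, `$cell_means`, `$per_cell`,
#'   `$table`.
#' @export
#' @examples
#' d <- expand.grid(subject = 1:5, group = c("delirium", "control"),
#'                  channel = c("F3", "F4"))
#' d$value <- rnorm(nrow(d)) + (d$group == "delirium")
#' two_way_anova(d)
two_way_anova <- function(table) {
  table <- as.data.frame(table)
  stopifnot(all(c("group", "channel", "value") %in% names(table)))
  table$group <- factor(table$group)
  table$channel <- factor(table$channel)
  counts <- stats::xtabs(~ group + channel, table)
  if (length(unique(as.vector(counts))) != 1L || any(counts == 0))
    stop("unbalanced design: every group x channel cell needs the same ",
         "number of observations")
  per_cell <- as.vector(counts)[1L]
  g <- nlevels(table$group); c <- nlevels(table$channel)
  df_error <- nrow(table) - g * c
  ss_total <- sum((table$value - mean(table$value))^2)
  if (ss_total < 1e-12 * max(1, mean(table$value)^2) * nrow(table)) {
    eff <- data.frame(effect = c("status", "channel", "interaction"),
                      df1 = c(g - 1L, c - 1L, (g - 1L) * (c - 1L)),
                      df2 = df_error, F = 0, p = 1,
                      stringsAsFactors = FALSE)
    ms_error <- 0
  } else {
    fit <- stats::aov(value ~ group * channel, data = table)
    sm <- summary(fit)[[1L]]
    eff <- data.frame(effect = c("status", "channel", "interaction"),
                      df1 = sm[1:3, "Df"], df2 = sm[4L, "Df"],
                      F = sm[1:3, "F value"], p = sm[1:3, "Pr(>F)"],
                      stringsAsFactors = FALSE)
    ms_error <- sm[4L, "Mean Sq"]
  }
  cm <- stats::aggregate(value ~ group + channel, table, mean)
  structure(list(effects = eff, ms_error = ms_error, df_error = df_error,
                 cell_means = cm, per_cell = per_cell, table = table),
            class = "anova2w")
}

#' @export
print.anova2w <- function(x, digits = 4, ...) {
  cat("<anova2w> balanced two-way ANOVA, error df ", x$df_error, "\n",
      sep = "")
  e <- x$effects
  for (r in seq_len(nrow(e)))
    cat(sprintf("  %-12s F(%d,%d) = %s, p = %s\n", e$effect[r], e$df1[r],
                e$df2[r], format(e$F[r], digits = digits),
                format.pval(e$p[r], digits = digits)))
  invisible(x)
}

#' @export
summary.anova2w <- function(object, ...) {
  cat("Cell means:\n")
  print(object$cell_means)
  print(object)
  invisible(object)
}

significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' Bonferroni post-tests at individual electrode sites
#'
#' Per-channel between-group t tests using the pooled ANOVA error term
#' (t = mean difference / sqrt(MS_error * 2 / per_cell), on the ANOVA
#' error df), with p-values multiplied by the number of channels and
#' capped at 1.
#'
#' @param anova An [two_way_anova()] result with exactly two groups.
#' @param group_order Length-2 character: difference is
#'   `mean(group_order[1]) - mean(group_order[2])`.
#' @return data.frame: `channel`, `mean_diff`, `t`, `df`, `p`,
#'   `p_adjusted`, `stars`.
#' @export
bonferroni_posttests <- function(anova,
                                 group_order = c("delirium", "control")) {
  stopifnot(inherits(anova, "anova2w"))
  cm <- anova$cell_means
  channels <- unique(as.character(cm$channel))
  nchan <- length(channels)
  se <- sqrt(anova$ms_error * 2 / anova$per_cell)
  out <- lapply(channels, function(ch) {
    m1 <- cm$value[cm$channel == ch & cm$group == group_order[1]]
    m2 <- cm$value[cm$channel == ch & cm$group == group_order[2]]
    d <- m1 - m2
    tstat <- if (se == 0) 0 else d / se
    p <- 2 * stats::pt(-abs(tstat), df = anova$df_error)
    data.frame(channel = ch, mean_diff = d, t = tstat,
               df = anova$df_error, p = p,
               p_adjusted = min(1, p * nchan),
               stars = significance_stars(min(1, p * nchan)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Exact two-tailed Mann-Whitney test
#'
#' U by rank summation with midranks for ties; the two-tailed p-value is
#' exact, obtained by enumerating all choose(n1+n2, n1) assignments of the
#' pooled observations to groups and counting assignments whose U deviates
#' from its null mean n1*n2/2 at least as much as the observed U.
#' Deterministic and defensible at the pilot sample sizes this package
#' targets (n1 + n2 <= 20 enforced).
#'
#' @param x,y Numeric samples for the two groups.
#' @return Object of class `mw_exact`: `U` (for `x`), `p` (exact
#'   two-tailed), `medians`, `n`.
#' @export
#' @examples
#' mann_whitney_exact(c(6, 7, 8, 9, 10), c(1, 2, 3, 4, 5))  # p = 2/252
mann_whitney_exact <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 1L, n2 >= 1L)
  if (n1 + n2 > 20L)
    stop("exact enumeration limited to n1 + n2 <= 20")
  pooled <- c(x, y)
  rk <- rank(pooled)  # midranks
  u_from <- function(idx) sum(rk[idx]) - length(idx) * (length(idx) + 1) / 2
  U <- u_from(seq_len(n1))
  dev_obs <- abs(U - n1 * n2 / 2)
  combs <- utils::combn(n1 + n2, n1)
  devs <- abs(apply(combs, 2L, u_from) - n1 * n2 / 2)
  p <- mean(devs >= dev_obs - 1e-9)
  structure(list(U = U, p = p,
                 medians = c(x = stats::median(x), y = stats::median(y)),
                 n = c(n1 = n1, n2 = n2)),
            class = "mw_exact")
}

#' @export
print.mw_exact <- function(x, digits = 4, ...) {
  cat("<mw_exact> U = ", x$U, " (n = ", x$n[1], ", ", x$n[2],
      "), exact two-tailed p = ", format(x$p, digits = digits),
      "\n  medians: ", format(x$medians[1], digits = digits), " vs ",
      format(x$medians[2], digits = digits), "\n", sep = "")
  invisible(x)
}
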