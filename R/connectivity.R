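#' Fit a vector autoregressive model by least squares
#'
#' Equation-by-equation ordinary least squares on lagged regressors, the
#' standard VAR estimator. Besides the coefficient matrices and innovation
#' covariance, the fit retains the per-equation coefficient covariance
#' (sigma_ii * (X'X)^-1), which the rPDC renormalization propagates into
#' frequency-domain confidence scaling. The default order of 16 at 256 Hz
#' keeps the parameter count tractable for 4 channels on 60-second epochs
#' while retaining sub-Hz resonance structure.
#'
#' @param epoch An [eeg_epoch()] or a channels x samples numeric matrix.
#' @param channels Optional subset of channel labels to model (rPDC is
#'   model dependent, so reduced-montage analyses must refit on the
#'   subset rather than subsetting a larger model).
#' @param order VAR order p.
#' @param sampling_rate Required when `epoch` is a bare matrix.
#' @return Object of class `var_model`: `n_channels`, `order`, `A` (list of
#'   p coefficient matrices), `Sigma` (innovation covariance), `XtX_inv`,
#'   `sigma2` (per-equation residual variances), `N` (effective sample
#'   count), `channels`, `sampling_rate`.
#' @export
fit_var <- function(epoch, channels = NULL, order = 16,
                    sampling_rate = NULL) {
  if (inherits(epoch, "eeg_epoch")) {
    Y <- epoch$signal
    sampling_rate <- epoch$sampling_rate
  } else {
    Y <- as.matrix(epoch)
    if (is.null(sampling_rate))
      stop("sampling_rate must be given for a bare matrix")
  }
  if (!is.null(channels)) {
    missing <- setdiff(channels, rownames(Y))
    if (length(missing) > 0L)
      stop("missing channel(s): ", paste(missing, collapse = ", "))
    Y <- Y[channels, , drop = FALSE]
  }
  n <- nrow(Y); Tlen <- ncol(Y); p <- as.integer(order)
  if (n < 2L) stop("need at least 2 channels for a VAR model")
  if (Tlen < 10L * p * n)
    stop("signal too short for VAR(", p, ") on ", n, " channels: need >= ",
         10L * p * n, " samples, got ", Tlen)
  Y <- Y - rowMeans(Y)
  N <- Tlen - p
  # regressor rows: [y_{t-1}', ..., y_{t-p}'], columns (k-1)*n + j
  X <- matrix(0, N, n * p)
  for (k in seq_len(p))
    X[, ((k - 1L) * n + 1L):(k * n)] <- t(Y[, (p - k + 1L):(Tlen - k), drop = FALSE])
  Yt <- t(Y[, (p + 1L):Tlen, drop = FALSE])
  XtX <- crossprod(X)
  ch <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(ch) || any(diag(ch) < sqrt(.Machine$double.eps) * max(diag(ch))))
    stop("rank-deficient regressor matrix (collinear or duplicated channels)")
  XtX_inv <- chol2inv(ch)
  B <- XtX_inv %*% crossprod(X, Yt)          # (n p) x n, column i = eqn i
  resid <- Yt - X %*% B
  Sigma <- crossprod(resid) / (N - n * p)
  sigma2 <- diag(Sigma)
  A <- lapply(seq_len(p), function(k)
    t(B[((k - 1L) * n + 1L):(k * n), , drop = FALSE]))  # A_k[i,j]
  comp <- companion_matrix(A)
  if (max(Mod(eigen(comp, only.values = TRUE)$values)) >= 1)
    stop("numerical failure: fitted VAR model is unstable")
  structure(list(n_channels = n, order = p, A = A, Sigma = Sigma,
                 XtX_inv = XtX_inv, sigma2 = sigma2, N = N,
                 channels = rownames(Y), sampling_rate = sampling_rate),
            class = "var_model")
}

companion_matrix <- function(A) {
  p <- length(A); n <- nrow(A[[1L]])
  C <- matrix(0, n * p, n * p)
  C[1:n, ] <- do.call(cbind, A)
  if (p > 1L)
    C[(n + 1L):(n * p), 1L:(n * (p - 1L))] <- diag(n * (p - 1L))
  C
}

#' Construct a VAR model from known coefficient matrices
#'
#' For analytically specified processes used as oracles. When no estimator
#' covariance is available, an identity-scaled surrogate `(X'X)^-1 = I/N`
#' is assumed; the rPDC statistic of an exactly zero coupling is zero
#' regardless of that choice.
#'
#' @param A List of p coefficient matrices (n x n), `A[[k]][i, j]` the
#'   influence of channel j at lag k on channel i.
#' @param Sigma Innovation covariance (default identity).
#' @param sampling_rate Hz.
#' @param N Nominal effective sample count.
#' @param channels Channel labels.
#' @return A `var_model`.
#' @export
var_model <- function(A, Sigma = NULL, sampling_rate = 256, N = 1000,
                      channels = NULL) {
  if (is.matrix(A)) A <- list(A)
  n <- nrow(A[[1L]]); p <- length(A)
  if (is.null(Sigma)) Sigma <- diag(n)
  if (is.null(channels)) channels <- paste0("ch", seq_len(n))
  comp <- companion_matrix(A)
  if (max(Mod(eigen(comp, only.values = TRUE)$values)) >= 1)
    stop("unstable VAR specification")
  structure(list(n_channels = n, order = p, A = A, Sigma = Sigma,
                 XtX_inv = diag(n * p) / N, sigma2 = diag(Sigma), N = N,
                 channels = channels, sampling_rate = sampling_rate),
            class = "var_model")
}

#' @export
print.var_model <- function(x, ...) {
  cat("<var_model> ", x$n_channels, " channels (",
      paste(x$channels, collapse = ", "), "), order ", x$order,
      ", N = ", x$N, " @ ", x$sampling_rate, " Hz\n", sep = "")
  invisible(x)
}

#' Renormalized partial directed coherence
#'
#' For every ordered channel pair j -> i (i != j) and every grid frequency
#' f, the Fourier-transformed off-diagonal VAR coefficient
#' A_bar_ij(f) = sum_k A_k\[i,j\] exp(-i 2 pi f k dt) is stacked as the
#' 2-vector Z = (Re, Im). Renormalization scales Z by its own estimator
#' covariance, propagated from the least-squares coefficient covariance:
#' lambda_ij(f) = N * Z' V^-1 Z with V = N * Cov_hat(Z) the asymptotic
#' covariance of sqrt(N) * Z. Unlike raw partial directed
#' coherence, lambda is comparable across pairs and frequencies and has a
#' chi-square(2) null distribution when the true coupling is zero, which
#' yields the analytic "expected by chance" level.
#'
#' @param model A fitted [fit_var()] (or analytic [var_model()]).
#' @param grid Frequencies in Hz.
#' @param alpha Significance level defining the attached chance level.
#' @return Object of class `rpdc_set`: a long data.frame `$values` with
#'   columns `source`, `sink`, `freq`, `rpdc`, plus `$chance_level`,
#'   `$pairs`, `$grid`, `$N`, `$channels`.
#' @export
rpdc <- function(model, grid = frequency_grid(), alpha = 0.05) {
  stopifnot(inherits(model, "var_model"))
  n <- model$n_channels; p <- model$order
  dt <- 1 / model$sampling_rate
  omega <- 2 * pi * grid * dt
  k <- seq_len(p)
  # 2 x p transforms per frequency: Z = T %*% a
  Tcos <- outer(omega, k, function(w, kk) cos(w * kk))
  Tsin <- -outer(omega, k, function(w, kk) sin(w * kk))
  chance <- chance_level(alpha)
  rows <- list()
  pair_R <- list()
  warned <- FALSE
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    idx <- j + (k - 1L) * n
    a <- vapply(k, function(kk) model$A[[kk]][i, j], 0)
    R <- model$sigma2[i] * model$XtX_inv[idx, idx, drop = FALSE]
    pair_R[[paste0(model$channels[j], "->", model$channels[i])]] <- R
    lam <- numeric(length(grid))
    for (q in seq_along(grid)) {
      Tq <- rbind(Tcos[q, ], Tsin[q, ])
      Z <- as.numeric(Tq %*% a)
      V <- Tq %*% R %*% t(Tq)
      detV <- V[1, 1] * V[2, 2] - V[1, 2] * V[2, 1]
      if (!is.finite(detV) || detV <= 1e-300 * max(V[1, 1] * V[2, 2], 1e-300)) {
        V <- V + diag(2) * 1e-12 * (V[1, 1] + V[2, 2])
        if (!warned) {
          warning("near-singular renormalization covariance; ",
                  "Tikhonov-regularized")
          warned <- TRUE
        }
      }
      lam[q] <- sum(Z * solve(V, Z))  # = N Z' (N V)^-1 Z
    }
    rows[[length(rows) + 1L]] <- data.frame(
      source = model$channels[j], sink = model$channels[i],
      freq = grid, rpdc = lam, stringsAsFactors = FALSE)
  }
  values <- do.call(rbind, rows)
  pairs <- unique(values[, c("source", "sink")])
  structure(list(values = values, chance_level = chance, alpha = alpha,
                 pairs = pairs, grid = grid, N = model$N,
                 channels = model$channels, pair_R = pair_R,
                 Tcos = Tcos, Tsin = Tsin),
            class = "rpdc_set")
}

#' @export
print.rpdc_set <- function(x, ...) {
  cat("<rpdc_set> ", nrow(x$pairs), " directed pairs x ", length(x$grid),
      " frequencies, chance level ", format(x$chance_level, digits = 4),
      "\n", sep = "")
  above <- tapply(x$values$rpdc > x$chance_level,
                  paste(x$values$source, "->", x$values$sink), mean)
  print(round(above, 3))
  invisible(x)
}

#' @export
plot.rpdc_set <- function(x, ...) {
  pr <- x$pairs
  nc <- ceiling(sqrt(nrow(pr)))
  old <- graphics::par(mfrow = c(ceiling(nrow(pr) / nc), nc),
                       mar = c(3, 3, 2, 1))
  on.exit(graphics::par(old))
  for (r in seq_len(nrow(pr))) {
    v <- x$values[x$values$source == pr$source[r] &
                    x$values$sink == pr$sink[r], ]
    graphics::plot(v$freq, v$rpdc, type = "l",
                   main = paste(pr$source[r], "→", pr$sink[r]),
                   xlab = "", ylab = "", ...)
    graphics::abline(h = x$chance_level, col = "blue")
  }
  invisible(x)
}

#' rPDC strength expected by chance
#'
#' Under zero true coupling the renormalized statistic is chi-square with
#' 2 degrees of freedom, so the chance level at significance `alpha` is its
#' upper alpha quantile (equivalently -2 log(alpha)).
#'
#' @param alpha Pointwise significance level in (0, 1).
#' @return The threshold (dimensionless).
#' @export
chance_level <- function(alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  stats::qchisq(1 - alpha, df = 2)
}

#' Pool per-epoch rPDC spectra into group means with confidence bands
#'
#' @param samples List of `rpdc_set` objects, one per pooled epoch
#'   (5 subjects x 3 epochs = 15 per group in the standard design), with
#'   identical grids and pair sets.
#' @param ci Confidence level for the t-based interval on the group mean.
#' @return Object of class `group_rpdc`: data.frame `$stats` with `source`,
#'   `sink`, `freq`, `mean`, `half_width`, plus `$n`, `$ci`,
#'   `$chance_level`, `$grid`, `$pairs`.
#' @export
group_rpdc <- function(samples, ci = 0.95) {
  stopifnot(length(samples) >= 2L)
  ref <- samples[[1L]]
  key <- function(s) paste(s$values$source, s$values$sink, s$values$freq)
  k0 <- key(ref)
  mat <- vapply(samples, function(s) {
    if (!identical(key(s), k0))
      stop("mismatched pair sets or grids between pooled samples")
    s$values$rpdc
  }, numeric(nrow(ref$values)))
  n <- length(samples)
  m <- rowMeans(mat)
  sdv <- apply(mat, 1L, stats::sd)
  hw <- stats::qt(1 - (1 - ci) / 2, df = n - 1) * sdv / sqrt(n)
  stats_df <- data.frame(source = ref$values$source, sink = ref$values$sink,
                         freq = ref$values$freq, mean = m, half_width = hw,
                         stringsAsFactors = FALSE)
  structure(list(stats = stats_df, n = n, ci = ci,
                 chance_level = ref$chance_level, grid = ref$grid,
                 pairs = ref$pairs, samples = mat),
            class = "group_rpdc")
}

#' @export
print.group_rpdc <- function(x, ...) {
  cat("<group_rpdc> ", nrow(x$pairs), " pairs, n = ", x$n,
      " pooled epochs, ", 100 * x$ci, "% CI\n", sep = "")
  invisible(x)
}

#' Null rate of the pointwise mutual CI-exclusion rule
#'
#' A frequency point is flagged when each group's mean lies outside the
#' other group's confidence interval. Under a common normal null this
#' conjunction fires with probability well above the CI's nominal
#' complement (the interval is scaled for a single mean, not a mean
#' difference), so "the number of points predicted at random" must be
#' computed from the rule itself. This evaluates
#' E\[2 Phi_bar(t_crit * max(s1, s2) / sqrt(sigma1^2/n1 + sigma2^2/n2))\]
#' over the sampling distributions of the two group standard deviations by
#' Gauss-Legendre quadrature; deterministic, no simulation.
#'
#' @param n1,n2 Group sample counts.
#' @param ci Confidence level of the intervals.
#' @return Pointwise null flag probability.
#' @export
pointwise_null_rate <- function(n1, n2, ci = 0.95) {
  t1 <- stats::qt(1 - (1 - ci) / 2, n1 - 1) / sqrt(n1)
  t2 <- stats::qt(1 - (1 - ci) / 2, n2 - 1) / sqrt(n2)
  sd_diff <- sqrt(1 / n1 + 1 / n2)
  gl <- gauss_legendre(60)
  # integrate over u = chisq_{n-1}/(n-1) via probability transform
  p_nodes <- (gl$x + 1) / 2 * (1 - 2e-9) + 1e-9
  w <- gl$w / 2
  s1 <- sqrt(stats::qchisq(p_nodes, n1 - 1) / (n1 - 1))
  s2 <- sqrt(stats::qchisq(p_nodes, n2 - 1) / (n2 - 1))
  thr <- outer(t1 * s1, t2 * s2, pmax)
  rate <- 2 * stats::pnorm(-thr / sd_diff)
  as.numeric(w %*% rate %*% w)
}

gauss_legendre <- function(n) {
  # Golub-Welsch: nodes/weights on [-1, 1]
  b <- seq_len(n - 1)
  b <- b / sqrt(4 * b^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1), 2:n)] <- b
  J[cbind(2:n, seq_len(n - 1))] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = rev(e$values), w = rev(2 * e$vectors[1, ]^2))
}

#' Smallest count of flagged points that exceeds chance
#'
#' The smallest k with P(Binomial(n_points, point_rate) >= k) < alpha,
#' treating frequency points as independent.
#'
#' @param n_points Points in the frequency range.
#' @param point_rate Null probability of a single-point flag.
#' @param alpha Range-level significance.
#' @return Integer critical count.
#' @export
critical_count <- function(n_points, point_rate, alpha = 0.05) {
  k <- stats::qbinom(1 - alpha, n_points, point_rate)
  while (stats::pbinom(k - 1, n_points, point_rate, lower.tail = FALSE) >= alpha)
    k <- k + 1L
  as.integer(k)
}

#' Group-difference verdicts over frequency ranges
#'
#' Implements the counting rule: a single frequency point differs between
#' groups when each group's pooled mean lies outside the other group's
#' confidence interval (the conjunction is symmetric in group labels); a
#' range differs significantly when the number of differing points reaches
#' the binomial critical count for that range, i.e. exceeds what the
#' pointwise rule would flag at random. By default the pointwise null rate
#' is derived from the rule itself via [pointwise_null_rate()]; pass
#' `point_rate` to override (e.g. 0.05 for a nominal-alpha reading).
#'
#' @param A,B `group_rpdc` objects for the two groups (conventionally
#'   A = delirium, B = control) on identical grids and pair sets.
#' @param ranges `"full"` for the whole 0.5-45 Hz range, `"bands"` for the
#'   five EEG bands, or a data.frame with `range`, `lo`, `hi`,
#'   `hi_inclusive`.
#' @param alpha Range-level significance.
#' @param point_rate Pointwise null rate for the binomial calibration;
#'   `NULL` (default) computes it from the group sizes and CI level.
#' @param calibration How the critical count is obtained: `"permutation"`
#'   (default) takes the (1 - alpha) quantile of the count under random
#'   relabelling of the pooled epochs, which respects the strong
#'   correlation of flags across neighbouring frequencies; `"binomial"`
#'   assumes independent points at `point_rate`.
#' @param n_perm Permutations for the permutation calibration.
#' @param labels Length-2 names for groups A and B, used in
#'   `lower_group`.
#' @return Object of class `range_decisions`: data.frame with one row per
#'   ordered pair x range: `source`, `sink`, `range`, `n_points`,
#'   `n_differing`, `critical_count`, `significant`, `lower_group`.
#'   `significant` is `n_differing >= critical_count`.
#' @export
compare_groups <- function(A, B, ranges = "full", alpha = 0.05,
                           point_rate = NULL,
                           calibration = c("permutation", "binomial"),
                           n_perm = 200,
                           labels = c("delirium", "control")) {
  stopifnot(inherits(A, "group_rpdc"), inherits(B, "group_rpdc"))
  calibration <- match.arg(calibration)
  if (!identical(A$grid, B$grid)) stop("frequency grid mismatch")
  if (!identical(A$pairs, B$pairs)) stop("pair set mismatch")
  if (is.null(point_rate))
    point_rate <- pointwise_null_rate(A$n, B$n, A$ci)
  rng <- resolve_ranges(ranges)
  sa <- A$stats; sb <- B$stats
  stopifnot(identical(sa$freq, sb$freq), identical(sa$source, sb$source))
  obs <- mutual_exclusion_stats(A$samples, B$samples, A$ci)
  perm <- NULL
  if (calibration == "permutation") {
    pooled <- cbind(A$samples, B$samples)
    nA <- A$n; ntot <- nA + B$n
    old <- get0(".Random.seed", globalenv())
    set.seed(314159L)
    perm <- lapply(seq_len(n_perm), function(i) {
      idx <- sample.int(ntot, nA)
      mutual_exclusion_stats(pooled[, idx, drop = FALSE],
                             pooled[, -idx, drop = FALSE], A$ci)
    })
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
  out <- list()
  for (r in seq_len(nrow(rng))) {
    idx_f <- band_index(A$grid, rng$lo[r], rng$hi[r], rng$hi_inclusive[r])
    if (length(idx_f) == 0L) stop("range ", rng$range[r], " is empty on the grid")
    fset <- A$grid[idx_f]
    for (pr in seq_len(nrow(A$pairs))) {
      sel <- sa$source == A$pairs$source[pr] & sa$sink == A$pairs$sink[pr] &
        sa$freq %in% fset
      np <- sum(sel)
      nd <- sum(obs$flag[sel])
      if (calibration == "binomial") {
        kc <- critical_count(np, point_rate, alpha)
        significant <- nd >= kc
      } else {
        # lexicographic count statistic: the integer part is the number of
        # flagged points; the fractional part breaks ties between equal
        # counts (in particular when the count saturates at n_points) by
        # the mean standardized group separation over the range
        lex <- function(st) sum(st$flag[sel]) +
          mean_sep_frac(st$sep[sel])
        thr <- stats::quantile(vapply(perm, lex, 0), 1 - alpha, type = 1)
        significant <- lex(obs) > thr
        kc <- if (significant) min(nd, floor(thr) + 1L) else floor(thr) + 1L
      }
      dsel <- sel & obs$flag
      lower <- if (nd > 0L) {
        if (mean(sa$mean[dsel]) < mean(sb$mean[dsel])) labels[1] else labels[2]
      } else if (mean(sa$mean[sel]) < mean(sb$mean[sel])) labels[1] else labels[2]
      out[[length(out) + 1L]] <- data.frame(
        source = A$pairs$source[pr], sink = A$pairs$sink[pr],
        range = rng$range[r], n_points = np, n_differing = nd,
        critical_count = as.integer(kc), significant = significant,
        lower_group = lower, stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, out),
            class = c("range_decisions", "data.frame"))
}

mean_sep_frac <- function(sep) {
  s <- mean(sep)
  s / (1 + s)  # maps [0, Inf) to [0, 1): never promotes a lower count
}

# pointwise rule: each group's mean outside the other group's CI;
# also returns the standardized mean separation used for tie-breaking
mutual_exclusion_stats <- function(MA, MB, ci) {
  nA <- ncol(MA); nB <- ncol(MB)
  mA <- rowMeans(MA); mB <- rowMeans(MB)
  vA <- (rowSums(MA^2) - nA * mA^2) / (nA - 1)
  vB <- (rowSums(MB^2) - nB * mB^2) / (nB - 1)
  hA <- stats::qt(1 - (1 - ci) / 2, nA - 1) * sqrt(vA / nA)
  hB <- stats::qt(1 - (1 - ci) / 2, nB - 1) * sqrt(vB / nB)
  d <- abs(mA - mB)
  list(flag = d > pmax(hA, hB),
       sep = d / sqrt(pmax(vA / nA + vB / nB, 1e-300)))
}

resolve_ranges <- function(ranges) {
  if (is.data.frame(ranges)) return(ranges)
  if (identical(ranges, "full"))
    return(data.frame(range = "full", lo = 0.5, hi = 45,
                      hi_inclusive = TRUE, stringsAsFactors = FALSE))
  if (identical(ranges, "bands")) {
    b <- eeg_bands()
    return(data.frame(range = b$band, lo = b$lo, hi = b$hi,
                      hi_inclusive = b$hi_inclusive, stringsAsFactors = FALSE))
  }
  stop("ranges must be 'full', 'bands' or a data.frame")
}

#' @export
print.range_decisions <- function(x, ...) {
  cat("<range_decisions> ", sum(x$significant), "/", nrow(x),
      " pair-range comparisons significant\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Full connectivity analysis for a cohort of epochs
#'
#' Refits the VAR on the requested channel subset for every epoch (rPDC is
#' model dependent: estimates for a connection change when channels are
#' added or removed, so a reduced montage is always refit, never
#' sub-selected from a larger model), pools per-epoch rPDC spectra within
#' each group, and applies the range decision rule.
#'
#' @param epochs_by_group Named list with elements `delirium` and
#'   `control`, each a list of [eeg_epoch()]s (pooled across subjects).
#' @param channels Channel subset (default F3, C3, P3, T7 — the left
#'   hemispheric montage covering all four regions).
#' @param ranges Passed to [compare_groups()].
#' @param order VAR order.
#' @param ci Confidence level; `alpha` range-level significance.
#' @param point_rate Optional pointwise rate override.
#' @return List of class `connectivity_result`: `decisions`
#'   (range_decisions), `group_rpdc` (named list), `channels`, `order`.
#' @export
run_connectivity <- function(epochs_by_group,
                             channels = c("F3", "C3", "P3", "T7"),
                             ranges = "full", order = 16, ci = 0.95,
                             alpha = 0.05, point_rate = NULL,
                             calibration = "permutation") {
  stopifnot(all(c("delirium", "control") %in% names(epochs_by_group)))
  pooled <- lapply(epochs_by_group[c("delirium", "control")], function(eps)
    lapply(eps, function(ep) rpdc(fit_var(ep, channels = channels,
                                          order = order))))
  grp <- lapply(pooled, group_rpdc, ci = ci)
  decisions <- compare_groups(grp$delirium, grp$control, ranges = ranges,
                              alpha = alpha, point_rate = point_rate,
                              calibration = calibration)
  structure(list(decisions = decisions, group_rpdc = grp,
                 channels = channels, order = order),
            class = "connectivity_result")
}

#' @export
print.connectivity_result <- function(x, ...) {
  cat("<connectivity_result> montage ",
      paste(x$channels, collapse = ", "), ", VAR order ", x$order, "\n",
      sep = "")
  print(x$decisions)
  invisible(x)
}

#' Directional detection against the chance level
#'
#' A direction is "detected" when its rPDC exceeds the chance level at
#' more grid points than expected at random. Because lambda across the 90
#' grid frequencies is driven by only 2p coefficient dimensions,
#' exceedances clump strongly under the null (typically none, occasionally
#' a long run), so a binomial count threshold is badly anticonservative.
#' The null distribution of the count is instead obtained by Monte Carlo
#' from the fitted model itself: coefficient vectors are drawn from
#' N(0, R_hat), the pair's estimated coefficient covariance, lambda is
#' recomputed on the grid, and the detection threshold is the (1 - alpha)
#' quantile of the resulting null counts. The draw uses a fixed internal
#' RNG substream and leaves the caller's random state untouched.
#'
#' @param rp An `rpdc_set` from a fitted model.
#' @param source,sink Channel labels of the direction.
#' @param n_draws Null Monte-Carlo draws.
#' @return Logical.
#' @export
rpdc_detected <- function(rp, source, sink, n_draws = 500) {
  v <- rp$values[rp$values$source == source & rp$values$sink == sink, ]
  if (nrow(v) == 0L) stop("no such direction: ", source, " -> ", sink)
  kc <- null_count_quantile(rp, paste0(source, "->", sink),
                            1 - rp$alpha, n_draws)
  sum(v$rpdc > rp$chance_level) > kc
}

# (1 - alpha) quantile of the null exceedance count for one direction,
# by simulation from the estimated coefficient covariance
null_count_quantile <- function(rp, pair_key, prob, n_draws = 500) {
  R <- rp$pair_R[[pair_key]]
  if (is.null(R)) stop("no stored covariance for ", pair_key)
  p <- ncol(R)
  nf <- length(rp$grid)
  # rows 2q-1, 2q = (Re, Im) transform at frequency q, whitened per freq
  B <- matrix(0, 2L * nf, p)
  L <- chol_psd(R)
  for (q in seq_len(nf)) {
    Tq <- rbind(rp$Tcos[q, ], rp$Tsin[q, ])
    V <- Tq %*% R %*% t(Tq)
    V <- V + diag(2) * 1e-12 * (V[1, 1] + V[2, 2])
    W <- backsolve(chol(V), diag(2), transpose = TRUE)  # V^{-1/2}
    B[(2L * q - 1L):(2L * q), ] <- W %*% Tq %*% t(L)
  }
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(271828L)
  U <- matrix(stats::rnorm(p * n_draws), p)
  S <- B %*% U                       # (2 nf) x n_draws
  lam <- S[seq(1, 2 * nf, 2), ]^2 + S[seq(2, 2 * nf, 2), ]^2
  counts <- colSums(lam > rp$chance_level)
  as.numeric(stats::quantile(counts, prob, type = 1))
}

chol_psd <- function(R) {
  out <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(out))
    out <- chol(R + diag(nrow(R)) * 1e-10 * mean(diag(R)))
  out
}
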