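# helper: simulate a stable VAR process from coefficient matrices
simulate_var <- function(A, n, burn = 200L) {
  p <- length(A); k <- nrow(A[[1]])
  Y <- matrix(0, k, n + burn)
  E <- matrix(rnorm(k * (n + burn)), k)
  for (t in (p + 1):(n + burn)) {
    acc <- E[, t]
    for (j in seq_len(p)) acc <- acc + A[[j]] %*% Y[, t - j]
    Y[, t] <- acc
  }
  Y <- Y[, (burn + 1):(burn + n), drop = FALSE]
  rownames(Y) <- paste0("ch", seq_len(k))
  Y
}

test_that("least-squares VAR recovers known coefficients within its own SEs", {
  A <- list(matrix(c(0.5, 0.4, 0.0, 0.3), 2, 2),
            matrix(c(-0.2, 0.1, 0.0, -0.15), 2, 2))
  truth <- c(A[[1]], A[[2]])
  hits <- 0L; total <- 0L
  for (s in 1:40) {
    set.seed(s)
    fit <- fit_var(simulate_var(A, 60 * 256), order = 2,
                   sampling_rate = 256)
    # SE of A_k[i,j]: regressors are lag-major, so its index in
    # equation i's covariance sigma2_i * XtX_inv is j + (k-1)*n
    se_mat <- vapply(1:2, function(i)
      sqrt(diag(fit$sigma2[i] * fit$XtX_inv)), numeric(4))
    for (k in 1:2) for (j in 1:2) for (i in 1:2) {
      se <- se_mat[j + (k - 1) * 2, i]
      ok <- abs(fit$A[[k]][i, j] - A[[k]][i, j]) < 3 * se
      hits <- hits + ok; total <- total + 1L
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("independent channels yield null off-diagonal coefficients", {
  within <- 0L; total <- 0L
  for (s in 1:20) {
    set.seed(300 + s)
    Y <- matrix(rnorm(2 * 60 * 256), 2,
                dimnames = list(c("a", "b"), NULL))
    fit <- fit_var(Y, order = 4, sampling_rate = 256)
    for (k in 1:4) for (i in 1:2) {
      j <- 3 - i
      se <- sqrt(fit$sigma2[i] *
                   diag(fit$XtX_inv)[j + (k - 1) * 2])
      within <- within + (abs(fit$A[[k]][i, j]) < 3 * se)
      total <- total + 1L
    }
  }
  expect_gte(within / total, 0.95)
})

test_that("duplicated channels are rejected as rank deficient", {
  set.seed(14)
  x <- rnorm(8000)
  Y <- rbind(a = x, b = x)
  expect_error(fit_var(Y, order = 2, sampling_rate = 256),
               "rank-deficient")
})

test_that("rPDC of an exactly uncoupled model is zero, below chance", {
  A <- list(diag(c(0.5, -0.3, 0.2)), diag(c(0.1, 0.2, -0.1)))
  rp <- rpdc(var_model(A, sampling_rate = 256))
  expect_equal(nrow(rp$pairs), 6L)
  expect_true(all(rp$values$rpdc == 0))
  expect_true(all(rp$values$rpdc < rp$chance_level))
})

test_that("a model has n(n-1) direction spectra", {
  set.seed(15)
  Y4 <- matrix(rnorm(4 * 8000), 4,
               dimnames = list(c("F3", "C3", "P3", "T7"), NULL))
  expect_equal(nrow(rpdc(fit_var(Y4, order = 4,
                                 sampling_rate = 256))$pairs), 12L)
  Y3 <- Y4[1:3, ]
  expect_equal(nrow(rpdc(fit_var(Y3, order = 4,
                                 sampling_rate = 256))$pairs), 6L)
})

test_that("unidirectional coupling shows up forward, not backward", {
  cfg <- bivariate_config(gain = 0.4, lag = 1)
  fwd <- rev <- numeric(40)
  for (s in 1:40) {
    rp <- rpdc(fit_var(simulate_epoch(cfg, "control", 500 + s), order = 16))
    v <- rp$values
    fwd[s] <- mean(v$rpdc[v$source == "C3" & v$sink == "P3"] >
                     rp$chance_level)
    rev[s] <- mean(v$rpdc[v$source == "P3" & v$sink == "C3"] >
                     rp$chance_level)
  }
  expect_gte(mean(fwd), 0.5)   # forward exceeds chance at most frequencies
  expect_lte(mean(rev), 0.10)  # reverse stays near the nominal rate
})

test_that("the chance level is the chi-square(2) upper quantile", {
  expect_equal(chance_level(0.05), -2 * log(0.05), tolerance = 1e-12)
  expect_lt(chance_level(1 - 1e-12), 1e-10)
  expect_error(chance_level(0), "alpha")
})

test_that("group pooling gives t-based intervals matching closed forms", {
  one <- fake_rpdc_set(list("a->b" = rep(4, 10)))
  g <- group_rpdc(list(one, one, one))
  expect_equal(g$stats$mean, rep(4, 10))
  expect_equal(g$stats$half_width, rep(0, 10))
  a <- fake_rpdc_set(list("a->b" = rep(2, 10)))
  b <- fake_rpdc_set(list("a->b" = rep(6, 10)))
  g2 <- group_rpdc(list(a, b))
  expect_equal(g2$stats$mean, rep(4, 10))
  expect_equal(g2$stats$half_width,
               rep(qt(0.975, 1) * abs(2 - 6) / 2, 10))
  # 15 samples against a brute-force loop
  set.seed(16)
  sets <- lapply(1:15, function(i)
    fake_rpdc_set(list("a->b" = rexp(10))))
  g15 <- group_rpdc(sets)
  for (q in 1:10) {
    vals <- vapply(sets, function(s) s$values$rpdc[q], 0)
    expect_equal(g15$stats$mean[q], mean(vals))
    expect_equal(g15$stats$half_width[q],
                 qt(0.975, 14) * sd(vals) / sqrt(15))
  }
  expect_error(group_rpdc(list(one, fake_rpdc_set(list("b->a" = rep(1, 10))))),
               "mismatched")
})

test_that("identical groups are never significant; forced separation always is", {
  set.seed(17)
  mk_group <- function(mu) lapply(1:15, function(i)
    fake_rpdc_set(list("a->b" = mu + rnorm(10, sd = 0.1)),
                  grid = seq(0.5, 5, 0.5)))
  rng <- data.frame(range = "low", lo = 0.5, hi = 5, hi_inclusive = TRUE)
  A <- group_rpdc(mk_group(2))
  dec_same <- compare_groups(A, A, ranges = rng)
  expect_equal(dec_same$n_differing, 0L)
  expect_false(dec_same$significant)
  B <- group_rpdc(mk_group(50))
  dec_far <- compare_groups(A, B, ranges = rng)
  expect_equal(dec_far$n_differing, dec_far$n_points)
  expect_true(dec_far$significant)
  expect_equal(dec_far$lower_group, "delirium")  # A is the lower group
})

test_that("the pointwise mutual-exclusion rule has the computed null rate", {
  # the quadrature result matches a direct Monte-Carlo of the rule
  p0 <- pointwise_null_rate(15, 15, 0.95)
  expect_gt(p0, 0.05)  # the rule is more liberal than the CI complement
  set.seed(18)
  flags <- replicate(4000, {
    x <- rnorm(15); y <- rnorm(15)
    d <- abs(mean(x) - mean(y))
    d > qt(0.975, 14) * max(sd(x), sd(y)) / sqrt(15)
  })
  expect_lt(abs(mean(flags) - p0), 0.02)
})

test_that("binomial critical counts bound the null tail below alpha", {
  for (n in c(10, 90)) for (p0 in c(0.05, 0.11)) {
    k <- critical_count(n, p0, 0.05)
    expect_lt(pbinom(k - 1, n, p0, lower.tail = FALSE), 0.05)
    expect_gte(pbinom(k - 2, n, p0, lower.tail = FALSE), 0.05)
  }
})

test_that("reduced montages are refit, giving model-dependent strengths", {
  cfg <- sim_config(epochs_per_subject = 1, recording_duration = 60,
                    artifact_rate = 0)
  ep <- select_epochs(simulate_subject(cfg, "control", 21)$recording,
                      n = 1, duration = 60)[[1]]
  rp4 <- rpdc(fit_var(ep, channels = c("F3", "C3", "P3", "T7"), order = 16))
  rp3 <- rpdc(fit_var(ep, channels = c("C3", "P3", "T7"), order = 16))
  expect_equal(nrow(rp4$pairs), 12L)
  expect_equal(nrow(rp3$pairs), 6L)
  shared <- merge(rp4$values, rp3$values,
                  by = c("source", "sink", "freq"))
  expect_gt(max(abs(shared$rpdc.x - shared$rpdc.y)), 1e-6)
  expect_error(fit_var(ep, channels = c("C3", "Oz"), order = 4), "Oz")
})

test_that("run_connectivity produces one decision per pair and range", {
  cfg <- reduced_config(duration = 120)  # two 60 s epochs per subject
  mk_eps <- function(group, base) do.call(c, lapply(1:2, function(i)
    select_epochs(simulate_subject(cfg, group, base + i)$recording,
                  n = 2, duration = 60)))
  by_group <- list(delirium = mk_eps("delirium", 40),
                   control = mk_eps("control", 60))
  cr <- run_connectivity(by_group, channels = c("C3", "P3", "T7"),
                         ranges = "bands")
  expect_equal(nrow(cr$decisions), 6L * 5L)
  expect_true(all(cr$decisions$n_points ==
                    rep(c(7, 8, 10, 14, 51), each = 6)))
  expect_true(all(cr$decisions$n_differing <= cr$decisions$n_points))
  expect_true(all(cr$decisions$significant ==
                    (cr$decisions$n_differing >= cr$decisions$critical_count)))
})
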