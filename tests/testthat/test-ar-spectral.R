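test_that("Burg fit recovers AR(1) coefficients and rejects degenerate input", {
  a_hat <- vapply(1:20, function(s) {
    set.seed(s)
    x <- as.numeric(arima.sim(list(ar = 0.5), 60 * 256))
    fit_ar(x, 256, order = 1)$coef
  }, 0)
  expect_true(all(abs(a_hat - 0.5) < 0.05))
  # empirical SE of a_hat ~ sqrt((1-a^2)/n) ~ 0.007
  expect_lt(abs(mean(a_hat) - 0.5), 3 * sd(a_hat) / sqrt(20))
  # white noise: no spurious structure at order 4
  for (s in 1:20) {
    set.seed(1000 + s)
    expect_true(all(abs(fit_ar(rnorm(60 * 256), 256, order = 4)$coef) < 0.05))
  }
  expect_error(fit_ar(rep(3, 5000), 256), "degenerate")
  expect_error(fit_ar(rnorm(100), 256, order = 64), "too short")
})

test_that("AR spectrum matches closed forms to 1e-9 relative error", {
  grid <- frequency_grid()
  dt <- 1 / 256
  # all-zero coefficients: flat spectrum at sigma^2 * dt exactly
  flat <- ar_spectrum(ar_model(0, 1, 256), grid)
  expect_equal(flat$power, rep(dt, 90), tolerance = 1e-12)
  # AR(1): algebraic form sigma^2 dt / (1 + a^2 - 2 a cos(w dt))
  a <- 0.62; s2 <- 2.5
  sp1 <- ar_spectrum(ar_model(a, s2, 256), grid)
  oracle1 <- s2 * dt / (1 + a^2 - 2 * a * cos(2 * pi * grid * dt))
  expect_lt(max(abs(sp1$power - oracle1) / oracle1), 1e-9)
  # random AR(4): transfer-function oracle via signal::freqz
  set.seed(7)
  repeat {
    cand <- rnorm(4, sd = 0.3)
    if (all(Mod(polyroot(c(1, -cand))) > 1.05)) break
  }
  sp4 <- ar_spectrum(ar_model(cand, 1.7, 256), grid)
  fr <- signal::freqz(1, c(1, -cand), n = 256, Fs = 256)
  oracle4 <- 1.7 * dt * Mod(fr$h[match(grid, fr$f)])^2
  expect_lt(max(abs(sp4$power - oracle4) / oracle4), 1e-9)
})

test_that("a 10 Hz resonator peaks at the 10 Hz grid point", {
  r <- 0.98; th <- 2 * pi * 10 / 256
  sp <- ar_spectrum(ar_model(c(2 * r * cos(th), -r^2), 1, 256))
  expect_equal(sp$freq[which.max(sp$power)], 10)
})

test_that("fitted spectra track the generating model and recover peaks", {
  # long AR(1) realization: fitted spectrum within 10% of closed form
  set.seed(11)
  x <- as.numeric(arima.sim(list(ar = 0.5), 120 * 256))
  sp <- ar_spectrum(fit_ar(x, 256, order = 1))
  oracle <- sp$power * 0  # closed form with the true parameters
  dt <- 1 / 256
  oracle <- 1 * dt / (1 + 0.25 - cos(2 * pi * sp$freq * dt))
  expect_lt(max(abs(sp$power - oracle) / oracle), 0.10)
  # narrowband oscillator peak recovered within one grid step, 20 seeds
  r <- 0.98; th <- 2 * pi * 10 / 256
  for (s in 1:20) {
    set.seed(200 + s)
    y <- as.numeric(arima.sim(list(ar = c(2 * r * cos(th), -r^2)), 60 * 256))
    spk <- ar_spectrum(fit_ar(y, 256))  # default order 64
    expect_lte(abs(spk$freq[which.max(spk$power)] - 10), 0.5)
  }
})

test_that("spectrum averaging is a pointwise mean with grid checking", {
  s1 <- flat_spectrum(2)
  expect_equal(average_spectra(list(s1))$power, s1$power)
  s3 <- power_spectrum(frequency_grid(), 3 * s1$power)
  expect_equal(average_spectra(list(s1, s3))$power, rep(4, 90))
  set.seed(12)
  sps <- lapply(1:3, function(i)
    power_spectrum(frequency_grid(), runif(90)))
  got <- average_spectra(sps)$power
  want <- numeric(90)  # independent accumulation loop
  for (sp in sps) want <- want + sp$power
  expect_equal(got, want / 3, tolerance = 1e-12)
  bad <- power_spectrum(seq(1, 45, 0.5), rep(1, 89))
  expect_error(average_spectra(list(s1, bad)), "grid mismatch")
})

test_that("band powers follow the split normalization and grid counting", {
  bp <- band_power(flat_spectrum())
  # grid-point counting oracle on the flat spectrum
  g <- frequency_grid()
  counts <- c(Delta = sum(g >= 0.5 & g < 4), Theta = sum(g >= 4 & g < 8),
              Alpha = sum(g >= 8 & g < 13), Beta = sum(g >= 13 & g < 20),
              Gamma = sum(g >= 20 & g <= 45))
  expect_equal(counts[["Delta"]], 7L)
  expect_equal(bp$relative_power[bp$band == "Delta"], 100 * 7 / 90)
  expect_equal(bp$relative_power[bp$band == "Theta"], 100 * 8 / 83)
  for (b in c("Alpha", "Beta", "Gamma"))
    expect_equal(bp$relative_power[bp$band == b], 100 * counts[[b]] / 83)
  # all power at one 10 Hz point: Alpha takes everything
  conc <- power_spectrum(g, ifelse(g == 10, 5, 0))
  bpc <- band_power(conc)
  expect_equal(bpc$relative_power[bpc$band == "Alpha"], 100)
  expect_equal(sum(bpc$relative_power[bpc$band %in%
                                        c("Theta", "Beta", "Gamma")]), 0)
})

test_that("relative powers are scale invariant and Theta..Gamma sum to 100", {
  set.seed(13)
  for (i in 1:10) {
    sp <- power_spectrum(frequency_grid(), rexp(90))
    bp <- band_power(sp)
    expect_equal(sum(bp$relative_power[bp$band != "Delta"]), 100,
                 tolerance = 1e-9)
    sc <- power_spectrum(sp$freq, 9 * sp$power)  # amplitude x3 => power x9
    bps <- band_power(sc)
    expect_equal(bps$absolute_power, 9 * bp$absolute_power)
    expect_equal(bps$relative_power, bp$relative_power, tolerance = 1e-12)
    expect_equal(sfpr(sc), sfpr(sp), tolerance = 1e-12)
  }
})

test_that("SFPR splits at 13 Hz and flags an empty fast side", {
  g <- frequency_grid()
  expect_equal(sfpr(flat_spectrum()), 25 / 65)
  balanced <- power_spectrum(g, ifelse(g < 13, 1 / 25, 1 / 65))
  expect_equal(sfpr(balanced), 1)
  slow_only <- power_spectrum(g, ifelse(g < 13, 1, 0))
  expect_identical(sfpr(slow_only), Inf)
})

test_that("the SFPR panel averages the three electrodes and names gaps", {
  g <- frequency_grid()
  mk <- function(ratio) {
    # spectrum engineered so sfpr == ratio
    power_spectrum(g, ifelse(g < 13, ratio / 25, 1 / 65))
  }
  sps <- list(C3 = mk(1), P3 = mk(2), T7 = mk(3))
  pan <- sfpr_panel(sps)
  expect_equal(unname(pan$per_channel), c(1, 2, 3))
  expect_equal(pan$average, 2)
  same <- list(C3 = mk(2), P3 = mk(2), T7 = mk(2))
  expect_equal(sfpr_panel(same)$average, 2)
  expect_error(sfpr_panel(sps[c("C3", "P3")]), "T7")
})

test_that("delirium preset raises the panel SFPR in every seed pair", {
  cfg <- reduced_config(duration = 60)
  for (s in 1:20) {
    del <- simulate_epoch(cfg, "delirium", 4000 + s)
    ctl <- simulate_epoch(cfg, "control", 8000 + s)
    sp_d <- subject_spectra(list(del))
    sp_c <- subject_spectra(list(ctl))
    expect_gt(sfpr_panel(sp_d)$average, sfpr_panel(sp_c)$average)
  }
})
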