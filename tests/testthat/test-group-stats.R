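# independent oracle: balanced two-way ANOVA from cell/margin means
anova_oracle <- function(d) {
  g <- unique(d$group); ch <- unique(d$channel)
  n <- nrow(d) / (length(g) * length(ch))
  gm <- mean(d$value)
  ss_status <- sum(vapply(g, function(a)
    sum((mean(d$value[d$group == a]) - gm)^2) * length(ch) * n, 0))
  ss_chan <- sum(vapply(ch, function(c)
    sum((mean(d$value[d$channel == c]) - gm)^2) * length(g) * n, 0))
  ss_cell <- 0; ss_err <- 0
  for (a in g) for (c in ch) {
    cell <- d$value[d$group == a & d$channel == c]
    ss_cell <- ss_cell + n * (mean(cell) - gm)^2
    ss_err <- ss_err + sum((cell - mean(cell))^2)
  }
  ss_int <- ss_cell - ss_status - ss_chan
  df_err <- nrow(d) - length(g) * length(ch)
  list(F_status = (ss_status / (length(g) - 1)) / (ss_err / df_err),
       F_chan = (ss_chan / (length(ch) - 1)) / (ss_err / df_err),
       F_int = (ss_int / ((length(g) - 1) * (length(ch) - 1))) /
         (ss_err / df_err),
       ss = c(ss_status, ss_chan, ss_int, ss_err),
       ss_total = sum((d$value - gm)^2))
}

test_that("the 2 x 8 x 5 design yields the (1,64) / (7,64) df structure", {
  set.seed(30)
  an <- two_way_anova(random_balanced_table())
  expect_equal(an$effects$df1, c(1L, 7L, 7L))
  expect_equal(unique(an$effects$df2), 64L)
  expect_equal(an$df_error, 64L)
})

test_that("ANOVA F values match the projection oracle; SS decompose", {
  for (s in 1:5) {
    set.seed(40 + s)
    d <- random_balanced_table()
    an <- two_way_anova(d)
    or <- anova_oracle(d)
    expect_equal(an$effects$F, c(or$F_status, or$F_chan, or$F_int),
                 tolerance = 1e-9)
    expect_equal(sum(or$ss), or$ss_total, tolerance = 1e-9)
  }
})

test_that("degenerate and unbalanced tables are handled explicitly", {
  d <- random_balanced_table()
  d$value <- 7
  an <- two_way_anova(d)
  expect_equal(an$effects$F, c(0, 0, 0))
  expect_equal(an$effects$p, c(1, 1, 1))
  expect_error(two_way_anova(d[-1, ]), "unbalanced")
})

test_that("ANOVA status effect holds its nominal size on null tables", {
  set.seed(50)
  hits <- replicate(200, {
    an <- two_way_anova(random_balanced_table())
    an$effects$p[an$effects$effect == "status"] < 0.05
  })
  expect_lt(abs(mean(hits) - 0.05), 0.03)
})

test_that("Bonferroni post-tests use the pooled error and cap at 1", {
  set.seed(60)
  d <- random_balanced_table(channels = 4)
  # make groups identical at ch1, shifted hugely at ch2
  d$value[d$channel == "ch1"] <- rep(d$value[d$channel == "ch1" &
                                               d$group == "control"], 2)
  an0 <- two_way_anova(d)
  shift <- 10 * sqrt(an0$ms_error)
  d$value[d$channel == "ch2" & d$group == "delirium"] <-
    d$value[d$channel == "ch2" & d$group == "delirium"] + shift
  an <- two_way_anova(d)
  pt <- bonferroni_posttests(an)
  expect_equal(pt$t[pt$channel == "ch1"], 0)
  expect_equal(pt$p_adjusted[pt$channel == "ch1"], 1)
  expect_lt(pt$p_adjusted[pt$channel == "ch2"], 0.001)
  expect_equal(pt$df, rep(an$df_error, 4))
  # closed-form t at ch2
  md <- pt$mean_diff[pt$channel == "ch2"]
  expect_equal(pt$t[pt$channel == "ch2"],
               md / sqrt(an$ms_error * 2 / 5), tolerance = 1e-12)
  for (s in 1:5) {
    set.seed(70 + s)
    pr <- bonferroni_posttests(two_way_anova(random_balanced_table()))
    expect_true(all(pr$p_adjusted >= pr$p - 1e-15))
    expect_true(all(pr$p_adjusted <= 1))
  }
})

test_that("exact Mann-Whitney: separation, symmetry, complementarity", {
  mw <- mann_whitney_exact(c(6, 7, 8, 9, 10), c(1, 2, 3, 4, 5))
  expect_equal(mw$p, 2 / 252)
  expect_equal(mw$U, 25)
  perm <- mann_whitney_exact(c(3, 1, 2), c(2, 3, 1))
  expect_equal(perm$p, 1)
  set.seed(80)
  for (i in 1:10) {
    x <- rnorm(5); y <- rnorm(4)
    expect_equal(mann_whitney_exact(x, y)$U + mann_whitney_exact(y, x)$U,
                 20)
  }
})

test_that("exact p matches wilcox.test and a value-level permutation oracle", {
  set.seed(90)
  for (i in 1:10) {
    x <- rnorm(5); y <- rnorm(5)
    expect_equal(mann_whitney_exact(x, y)$p,
                 wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  # with ties: enumerate assignments of the observed values and recompute
  # U by pair counting (x > y counts 1, ties count 1/2)
  u_count <- function(x, y)
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  for (i in 1:5) {
    set.seed(100 + i)
    pool <- sample(rep(1:5, 2), 8)
    x <- pool[1:4]; y <- pool[5:8]
    dev <- abs(u_count(x, y) - 8)   # null mean n1 n2 / 2
    combs <- combn(8, 4)
    devs <- apply(combs, 2, function(idx)
      abs(u_count(pool[idx], pool[-idx]) - 8))
    expect_equal(mann_whitney_exact(x, y)$p, mean(devs >= dev - 1e-9))
  }
})
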