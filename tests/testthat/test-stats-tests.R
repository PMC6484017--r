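test_that("paired t-test handles the degenerate batch-comparison cases", {
  x <- c(1.2, 3.4, 5.6, 7.8)
  r <- paired_t(x, x)
  expect_equal(r$p, 1)
  expect_equal(r$t, 0)

  r2 <- paired_t(c(2, 3, 4, 5), c(1, 2, 3, 4))   # constant nonzero shift
  expect_equal(r2$p, 0)
  expect_true(r2$degenerate)

  r3 <- paired_t(c(1, 2, 3), c(3, 2, 1))          # mean difference zero
  expect_equal(r3$t, 0, tolerance = 1e-12)
  expect_equal(r3$p, 1, tolerance = 1e-12)

  set.seed(6)
  a <- rnorm(20); b <- rnorm(20)
  ref <- t.test(a, b, paired = TRUE)
  got <- paired_t(a, b)
  expect_equal(got$t, unname(ref$statistic))
  expect_equal(got$p, ref$p.value)
  expect_error(paired_t(1:3, 1:4), "equal length")
})

test_that("eta squared matches its definition and edge cases", {
  v <- c(1, 2, 3, 4, 5, 6)
  g <- c(1, 1, 2, 2, 3, 3)
  fit <- lm(v ~ factor(g))
  expect_equal(eta_squared(v, g),
               summary(fit)$r.squared)   # SS_between/SS_total == R^2 of one-way fit
  expect_equal(eta_squared(c(1, 2, 1, 2), c(1, 1, 2, 2)), 0)
  expect_equal(eta_squared(c(1, 1, 5, 5), c(1, 1, 2, 2)), 1)
  expect_error(eta_squared(1:5, rep(1, 5)), "2 groups")
})

test_that("normality battery behaves under the null and against bimodality", {
  mk <- function(values) data.frame(
    subject_id = rep(sprintf("S%03d", seq_len(length(values) / 3)), each = 3),
    age = 30, sex = factor("male", levels = c("female", "male")),
    dental_status = factor("natural", levels = c("natural", "artificial")),
    cgc = 0L, session = rep(1:3, length(values) / 3), vhh = values)

  set.seed(10)
  null_ps <- replicate(60, {
    co <- mk(abs(rnorm(201, 100, 5)))
    r <- normality_battery(co, character(0))
    c(r$ks_p, r$sw_p)
  })
  expect_gte(mean(null_ps > 0.05), 0.9)

  bimodal <- mk(c(rnorm(99, 100, 2), rnorm(102, 112, 2)))
  r <- normality_battery(bimodal, character(0))
  expect_lt(r$sw_p, 0.001)
  expect_lt(r$ks_p, 0.01)

  tiny <- mk(rep(c(1, 2), c(3, 3)) * 1.0)
  w <- capture_warnings(normality_battery(tiny, "session"))
  expect_length(w, 3)   # all three session groups are below the minimum n
  expect_match(w, "skipped", all = TRUE)
})

test_that("Levene test calibrates under the null and detects heteroscedasticity", {
  set.seed(12)
  rej <- mean(replicate(100, {
    v <- rnorm(90); g <- rep(1:3, each = 30)
    levene(v, g)$p < 0.05
  }))
  expect_gt(rej, 0.005); expect_lt(rej, 0.12)

  set.seed(13)
  v <- c(rnorm(100, sd = 1), rnorm(100, sd = 3))
  expect_lt(levene(v, rep(1:2, each = 100))$p, 0.01)

  g2 <- rep(1:2, each = 4)
  expect_equal(levene(c(1, 2, 3, 4, 1, 2, 3, 4), g2)$F, 0)
  expect_error(levene(1:4, rep(1, 4)), "2 groups")
})

test_that("Welch ANOVA reduces to the squared Welch t for two groups", {
  set.seed(14)
  for (i in 1:5) {
    v <- c(rnorm(12, sd = 1), rnorm(20, 1, 3))
    g <- rep(1:2, c(12, 20))
    w <- welch_anova(v, g)
    tt <- t.test(v[g == 1], v[g == 2])
    expect_equal(w$F, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(w$df2, unname(tt$parameter), tolerance = 1e-10)
    expect_equal(w$p, tt$p.value, tolerance = 1e-10)
  }
  expect_equal(welch_anova(c(1, 2, 3, 1, 2, 3), rep(1:2, each = 3))$F, 0)
  expect_error(welch_anova(c(1, 1, 1, 2, 3, 4), rep(1:2, each = 3)),
               "zero-variance")
})

test_that("Games-Howell agrees with Welch t for two groups and is null-stable", {
  set.seed(15)
  v <- c(rnorm(15, sd = 1), rnorm(25, 0.5, 2.5))
  g <- rep(c("a", "b"), c(15, 25))
  gh <- games_howell(v, g)
  tt <- t.test(v[g == "a"], v[g == "b"])
  row <- gh[gh$level_i == "a" & gh$level_j == "b", ]
  expect_equal(row$p_adjusted, tt$p.value, tolerance = 1e-6)
  expect_equal(row$df, unname(tt$parameter), tolerance = 1e-10)

  # equal groups: all adjusted p near 1
  v2 <- rep(c(1, 2, 3, 4), 3)
  g2 <- rep(1:3, each = 4)
  gh2 <- games_howell(v2, g2)
  expect_true(all(gh2$p_adjusted > 0.999))

  # antisymmetry of differences
  expect_equal(gh2$mean_diff[gh2$level_i == "1" & gh2$level_j == "2"],
               -gh2$mean_diff[gh2$level_i == "2" & gh2$level_j == "1"])
})
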