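test_that("descriptives reproduce exact cell statistics", {
  co <- generate_cohort(cohort_spec(n_subjects = 40, seed = 6))
  d <- descriptives(co)
  cell <- co$vhh[co$cgc == 0 & co$session == 1]
  row <- d$mp[d$mp$cgc == 0 & d$mp$session == 1, ]
  expect_equal(row$n, length(cell))
  expect_equal(row$mean, mean(cell))
  expect_equal(row$sd, sd(cell))
  expect_equal(row$min, min(cell))
  # cell n summed over sessions = 3 x subjects
  expect_equal(sum(d$mp$n), nrow(co))
  # age table is per subject
  expect_equal(sum(d$age$n), 40)

  one <- co[co$subject_id == co$subject_id[1], ]
  d1 <- descriptives(one)
  r1 <- d1$mp[d1$mp$n == 1, ][1, ]
  expect_equal(r1$min, r1$max)
  expect_equal(r1$sd, 0)
})

test_that("noise-free cohorts give cell means equal to the linear predictor", {
  sp <- cohort_spec(n_subjects = 30, subject_sd = 0, residual_sd = 0,
                    age_slope = 0, seed = 8)
  co <- generate_cohort(sp)
  d <- descriptives(co)
  beta_s <- c(0, sp$session_effects); beta_c <- c(0, sp$cgc_effects)
  for (i in seq_len(nrow(d$mp))) {
    if (d$mp$n[i] > 0)
      expect_equal(d$mp$mean[i],
                   sp$baseline_vhh + beta_c[d$mp$cgc[i] + 1] +
                     beta_s[d$mp$session[i]])
  }
  # Bonferroni differences recover the generative session contrasts exactly
  b <- bonferroni_pairwise(co)
  expect_equal(b$mean_diff[b$level_i == 1 & b$level_j == 2],
               -sp$session_effects[1])
  expect_equal(b$mean_diff[b$level_i == 2 & b$level_j == 3],
               sp$session_effects[1] - sp$session_effects[2])
})

test_that("split-plot decomposition matches a brute-force cell-means oracle", {
  for (s in 1:50) {
    co <- random_balanced_cohort(n_per_group = 4, seed = 100 + s)
    a <- mixed_anova(co)
    bf <- bruteforce_splitplot(co)
    expect_equal(a$within$SS[1], bf$SS_S, tolerance = 1e-8)
    expect_equal(a$within$SS[2], bf$SS_SG, tolerance = 1e-8)
    expect_equal(a$within$SS[3], bf$SS_E, tolerance = 1e-8)
    expect_equal(a$between$SS[1], bf$SS_G, tolerance = 1e-8)
    expect_equal(a$between$SS[2], bf$SS_EB, tolerance = 1e-8)
  }
})

test_that("unbalanced Type III ANOVA and Mauchly match the multivariate GLM route", {
  co <- generate_cohort(cohort_spec(n_subjects = 120, seed = 11))
  a <- mixed_anova(co)
  wide <- chewmix:::cohort_wide(co)
  mlm <- lm(cbind(s1, s2, s3) ~ factor(cgc), data = wide,
            contrasts = list("factor(cgc)" = "contr.sum"))
  av <- summary(car::Anova(mlm, idata = data.frame(session = factor(1:3)),
                           idesign = ~session, type = 3),
                multivariate = FALSE)
  ut <- av$univariate.tests
  expect_equal(a$within$SS[1], ut["session", "Sum Sq"], tolerance = 1e-10)
  expect_equal(a$within$SS[2], ut["factor(cgc):session", "Sum Sq"],
               tolerance = 1e-10)
  expect_equal(a$within$SS[3], ut["session", "Error SS"], tolerance = 1e-10)
  expect_equal(a$within$F[1], ut["session", "F value"], tolerance = 1e-10)
  expect_equal(a$between$SS[1], ut["factor(cgc)", "Sum Sq"], tolerance = 1e-10)
  expect_equal(a$between$F[1], ut["factor(cgc)", "F value"], tolerance = 1e-10)

  sph <- a$sphericity
  expect_equal(sph$W, av$sphericity.tests["session", "Test statistic"],
               tolerance = 1e-8)
  expect_equal(sph$p, av$sphericity.tests["session", "p-value"],
               tolerance = 1e-6)
  gg_ref <- av$pval.adjustments["session", "GG eps"]
  expect_equal(sph$eps_gg, unname(gg_ref), tolerance = 1e-8)
  # Huynh-Feldt via the split-plot closed form at the reference GG epsilon
  N <- sph$n_subjects; G <- sph$n_groups
  hf_expect <- min(1, (N * 2 * gg_ref - 2) / (2 * (N - G - 2 * gg_ref)))
  expect_equal(sph$eps_hf, unname(hf_expect), tolerance = 1e-8)
  expect_equal(sph$eps_lower, 0.5)
})

test_that("compound-symmetric data are recognised as spherical", {
  co <- generate_cohort(cohort_spec(n_subjects = 500, session_effects = c(0, 0),
                                    seed = 17))
  sph <- mauchly(co)
  expect_lt(abs(sph$eps_gg - 1), 0.02)
  expect_gte(sph$eps_gg, 0.5)
  expect_lte(sph$eps_gg, 1)
  expect_gte(sph$eps_hf, sph$eps_gg)
  expect_lte(sph$eps_hf, 1)
  expect_equal(sph$df, 2)
})

test_that("Bonferroni pairwise table is antisymmetric with capped p-values", {
  co <- generate_cohort(cohort_spec(n_subjects = 50, seed = 19))
  b <- bonferroni_pairwise(co)
  expect_equal(nrow(b), 6)
  for (r in seq_len(nrow(b))) {
    mirror <- b[b$level_i == b$level_j[r] & b$level_j == b$level_i[r], ]
    expect_equal(b$mean_diff[r], -mirror$mean_diff)
    expect_equal(b$se[r], mirror$se)
  }
  expect_true(all(b$p_adjusted >= 0 & b$p_adjusted <= 1))
  expect_true(all(b$ci_low <= b$mean_diff & b$mean_diff <= b$ci_high))
})

test_that("mixed ANOVA rejects structurally invalid cohorts", {
  co <- generate_cohort(cohort_spec(n_subjects = 20, seed = 23))
  broken <- co[-1, ]
  expect_error(mixed_anova(broken), "session")
  one_group <- co; one_group$cgc <- 0
  expect_error(mixed_anova(one_group), "2 between-subject groups")
})
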