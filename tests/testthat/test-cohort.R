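test_that("cohort generator honours the additive noise-free model exactly", {
  sp <- cohort_spec(n_subjects = 20, session_effects = c(0, 0),
                    cgc_effects = c(0, 0), age_slope = 0,
                    subject_sd = 0, residual_sd = 0, seed = 2)
  co <- generate_cohort(sp)
  expect_equal(nrow(co), 60)
  expect_true(all(co$vhh == sp$baseline_vhh))
  # with effects switched on, cell values equal the linear predictor
  sp2 <- cohort_spec(n_subjects = 30, subject_sd = 0, residual_sd = 0, seed = 3)
  co2 <- generate_cohort(sp2)
  beta_s <- c(0, sp2$session_effects)
  beta_c <- c(0, sp2$cgc_effects)
  pred <- sp2$baseline_vhh + beta_c[co2$cgc + 1] + beta_s[co2$session] +
    sp2$age_slope * co2$age
  expect_equal(co2$vhh, pred)
})

test_that("cohort structure and seeding invariants hold", {
  sp <- cohort_spec(n_subjects = 80, seed = 7)
  co <- generate_cohort(sp)
  expect_identical(co, generate_cohort(sp))
  expect_equal(nrow(co), 240)
  expect_true(all(table(co$subject_id) == 3))
  expect_true(all(co$vhh > 0))
  expect_true(all(tapply(co$session, co$subject_id,
                         function(s) all(sort(s) == 1:3))))
  # age group consistent with age
  expect_true(all(co$age_group == 1 + findInterval(co$age, c(24, 44, 64) + 0.5)))
})

test_that("cohort age-group proportions track the design within sampling error", {
  co <- generate_cohort(cohort_spec(n_subjects = 2000, seed = 4))
  props <- table(co$age_group[co$session == 1]) / 2000
  target <- c(71, 53, 70, 71) / 265
  # 4 binomial proportions at n = 2000: 4 SD band
  expect_true(all(abs(props - target) < 4 * sqrt(target * (1 - target) / 2000)))
})

test_that("within-subject residual variance is recoverable from a large cohort", {
  sp <- cohort_spec(n_subjects = 3400, seed = 9)
  co <- generate_cohort(sp)
  beta_s <- c(0, sp$session_effects)
  adj <- co$vhh - beta_s[co$session]
  v <- tapply(adj, co$subject_id, var)   # E[sample var across sessions] = sigma_e^2
  expect_equal(mean(v), sp$residual_sd^2, tolerance = 0.1)
})

test_that("flat consumption-by-age weights remove the age-CGC association", {
  sp <- cohort_spec(cgc_given_age = matrix(rep(c(0.4, 0.3, 0.3), 4), 4,
                                           byrow = TRUE))
  etas <- vapply(1:50, function(s) {
    sp$seed <- s
    co <- generate_cohort(sp)
    s1 <- co[co$session == 1, ]
    eta_squared(s1$age, s1$cgc)
  }, numeric(1))
  expect_lt(mean(etas), 0.05)
})

test_that("cohort CSV writing and supplementary reading round-trip", {
  co <- generate_cohort(cohort_spec(n_subjects = 2, seed = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_supplementary(path, quiet = TRUE)
  expect_equal(back$vhh, co$vhh)
  expect_equal(back$subject_id, co$subject_id)
  expect_equal(as.character(back$sex), as.character(co$sex))
  expect_equal(back$cgc, co$cgc)
})

test_that("supplementary reader normalizes codes and enforces the schema", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id;years;gender;teeth;rate;visit;score",
               "A;30;F;natural;low;1;1.1e7",
               "A;30;F;natural;low;2;1.2e7",
               "A;30;F;natural;low;3;1.3e7",
               "B;70;M;denture;high;1;0.9e7",
               "B;70;M;denture;high;2;1.0e7",
               "B;70;M;denture;high;3;1.1e7"), path)
  map <- list(subject_id = "id", age = "years", sex = "gender",
              dental_status = "teeth", cgc = "rate", session = "visit",
              vhh = "score")
  co <- read_supplementary(path, map, quiet = TRUE)
  expect_equal(nrow(co), 6)
  expect_equal(as.character(co$sex), rep(c("female", "male"), each = 3))
  expect_equal(co$cgc, rep(c(0L, 2L), each = 3))
  expect_equal(as.character(co$dental_status),
               rep(c("natural", "artificial"), each = 3))

  expect_error(read_supplementary(path, list(vhh = "nope"), quiet = TRUE),
               "nope")

  # subject with only two sessions is named in the error
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,age,sex,dental_status,cgc,session,vhh",
               "A,30,f,natural,0,1,1e7", "A,30,f,natural,0,2,1e7",
               "A,30,f,natural,0,3,1e7",
               "B,40,m,natural,1,1,1e7", "B,40,m,natural,1,2,1e7"), path2)
  expect_error(read_supplementary(path2, quiet = TRUE), "B")

  # non-numeric vhh points at the row
  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,age,sex,dental_status,cgc,session,vhh",
               "A,30,f,natural,0,1,1e7", "A,30,f,natural,0,2,oops",
               "A,30,f,natural,0,3,1e7"), path3)
  expect_error(read_supplementary(path3, quiet = TRUE), "row")
})
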