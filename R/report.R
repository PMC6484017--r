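#' Run the full statistical battery on a cohort
#'
#' Executes, in order: descriptive statistics, the age-by-CGC eta-squared
#' association, the normality battery (Lilliefors KS + Shapiro-Wilk per
#' CGC-by-session group and pooled), Mauchly's sphericity test, the mixed
#' ANOVA with the epsilon-correction decision rule, Bonferroni session
#' comparisons, Levene's homogeneity test on the measurement-level values
#' by CGC, the Welch heteroscedastic ANOVA with Games-Howell post hoc
#' comparisons (also at measurement level), and the Gaussian GEE.  The
#' result mirrors the table set of a mixing-test study report:
#' descriptives, the corrected within-subject ANOVA, Bonferroni pairwise,
#' Games-Howell pairwise, and GEE parameter estimates.
#'
#' @param cohort a cohort table.
#' @param gee_corr working correlation for [fit_gee()].
#' @return a list of class `chewmix_report` with elements `descriptives`,
#'   `eta_squared_age_cgc`, `normality`, `normality_pooled`, `sphericity`,
#'   `anova`, `bonferroni`, `levene`, `welch`, `games_howell`, `gee`, and
#'   `decisions` (which epsilon correction fired).
#' @export
build_report <- function(cohort, gee_corr = "independence") {
  validate_cohort(cohort)
  subj <- cohort[cohort$session == 1, ]

  desc <- descriptives(cohort)
  eta <- eta_squared(subj$age, subj$cgc)
  norm <- withCallingHandlers(
    normality_battery(cohort, c("cgc", "session")),
    warning = function(w) invokeRestart("muffleWarning"))
  norm_pooled <- withCallingHandlers(
    normality_battery(cohort, character(0)),
    warning = function(w) invokeRestart("muffleWarning"))
  aov_res <- mixed_anova(cohort)
  bonf <- bonferroni_pairwise(cohort)
  lev <- levene(cohort$vhh, cohort$cgc)
  wel <- welch_anova(cohort$vhh, cohort$cgc)
  gh <- games_howell(cohort$vhh, cohort$cgc)
  gee <- fit_gee(cohort, corr = gee_corr)

  structure(list(
    descriptives = desc,
    eta_squared_age_cgc = eta,
    normality = norm,
    normality_pooled = norm_pooled,
    sphericity = aov_res$sphericity,
    anova = aov_res,
    bonferroni = bonf,
    levene = lev,
    welch = wel,
    games_howell = gh,
    gee = gee,
    decisions = list(
      sphericity_violated = aov_res$sphericity$p < 0.05,
      epsilon_correction = aov_res$correction,
      epsilon = aov_res$epsilon,
      variances_homogeneous = lev$p >= 0.05,
      gee_working_correlation = gee_corr)),
    class = "chewmix_report")
}

#' Serialize a report to CSV tables and JSON
#'
#' Writes the descriptive table (`table3.csv`), the corrected
#' within-subject ANOVA (`table4.csv`), the Bonferroni session comparisons
#' (`table5.csv`), the Games-Howell group comparisons (`table6.csv`), the
#' GEE parameter estimates (`table7.csv`) and the complete report
#' (`report.json`) into `dir`.  Output is deterministic: re-running on the
#' same cohort reproduces the files byte for byte.
#'
#' @param report a `chewmix_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "chewmix_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, f) write.csv(df, file.path(dir, f), row.names = FALSE,
                                 quote = FALSE)
  w(report$descriptives$mp, "table3.csv")
  w(report$anova$within, "table4.csv")
  w(as.data.frame(report$bonferroni), "table5.csv")
  w(as.data.frame(report$games_howell), "table6.csv")
  w(report$gee$coefficients, "table7.csv")
  json <- list(
    eta_squared_age_cgc = report$eta_squared_age_cgc,
    sphericity = unclass(report$sphericity),
    anova_within = report$anova$within,
    anova_between = report$anova$between,
    bonferroni = as.data.frame(report$bonferroni),
    levene = report$levene,
    welch = report$welch,
    games_howell = as.data.frame(report$games_howell),
    gee = list(coefficients = report$gee$coefficients,
               scale = report$gee$scale, corr = report$gee$corr),
    normality = report$normality,
    normality_pooled = report$normality_pooled,
    decisions = report$decisions)
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.chewmix_report <- function(x, ...) {
  fmt_p <- function(p) ifelse(p < 0.001, "<0.001", sprintf("%.3f", p))
  cat("Mixing-test statistical report\n")
  cat(sprintf("  subjects: %d, groups: %d\n",
              x$anova$n_subjects, x$anova$n_groups))
  cat(sprintf("  age~CGC eta^2 = %.3f\n", x$eta_squared_age_cgc))
  s <- x$sphericity
  cat(sprintf("  Mauchly W = %.3f, chi2(%d) = %.3f, p = %s; eps GG = %.3f, HF = %.3f\n",
              s$W, s$df, s$chi2, fmt_p(s$p), s$eps_gg, s$eps_hf))
  cat(sprintf("  correction: %s (epsilon = %.3f)\n",
              x$anova$correction, x$anova$epsilon))
  wi <- x$anova$within
  cat(sprintf("  SESSION F(%.3f, %.3f) = %.3f, p = %s, partial eta^2 = %.3f\n",
              wi$df_corrected[1], wi$df_corrected[3], wi$F[1],
              fmt_p(wi$p[1]), wi$partial_eta_sq[1]))
  cat(sprintf("  SESSION:CGC F(%.3f, %.3f) = %.3f, p = %s\n",
              wi$df_corrected[2], wi$df_corrected[3], wi$F[2], fmt_p(wi$p[2])))
  cat(sprintf("  Levene p = %s; Welch F(%g, %.2f) = %.2f, p = %s\n",
              fmt_p(x$levene$p), x$welch$df1, x$welch$df2, x$welch$F,
              fmt_p(x$welch$p)))
  cat(sprintf("  GEE (%s): see $gee\n", x$gee$corr))
  invisible(x)
}
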