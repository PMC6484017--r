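## Repeated-measures statistical battery for mixing-test cohorts.
##
## The design throughout is a 3 x 3 split plot: SESSION (1..3) within
## subjects, CGC (0..2) between subjects, with unequal group sizes.  All
## within-subject quantities are computed from the multivariate
## formulation: Y is the N x 3 matrix of per-subject session scores, M the
## 3 x 2 orthonormal within-subject contrast basis, and E the pooled
## within-group SSCP of Z = Y M.  Hypothesis sums of squares use Type III
## (unweighted cell means), matching the conventions of mainstream GLM
## repeated-measures software.

# Wide per-subject view: one row per subject with covariates and the three
# session scores s1..s3.
cohort_wide <- function(cohort) {
  validate_cohort(cohort)
  o <- cohort[order(cohort$subject_id, cohort$session), ]
  n <- nrow(o) / 3
  first <- o[seq(1, nrow(o), by = 3), , drop = FALSE]
  wide <- data.frame(first[, setdiff(names(first), c("session", "vhh"))],
                     stringsAsFactors = FALSE)
  wide$s1 <- o$vhh[o$session == 1]
  wide$s2 <- o$vhh[o$session == 2]
  wide$s3 <- o$vhh[o$session == 3]
  rownames(wide) <- NULL
  wide
}

# Orthonormal within-subject contrast basis for k = 3 (normalized Helmert).
contrast_basis <- function() {
  cbind(c(-1, 1, 0) / sqrt(2), c(-1, -1, 2) / sqrt(6))
}

#' Descriptive statistics per consumption group and session
#'
#' Summarizes VhH per (CGC, SESSION) cell and age per CGC group (one value
#' per subject), the layout of the descriptive table of a mixing-test
#' report.
#'
#' @param cohort a cohort table.
#' @return a list of class `mp_descriptives` with data frames `mp`
#'   (columns `cgc`, `session`, `n`, `min`, `max`, `mean`, `sd`) and `age`.
#' @export
descriptives <- function(cohort) {
  validate_cohort(cohort)
  cells <- expand.grid(cgc = 0:2, session = 1:3)
  mp <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    v <- cohort$vhh[cohort$cgc == cells$cgc[i] & cohort$session == cells$session[i]]
    if (!length(v))
      data.frame(cgc = cells$cgc[i], session = cells$session[i], n = 0L,
                 min = NA_real_, max = NA_real_, mean = NA_real_, sd = NA_real_)
    else
      data.frame(cgc = cells$cgc[i], session = cells$session[i],
                 n = length(v), min = min(v), max = max(v), mean = mean(v),
                 sd = if (length(v) > 1) sd(v) else 0)
  }))
  subj <- cohort[cohort$session == 1, ]
  age <- do.call(rbind, lapply(0:2, function(g) {
    a <- subj$age[subj$cgc == g]
    if (!length(a))
      data.frame(cgc = g, n = 0L, min = NA_real_, max = NA_real_,
                 mean = NA_real_, sd = NA_real_)
    else
      data.frame(cgc = g, n = length(a), min = min(a), max = max(a),
                 mean = mean(a), sd = if (length(a) > 1) sd(a) else 0)
  }))
  structure(list(mp = mp[order(mp$cgc, mp$session), ], age = age),
            class = "mp_descriptives")
}

#' Paired t-test with degenerate-case conventions
#'
#' Classical paired t-test, used to check for systematic error between two
#' runs of the image pipeline over the same batch.  Two degenerate cases
#' are defined rather than left as errors: if every difference is exactly
#' zero (identical batches) the result is `t = 0, p = 1`; if the
#' differences are constant but non-zero the test statistic is infinite
#' and `p = 0` is reported with `degenerate = TRUE`.
#'
#' @param x,y numeric vectors of equal length (>= 2).
#' @return a list with `t`, `df`, `p`, `mean_diff`, `degenerate`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least 2 pairs")
  d <- x - y
  if (all(d == 0))
    return(list(t = 0, df = length(d) - 1, p = 1, mean_diff = 0,
                degenerate = FALSE))
  if (sd(d) == 0)
    return(list(t = sign(mean(d)) * Inf, df = length(d) - 1, p = 0,
                mean_diff = mean(d), degenerate = TRUE))
  tt <- t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = unname(tt$estimate), degenerate = FALSE)
}

#' Eta-squared association between a numeric and a categorical variable
#'
#' `eta^2 = SS_between / SS_total`, the proportion of the variance of
#' `values` explained by `groups`; used to quantify the association between
#' age and the habitual consumption group.
#'
#' @param values numeric vector.
#' @param groups categorical vector of the same length, >= 2 non-empty
#'   levels.
#' @return a number in `[0, 1]`.
#' @export
eta_squared <- function(values, groups) {
  groups <- factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  gm <- mean(values)
  ss_total <- sum((values - gm)^2)
  if (ss_total == 0) return(0)
  means <- tapply(values, groups, mean)
  ns <- tabulate(groups)
  ss_between <- sum(ns * (means - gm)^2)
  ss_between / ss_total
}

#' Normality battery (Lilliefors KS and Shapiro-Wilk) per group
#'
#' Applies the Kolmogorov-Smirnov test with the estimated-parameter
#' (Lilliefors) correction and the Shapiro-Wilk test to the VhH values of
#' every group defined by the `grouping` columns.  Groups with fewer than 5
#' observations (the Lilliefors minimum), or with zero variance, are
#' skipped with a warning and reported as `NA`.
#'
#' @param cohort a cohort table.
#' @param grouping character vector of grouping column names; default
#'   `c("cgc", "session")` (per-session values grouped by consumption
#'   rate).  Use `character(0)` for the pooled, ungrouped battery.
#' @return a data frame with one row per group: `group`, `n`, `ks_d`,
#'   `ks_p`, `sw_w`, `sw_p`.
#' @export
normality_battery <- function(cohort, grouping = c("cgc", "session")) {
  validate_cohort(cohort)
  key <- if (length(grouping)) {
    interaction(cohort[grouping], sep = ":", drop = TRUE)
  } else factor(rep("all", nrow(cohort)))
  out <- lapply(levels(key), function(g) {
    v <- cohort$vhh[key == g]
    row <- data.frame(group = g, n = length(v), ks_d = NA_real_,
                      ks_p = NA_real_, sw_w = NA_real_, sw_p = NA_real_,
                      stringsAsFactors = FALSE)
    if (length(v) < 5 || sd(v) == 0) {
      warning(sprintf("group %s skipped (n < 5 or constant values)", g))
      return(row)
    }
    ks <- nortest::lillie.test(v)
    row$ks_d <- unname(ks$statistic); row$ks_p <- ks$p.value
    if (length(v) >= 3 && length(v) <= 5000) {
      sw <- shapiro.test(v)
      row$sw_w <- unname(sw$statistic); row$sw_p <- sw$p.value
    }
    row
  })
  do.call(rbind, out)
}

#' Mauchly's sphericity test and epsilon corrections
#'
#' Tests sphericity of the within-subject (session) covariance from the
#' pooled within-group SSCP of the orthonormalized session contrasts, and
#' returns the Greenhouse-Geisser and Huynh-Feldt epsilon estimates used to
#' deflate the repeated-measures degrees of freedom.  With `k = 3` sessions
#' and `g` between-subject groups, `W` is evaluated against a chi-squared
#' approximation on `k(k-1)/2 - 1 = 2` degrees of freedom using the error
#' degrees of freedom `N - g`; the Huynh-Feldt estimate uses the split-plot
#' formula `((N)(k-1)e - 2) / ((k-1)(N - g - (k-1)e))`, capped at 1.
#'
#' @param cohort a cohort table.
#' @return a list of class `sphericity_result`: `W`, `chi2`, `df`, `p`,
#'   `eps_gg`, `eps_hf`, `eps_lower`, `n_subjects`, `n_groups`.
#' @export
mauchly <- function(cohort) {
  wide <- cohort_wide(cohort)
  Y <- as.matrix(wide[, c("s1", "s2", "s3")])
  g <- factor(wide$cgc)
  g <- droplevels(g)
  N <- nrow(Y); G <- nlevels(g); k <- 3
  if (N <= k) stop("need more subjects than sessions")
  M <- contrast_basis()
  Z <- Y %*% M
  Zc <- Z - apply(Z, 2, ave, g)
  E <- crossprod(Zc)                      # pooled within-group SSCP
  S <- E / (N - G)
  A <- S                                  # already in contrast space (2 x 2)
  W <- det(A) / (sum(diag(A)) / (k - 1))^(k - 1)
  ne <- N - G
  d <- 1 - (2 * (k - 1)^2 + (k - 1) + 2) / (6 * (k - 1) * ne)
  chi2 <- -ne * d * log(W)
  df <- k * (k - 1) / 2 - 1
  p <- pchisq(chi2, df, lower.tail = FALSE)
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  eps_gg <- sum(ev)^2 / ((k - 1) * sum(ev^2))
  eps_hf <- min(1, (N * (k - 1) * eps_gg - 2) /
                  ((k - 1) * (N - G - (k - 1) * eps_gg)))
  structure(list(W = W, chi2 = chi2, df = df, p = p,
                 eps_gg = eps_gg, eps_hf = eps_hf,
                 eps_lower = 1 / (k - 1),
                 n_subjects = N, n_groups = G),
            class = "sphericity_result")
}

# Type III hypothesis SS machinery shared by the mixed ANOVA.
# B: G x q matrix of group means of (possibly transformed) responses,
# n_g: group sizes, L: c x G hypothesis matrix.  Returns trace of the
# hypothesis SSCP.
type3_ss <- function(B, n_g, L) {
  W <- diag(1 / n_g, length(n_g))
  LB <- L %*% B
  H <- t(LB) %*% solve(L %*% W %*% t(L), LB)
  sum(diag(H))
}

#' Mixed (split-plot) ANOVA with sphericity corrections
#'
#' Fits the 3 x 3 mixed ANOVA with SESSION as the within-subject factor and
#' CGC as the between-subjects factor.  Within-subject sums of squares come
#' from the multivariate contrast formulation with Type III (unweighted
#' cell-mean) hypotheses; between-subject groups may be unbalanced, but
#' every subject must have all three sessions.  When Mauchly's test rejects
#' sphericity, the within-subject degrees of freedom are multiplied by the
#' Huynh-Feldt epsilon if the Greenhouse-Geisser estimate exceeds 0.75 and
#' by the Greenhouse-Geisser epsilon otherwise; the table also carries the
#' uncorrected and lower-bound rows.  Partial eta-squared is
#' `SS_effect / (SS_effect + SS_error)`.
#'
#' @param cohort a cohort table.
#' @param sphericity_alpha alpha for the Mauchly gatekeeping decision.
#' @return a list of class `mixed_anova_result`: `within` (data frame with
#'   rows SESSION, SESSION:CGC, Error(SESSION)), `between` (CGC row and its
#'   error), `sphericity`, `correction` (one of `"none"`,
#'   `"greenhouse-geisser"`, `"huynh-feldt"`), `epsilon` (the factor
#'   applied).
#' @export
mixed_anova <- function(cohort, sphericity_alpha = 0.05) {
  wide <- cohort_wide(cohort)
  Y <- as.matrix(wide[, c("s1", "s2", "s3")])
  g <- droplevels(factor(wide$cgc))
  N <- nrow(Y); G <- nlevels(g); k <- 3
  if (G < 2) stop("need at least 2 between-subject groups")
  n_g <- as.vector(table(g))
  if (any(n_g < 2)) stop("each group needs at least 2 subjects")

  M <- contrast_basis()
  Z <- Y %*% M
  B <- apply(Z, 2, function(col) tapply(col, g, mean))   # G x 2 group means
  Zc <- Z - apply(Z, 2, ave, g)
  SS_E <- sum(Zc^2)

  # SESSION: unweighted grand mean of group means (Type III intercept).
  L0 <- matrix(1 / G, 1, G)
  SS_S <- type3_ss(B, n_g, L0)
  # SESSION x CGC: contrasts among groups.
  Lg <- cbind(diag(G - 1), -1)
  SS_SG <- type3_ss(B, n_g, Lg)

  df_s <- k - 1; df_sg <- (k - 1) * (G - 1); df_e <- (k - 1) * (N - G)
  MS_E <- SS_E / df_e
  F_s <- (SS_S / df_s) / MS_E
  F_sg <- (SS_SG / df_sg) / MS_E

  sph <- mauchly(cohort)
  correction <- "none"; eps <- 1
  if (sph$p < sphericity_alpha) {
    if (sph$eps_gg > 0.75) { correction <- "huynh-feldt"; eps <- sph$eps_hf }
    else { correction <- "greenhouse-geisser"; eps <- sph$eps_gg }
  }

  within <- data.frame(
    source = c("SESSION", "SESSION:CGC", "Error(SESSION)"),
    SS = c(SS_S, SS_SG, SS_E),
    df = c(df_s, df_sg, df_e),
    df_corrected = c(df_s, df_sg, df_e) * eps,
    df_lower = c(1, G - 1, N - G),
    MS = c(SS_S / (df_s * eps), SS_SG / (df_sg * eps), SS_E / (df_e * eps)),
    F = c(F_s, F_sg, NA),
    p = c(pf(F_s, df_s * eps, df_e * eps, lower.tail = FALSE),
          pf(F_sg, df_sg * eps, df_e * eps, lower.tail = FALSE),
          NA),
    partial_eta_sq = c(SS_S / (SS_S + SS_E), SS_SG / (SS_SG + SS_E), NA))

  # Between-subjects stratum on the subject means, scaled back by k.
  m_i <- rowMeans(Y)
  m_bar <- tapply(m_i, g, mean)
  SS_G <- k * type3_ss(matrix(m_bar, ncol = 1), n_g, Lg)
  SS_EB <- k * sum((m_i - m_bar[g])^2)
  df_g <- G - 1; df_eb <- N - G
  F_g <- (SS_G / df_g) / (SS_EB / df_eb)
  between <- data.frame(
    source = c("CGC", "Error(between)"),
    SS = c(SS_G, SS_EB), df = c(df_g, df_eb),
    MS = c(SS_G / df_g, SS_EB / df_eb),
    F = c(F_g, NA),
    p = c(pf(F_g, df_g, df_eb, lower.tail = FALSE), NA),
    partial_eta_sq = c(SS_G / (SS_G + SS_EB), NA))

  structure(list(within = within, between = between, sphericity = sph,
                 correction = correction, epsilon = eps,
                 n_subjects = N, n_groups = G),
            class = "mixed_anova_result")
}

#' Bonferroni pairwise session comparisons
#'
#' Pairwise comparisons of the estimated marginal means of SESSION from the
#' mixed ANOVA.  Session EMMs are unweighted averages of the three CGC cell
#' means; the standard error of a difference uses the pooled within-group
#' session covariance, `se^2 = (S_ii + S_jj - 2 S_ij) * sum(1/n_g) / g^2`,
#' on `N - g` degrees of freedom.  P-values are multiplied by the number of
#' pairs (3) and capped at 1; confidence intervals are Bonferroni-adjusted
#' 95% intervals.
#'
#' @param cohort a cohort table.
#' @param conf_level family confidence level, default 0.95.
#' @return a data frame of class `pairwise_table` with both orderings of
#'   every pair: `level_i`, `level_j`, `mean_diff`, `se`, `p_adjusted`,
#'   `ci_low`, `ci_high`, and attribute `adjustment = "bonferroni"`.
#' @export
bonferroni_pairwise <- function(cohort, conf_level = 0.95) {
  wide <- cohort_wide(cohort)
  Y <- as.matrix(wide[, c("s1", "s2", "s3")])
  g <- droplevels(factor(wide$cgc))
  N <- nrow(Y); G <- nlevels(g)
  n_g <- as.vector(table(g))
  cell <- apply(Y, 2, function(col) tapply(col, g, mean))   # G x 3
  emm <- colMeans(cell)                                     # unweighted
  Yc <- Y - apply(Y, 2, ave, g)
  S <- crossprod(Yc) / (N - G)
  c_var <- sum(1 / n_g) / G^2
  df <- N - G
  n_pairs <- 3
  alpha <- 1 - conf_level
  rows <- expand.grid(i = 1:3, j = 1:3)
  rows <- rows[rows$i != rows$j, ]
  out <- do.call(rbind, lapply(seq_len(nrow(rows)), function(r) {
    i <- rows$i[r]; j <- rows$j[r]
    d <- emm[i] - emm[j]
    se <- sqrt((S[i, i] + S[j, j] - 2 * S[i, j]) * c_var)
    tval <- d / se
    p <- min(1, n_pairs * 2 * pt(-abs(tval), df))
    crit <- qt(1 - alpha / (2 * n_pairs), df)
    data.frame(level_i = i, level_j = j, mean_diff = d, se = se,
               t = tval, p_adjusted = p,
               ci_low = d - crit * se, ci_high = d + crit * se)
  }))
  out <- out[order(out$level_i, out$level_j), ]
  rownames(out) <- NULL
  attr(out, "adjustment") <- "bonferroni"
  class(out) <- c("pairwise_table", "data.frame")
  out
}

#' Levene's test for homogeneity of variances
#'
#' Classic (mean-centred) Levene test: a one-way ANOVA on the absolute
#' deviations from the group means, delegated to `car::leveneTest()`.
#'
#' @param values numeric vector.
#' @param groups categorical vector, >= 2 non-empty groups.
#' @return a list with `F`, `df1`, `df2`, `p`.
#' @export
levene <- function(values, groups) {
  groups <- droplevels(factor(groups))
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  lt <- car::leveneTest(values, groups, center = mean)
  list(F = lt[1, "F value"], df1 = lt[1, "Df"], df2 = lt[2, "Df"],
       p = lt[1, "Pr(>F)"])
}

#' Welch's heteroscedastic one-way ANOVA
#'
#' Welch's F test for equality of group means without assuming equal
#' variances (Welch-Satterthwaite denominator degrees of freedom);
#' delegated to `stats::oneway.test()`.  Used on the measurement-level VhH
#' values grouped by CGC when Levene's test rejects homogeneity.
#'
#' @param values numeric vector.
#' @param groups categorical vector; every group needs `n >= 2` and
#'   non-zero variance.
#' @return a list with `F`, `df1`, `df2`, `p`.
#' @export
welch_anova <- function(values, groups) {
  groups <- droplevels(factor(groups))
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  ns <- tapply(values, groups, length)
  vs <- tapply(values, groups, var)
  if (any(ns < 2)) stop("every group needs at least 2 observations")
  if (any(vs == 0)) stop("zero-variance group")
  ow <- oneway.test(values ~ groups, var.equal = FALSE)
  list(F = unname(ow$statistic), df1 = unname(ow$parameter[1]),
       df2 = unname(ow$parameter[2]), p = ow$p.value)
}

#' Games-Howell post hoc pairwise comparisons
#'
#' All pairwise group comparisons under unequal variances and group sizes:
#' Welch standard errors, pair-specific Welch-Satterthwaite degrees of
#' freedom, and p-values/intervals from the studentized range distribution
#' with the full number of groups.
#'
#' @param values numeric vector.
#' @param groups categorical vector (same preconditions as
#'   [welch_anova()]).
#' @param conf_level confidence level, default 0.95.
#' @return a data frame of class `pairwise_table` with both orderings of
#'   every pair and attribute `adjustment = "games_howell"`.
#' @export
games_howell <- function(values, groups, conf_level = 0.95) {
  groups <- droplevels(factor(groups))
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  lev <- levels(groups)
  ns <- tapply(values, groups, length)
  vs <- tapply(values, groups, var)
  ms <- tapply(values, groups, mean)
  if (any(ns < 2)) stop("every group needs at least 2 observations")
  if (any(vs == 0)) stop("zero-variance group")
  G <- length(lev)
  rows <- expand.grid(i = seq_len(G), j = seq_len(G))
  rows <- rows[rows$i != rows$j, ]
  out <- do.call(rbind, lapply(seq_len(nrow(rows)), function(r) {
    i <- rows$i[r]; j <- rows$j[r]
    d <- ms[i] - ms[j]
    a <- vs[i] / ns[i]; b <- vs[j] / ns[j]
    se <- sqrt(a + b)
    df <- (a + b)^2 / (a^2 / (ns[i] - 1) + b^2 / (ns[j] - 1))
    q <- abs(d) / se * sqrt(2)
    p <- ptukey(q, G, df, lower.tail = FALSE)
    crit <- qtukey(conf_level, G, df) / sqrt(2)
    data.frame(level_i = lev[i], level_j = lev[j], mean_diff = unname(d),
               se = unname(se), df = unname(df), p_adjusted = unname(p),
               ci_low = unname(d - crit * se), ci_high = unname(d + crit * se),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$level_i, out$level_j), ]
  rownames(out) <- NULL
  attr(out, "adjustment") <- "games_howell"
  class(out) <- c("pairwise_table", "data.frame")
  out
}
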