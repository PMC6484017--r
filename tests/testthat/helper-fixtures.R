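# Shared fixtures: all synthetic, generated in code at test time.

# Bolus pixels of a wafer via its ground-truth mask (bypasses segmentation).
truth_pixels <- function(w) {
  cbind(w$image[, , 1][w$mask], w$image[, , 2][w$mask], w$image[, , 3][w$mask])
}

vhh_of_wafer <- function(w, bins = 256) {
  h <- rgb_to_hue(truth_pixels(w))
  vhh(hue_histogram(h$hue, bins))
}

# Small wafer spec for fast segmentation tests.
small_wafer <- function(...) {
  wafer_spec(width_px = 96, height_px = 96, blob_radius_px = 30,
             patch_scale_px = 8, ...)
}

# A balanced small cohort with arbitrary values; used by the ANOVA oracle.
random_balanced_cohort <- function(n_per_group = 4, seed = 1) {
  set.seed(seed)
  n <- 3 * n_per_group
  data.frame(
    subject_id = rep(sprintf("S%02d", 1:n), each = 3),
    age = rep(sample(20:80, n, replace = TRUE), each = 3),
    sex = factor(rep(sample(c("female", "male"), n, replace = TRUE), each = 3),
                 levels = c("female", "male")),
    dental_status = factor(rep("natural", 3 * n),
                           levels = c("natural", "artificial")),
    cgc = rep(rep(0:2, each = n_per_group), each = 3),
    session = rep(1:3, n),
    vhh = exp(rnorm(3 * n, log(1e7), 0.2)))
}

# Brute-force balanced split-plot decomposition from cell means; an
# independent route to the same sums of squares as mixed_anova().
bruteforce_splitplot <- function(cohort) {
  y <- cohort$vhh
  subj <- cohort$subject_id
  g <- cohort$cgc
  s <- cohort$session
  ym <- mean(y)
  ys <- tapply(y, s, mean)
  ygs <- tapply(y, list(g, s), mean)
  yg <- tapply(y, g, mean)
  yi <- tapply(y, subj, mean)
  gi <- tapply(g, subj, function(v) v[1])
  n_per <- length(unique(subj)) / length(unique(g))
  SS_S <- 3 * n_per * sum((ys - ym)^2)  # 3 groups, balanced
  SS_SG <- n_per * sum((ygs - matrix(yg, 3, 3) -
                          matrix(ys, 3, 3, byrow = TRUE) + ym)^2)
  resid <- y - yi[subj] - ygs[cbind(as.character(g), as.character(s))] +
    yg[as.character(g)]
  SS_E <- sum(resid^2)
  SS_G <- 3 * n_per * sum((yg - ym)^2)
  SS_EB <- 3 * sum((yi - yg[as.character(gi)])^2)
  list(SS_S = SS_S, SS_SG = SS_SG, SS_E = SS_E, SS_G = SS_G, SS_EB = SS_EB)
}

# Null cohort generator with an explicit within-subject covariance (for
# sphericity-related simulations); covariates are inert.
null_cohort <- function(N, chol_sigma) {
  Y <- matrix(rnorm(N * 3), N) %*% chol_sigma
  data.frame(
    subject_id = rep(sprintf("S%03d", 1:N), each = 3),
    age = rep(30, 3 * N),
    sex = factor(rep("male", 3 * N), levels = c("female", "male")),
    dental_status = factor(rep("natural", 3 * N),
                           levels = c("natural", "artificial")),
    cgc = rep(rep(0:2, each = N / 3), each = 3),
    session = rep(1:3, N),
    vhh = as.vector(t(Y)) + 100)
}
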