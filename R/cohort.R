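#' Specification of a synthetic longitudinal cohort
#'
#' Describes the generative model for a synthetic mixing-test cohort: each
#' subject carries demographic covariates (age, sex, dental status and the
#' habitual chewing-gum consumption group CGC) and contributes one VhH
#' masticatory-performance value at each of three sessions.  The VhH model
#' is additive,
#' \deqn{vhh_{is} = \beta_0 + \beta_c(cgc_i) + \beta_s(s) + \beta_{age} \cdot
#'   age_i + b_i + \varepsilon_{is},}
#' with a Gaussian subject intercept `b_i ~ N(0, subject_sd^2)` and i.i.d.
#' residuals `N(0, residual_sd^2)` — exactly the marginal structure the GEE
#' and mixed-ANOVA battery assumes.  Age groups, their proportions, and the
#' strong age-to-CGC gradient (older subjects consume fewer gums, to the
#' point that the oldest group contains essentially no high consumers)
#' default to the demographic profile of a 265-subject clinical sample.
#'
#' @param n_subjects number of subjects (3 rows each in the output).
#' @param age_group_edges inclusive upper ages of the first three age
#'   groups; group 4 is everyone older.
#' @param age_range overall age span in years.
#' @param age_group_probs marginal probability of each of the 4 age groups.
#' @param cgc_given_age 4 x 3 row-stochastic matrix, `P(CGC = 0,1,2 | age
#'   group)`; rows must sum to 1.
#' @param p_artificial_given_age probability of artificial dentures per age
#'   group.
#' @param p_male probability of male sex.
#' @param baseline_vhh intercept `beta_0` in VhH units.
#' @param session_effects `beta_s` for sessions 2 and 3 (session 1 = 0).
#' @param cgc_effects `beta_c` for CGC 1 and 2 (CGC 0 = 0).
#' @param age_slope `beta_age`, VhH units per year (negative: performance
#'   declines with age).
#' @param subject_sd,residual_sd between-subject and residual SDs, VhH
#'   units; both must be positive (set them to machine-zero via `1e-12`
#'   rather than 0 if a degenerate cohort is needed — or use 0, which is
#'   accepted for exact closed-form checks).
#' @param seed integer seed.
#' @return an object of class `cohort_spec`.
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_subjects = 265,
                        age_group_edges = c(24, 44, 64),
                        age_range = c(18, 90),
                        age_group_probs = c(71, 53, 70, 71) / 265,
                        cgc_given_age = rbind(c(7, 31, 33) / 71,
                                              c(28, 12, 13) / 53,
                                              c(57, 9, 4) / 70,
                                              c(70, 1, 0) / 71),
                        p_artificial_given_age = c(0, 4 / 53, 23 / 70, 31 / 71),
                        p_male = 143 / 265,
                        baseline_vhh = 2.0e7,
                        session_effects = c(8.5e5, 9.4e5),
                        cgc_effects = c(2.0e6, 3.2e6),
                        age_slope = -4.5e4,
                        subject_sd = 1.2e6,
                        residual_sd = 8e5,
                        seed = NULL) {
  spec <- list(n_subjects = n_subjects, age_group_edges = age_group_edges,
               age_range = age_range, age_group_probs = age_group_probs,
               cgc_given_age = cgc_given_age,
               p_artificial_given_age = p_artificial_given_age,
               p_male = p_male, baseline_vhh = baseline_vhh,
               session_effects = session_effects, cgc_effects = cgc_effects,
               age_slope = age_slope, subject_sd = subject_sd,
               residual_sd = residual_sd, seed = seed)
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  with(spec, {
    if (n_subjects < 1) stop("n_subjects must be >= 1")
    if (any(abs(rowSums(cgc_given_age) - 1) > 1e-8))
      stop("cgc_given_age rows must sum to 1")
    if (abs(sum(age_group_probs) - 1) > 1e-8)
      stop("age_group_probs must sum to 1")
    if (any(p_artificial_given_age < 0 | p_artificial_given_age > 1))
      stop("p_artificial_given_age must be probabilities")
    if (subject_sd < 0 || residual_sd < 0)
      stop("subject_sd and residual_sd must be non-negative")
    if (length(session_effects) != 2 || length(cgc_effects) != 2)
      stop("session_effects and cgc_effects must each have length 2")
  })
  invisible(spec)
}

#' Generate a synthetic mixing-test cohort
#'
#' Draws a cohort from a [cohort_spec()]: an age group per subject (ages
#' uniform integers within group bounds), sex, dental status and CGC
#' conditional on age group, then three VhH measurements per subject from
#' the additive subject-intercept model.
#'
#' @param spec a [cohort_spec()].
#' @return a long-format `data.frame` (a cohort table) with columns
#'   `subject_id`, `age`, `age_group`, `sex`, `dental_status`, `cgc`,
#'   `session`, `vhh` — exactly 3 rows per subject, one per session.
#' @examples
#' head(generate_cohort(cohort_spec(n_subjects = 5, seed = 1)))
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  validate_cohort_spec(spec)
  with_seed(spec$seed, {
    n <- spec$n_subjects
    edges <- spec$age_group_edges
    lo <- c(spec$age_range[1], edges + 1)
    hi <- c(edges, spec$age_range[2])
    ag <- sample.int(4L, n, replace = TRUE, prob = spec$age_group_probs)
    age <- lo[ag] + floor(runif(n) * (hi[ag] - lo[ag] + 1))
    sex <- ifelse(runif(n) < spec$p_male, "male", "female")
    ds <- ifelse(runif(n) < spec$p_artificial_given_age[ag],
                 "artificial", "natural")
    cgc <- vapply(seq_len(n), function(i)
      sample(0:2, 1, prob = spec$cgc_given_age[ag[i], ]), integer(1))
    b <- rnorm(n, 0, spec$subject_sd)

    subj <- data.frame(
      subject_id = sprintf("S%04d", seq_len(n)),
      age = age, age_group = ag,
      sex = factor(sex, levels = c("female", "male")),
      dental_status = factor(ds, levels = c("natural", "artificial")),
      cgc = cgc, stringsAsFactors = FALSE)

    out <- subj[rep(seq_len(n), each = 3), ]
    out$session <- rep(1:3, n)
    beta_s <- c(0, spec$session_effects)
    beta_c <- c(0, spec$cgc_effects)
    out$vhh <- spec$baseline_vhh + beta_c[out$cgc + 1] + beta_s[out$session] +
      spec$age_slope * out$age + b[rep(seq_len(n), each = 3)] +
      rnorm(3 * n, 0, spec$residual_sd)
    rownames(out) <- NULL
    validate_cohort(out)
    out
  })
}

#' Validate a cohort table
#'
#' Checks the structural invariants of a long-format cohort table: required
#' columns, exactly three sessions (1, 2, 3) per subject, constant
#' covariates within subject, and positive VhH.
#'
#' @param cohort a cohort `data.frame` as produced by [generate_cohort()] or
#'   [read_supplementary()].
#' @return the cohort, invisibly; errors describe the offending subjects or
#'   rows.
#' @export
validate_cohort <- function(cohort) {
  req <- c("subject_id", "age", "sex", "dental_status", "cgc", "session", "vhh")
  miss <- setdiff(req, names(cohort))
  if (length(miss)) stop("cohort table is missing columns: ",
                         paste(miss, collapse = ", "))
  if (!is.numeric(cohort$vhh)) stop("vhh must be numeric")
  if (any(!is.finite(cohort$vhh)) || any(cohort$vhh <= 0))
    stop("vhh must be finite and positive; offending rows: ",
         paste(utils::head(which(!is.finite(cohort$vhh) | cohort$vhh <= 0), 5),
               collapse = ", "))
  if (!all(cohort$session %in% 1:3)) stop("session must be 1, 2 or 3")
  if (!all(cohort$cgc %in% 0:2)) stop("cgc must be 0, 1 or 2")
  tab <- table(cohort$subject_id)
  bad <- names(tab)[tab != 3]
  sess_ok <- tapply(cohort$session, cohort$subject_id,
                    function(s) length(s) == 3 && all(sort(s) == 1:3))
  bad <- union(bad, names(sess_ok)[!sess_ok])
  if (length(bad))
    stop("subjects without exactly one row per session 1..3: ",
         paste(sort(bad), collapse = ", "))
  invisible(cohort)
}

#' Read and write cohort tables
#'
#' `write_cohort()` serializes a cohort table as a plain CSV with the
#' canonical header `subject_id,age,age_group,sex,dental_status,cgc,session,
#' vhh`.  `read_supplementary()` reads a deposited per-subject dataset whose
#' column layout is not fixed: `column_map` names, for each canonical field,
#' the column that holds it in the file.  Categorical codes are normalized
#' (`f`/`female`/`0` to female, `low`/`medium`/`high` or `0`/`1`/`2` to CGC
#' 0..2, `natural`/`artificial` or `0`/`1` dental status), and the result is
#' validated with [validate_cohort()].  Comma-, semicolon- and tab-delimited
#' files are sniffed from the header line.
#'
#' @param cohort a cohort table.
#' @param path file path.
#' @param column_map named list mapping the canonical fields `subject_id`,
#'   `age`, `sex`, `dental_status`, `cgc`, `session`, `vhh` (and optionally
#'   `age_group`) to column names in the file.  Defaults to the canonical
#'   names themselves.
#' @param quiet suppress the row/subject count message.
#' @return `read_supplementary()` returns a validated cohort `data.frame`.
#' @export
read_supplementary <- function(path, column_map = list(), quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  defaults <- list(subject_id = "subject_id", age = "age", sex = "sex",
                   dental_status = "dental_status", cgc = "cgc",
                   session = "session", vhh = "vhh")
  map <- utils::modifyList(defaults, column_map[names(column_map) != "age_group"])

  header <- readLines(path, n = 1L)
  seps <- c("," = lengths(regmatches(header, gregexpr(",", header))),
            ";" = lengths(regmatches(header, gregexpr(";", header))),
            "\t" = lengths(regmatches(header, gregexpr("\t", header))))
  sep <- names(which.max(seps))
  raw <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)

  missing_cols <- unlist(map)[!unlist(map) %in% names(raw)]
  if (length(missing_cols))
    stop("mapped column(s) not found in file: ",
         paste(missing_cols, collapse = ", "))

  norm_sex <- function(x) {
    x <- tolower(trimws(as.character(x)))
    out <- ifelse(x %in% c("f", "female", "0", "w"), "female",
                  ifelse(x %in% c("m", "male", "1"), "male", NA))
    if (anyNA(out)) stop("unrecognized sex codes: ",
                         paste(unique(x[is.na(out)]), collapse = ", "))
    factor(out, levels = c("female", "male"))
  }
  norm_ds <- function(x) {
    x <- tolower(trimws(as.character(x)))
    out <- ifelse(x %in% c("natural", "n", "0"), "natural",
                  ifelse(x %in% c("artificial", "a", "1", "denture"),
                         "artificial", NA))
    if (anyNA(out)) stop("unrecognized dental status codes: ",
                         paste(unique(x[is.na(out)]), collapse = ", "))
    factor(out, levels = c("natural", "artificial"))
  }
  norm_cgc <- function(x) {
    x <- tolower(trimws(as.character(x)))
    out <- ifelse(x %in% c("0", "low"), 0L,
                  ifelse(x %in% c("1", "medium"), 1L,
                         ifelse(x %in% c("2", "high"), 2L, NA)))
    if (anyNA(out)) stop("unrecognized cgc codes: ",
                         paste(unique(x[is.na(out)]), collapse = ", "))
    out
  }

  vhh_raw <- raw[[map$vhh]]
  vhh <- suppressWarnings(as.numeric(vhh_raw))
  if (anyNA(vhh))
    stop("non-numeric vhh at row(s): ",
         paste(utils::head(which(is.na(vhh)), 10), collapse = ", "))

  out <- data.frame(
    subject_id = as.character(raw[[map$subject_id]]),
    age = as.numeric(raw[[map$age]]),
    sex = norm_sex(raw[[map$sex]]),
    dental_status = norm_ds(raw[[map$dental_status]]),
    cgc = norm_cgc(raw[[map$cgc]]),
    session = as.integer(raw[[map$session]]),
    vhh = vhh, stringsAsFactors = FALSE)
  out$age_group <- 1L + findInterval(out$age, c(24, 44, 64) + 0.5)
  out <- out[, c("subject_id", "age", "age_group", "sex", "dental_status",
                 "cgc", "session", "vhh")]
  validate_cohort(out)
  if (!quiet)
    message(sprintf("read %d rows, %d subjects from %s",
                    nrow(out), length(unique(out$subject_id)), path))
  out
}

#' @rdname read_supplementary
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  cols <- c("subject_id", "age", "age_group", "sex", "dental_status",
            "cgc", "session", "vhh")
  cols <- intersect(cols, names(cohort))
  write.csv(cohort[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
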