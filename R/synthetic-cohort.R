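#' Configuration for the synthetic clinical cohort generator
#'
#' Defines the population structure of a simulated neovascular AMD cohort
#' treated with an aflibercept loading-phase: demographics, treatment-protocol
#' mix, and a logistic outcome model on standardised baseline covariates.
#' Defaults follow the population the downstream analysis assumes: mean age
#' 80 (SD 8) years, residual-fluid prevalence 59.3% under the standard
#' protocol and 37.5% under the short protocol, older age and female sex
#' protective, higher (log) central subfield thickness harmful.
#'
#' @param n_patients number of patients to simulate.
#' @param second_eye_prob probability that a patient contributes both eyes.
#' @param prevalence_standard target residual-fluid prevalence among
#'   standard-protocol eyes.
#' @param prevalence_short target prevalence among short-protocol eyes.
#' @param short_protocol_prob probability a patient is treated under the
#'   short protocol.
#' @param age_mean,age_sd age distribution in years (truncated to 50--100).
#' @param effect_age log-odds of residual fluid per SD of age (negative:
#'   older patients respond better).
#' @param effect_sex_female log-odds for female vs male sex (negative:
#'   protective).
#' @param effect_logcst log-odds per SD of log central subfield thickness
#'   (positive: thicker maculae respond worse).
#' @param n_clinics number of recruiting clinics (uniform categorical).
#' @param seed integer seed; fixes every draw of the generator.
#' @return an object of class `cohort_config`.
#' @seealso [generate_synthetic_cohort()]
#' @export
cohort_config <- function(n_patients,
                          second_eye_prob = 0.067,
                          prevalence_standard = 0.593,
                          prevalence_short = 0.375,
                          short_protocol_prob = 0.32,
                          age_mean = 80, age_sd = 8,
                          effect_age = -0.5,
                          effect_sex_female = -0.35,
                          effect_logcst = 0.5,
                          n_clinics = 10,
                          seed = 1L) {
  check_count(n_patients, "n_patients")
  check_prob(second_eye_prob, "second_eye_prob")
  check_prob(prevalence_standard, "prevalence_standard")
  check_prob(prevalence_short, "prevalence_short")
  check_prob(short_protocol_prob, "short_protocol_prob")
  check_count(n_clinics, "n_clinics")
  if (!is.numeric(age_sd) || age_sd <= 0) stop_config("'age_sd' must be > 0")
  structure(list(
    n_patients = as.integer(n_patients),
    second_eye_prob = second_eye_prob,
    prevalence_standard = prevalence_standard,
    prevalence_short = prevalence_short,
    short_protocol_prob = short_protocol_prob,
    age_mean = age_mean, age_sd = age_sd,
    effect_age = effect_age,
    effect_sex_female = effect_sex_female,
    effect_logcst = effect_logcst,
    n_clinics = as.integer(n_clinics),
    seed = as.integer(seed)
  ), class = "cohort_config")
}

# Solve the intercept of the logistic outcome model by bisection so that the
# mean predicted probability over the realised covariates equals `target`.
# Lets effect sizes and prevalence be configured independently.
solve_logit_intercept <- function(eta, target, tol = 1e-10) {
  f <- function(b0) mean(sigmoid(b0 + eta)) - target
  lo <- -30; hi <- 30
  if (f(lo) > 0 || f(hi) < 0) stop_config("prevalence target unattainable")
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# protocol timing distributions (days): therapy course = first injection to
# final observation; gap = third injection to final observation.
protocol_windows <- list(
  standard = list(course = c(105L, 135L), gap = c(49L, 70L),
                  course_mean = 117, course_sd = 6, gap_mean = 58, gap_sd = 3),
  short    = list(course = c(75L, 104L), gap = c(21L, 48L),
                  course_mean = 91, course_sd = 6, gap_mean = 32, gap_sd = 6)
)

draw_in_window <- function(n, mean, sd, window) {
  pmin(pmax(round_half_up(stats::rnorm(n, mean, sd)), window[1]), window[2])
}

#' Generate a synthetic clinical cohort of eye records
#'
#' Simulates per-eye baseline records (demographics, visual acuity, central
#' subfield thickness, total retinal volume, injection and observation dates)
#' together with a binary residual-fluid outcome drawn from a logistic model
#' on standardised age, sex, and log-CST. The model intercept is solved
#' numerically (bisection per protocol) so that the expected prevalence over
#' the realised covariates matches the configured target exactly; the
#' realised prevalence then fluctuates with binomial sampling noise only.
#'
#' Dates are consistent with the assigned protocol: therapy course and the
#' final third-injection-to-observation gap are drawn from the protocol's
#' timing distribution and clamped to its defining day window (standard:
#' course 105--135 d, gap 49--70 d; short: course 75--104 d, gap 21--48 d).
#'
#' @param config a [cohort_config()] object.
#' @return a `data.frame` of class `eye_cohort`, one row per eye, with
#'   columns `patient_id`, `eye_id`, `clinic`, `age`, `sex`, `ethnicity`,
#'   `va_letters`, `cst` (micrometres), `trv` (mm^3),
#'   `injection_date_1..3`, `baseline_date`, `final_date`, `protocol`,
#'   `outcome` (1 = residual macular fluid), `n_scans`, `has_imaging`.
#' @examples
#' cohort <- generate_synthetic_cohort(cohort_config(50, seed = 7))
#' table(cohort$protocol, cohort$outcome)
#' @export
generate_synthetic_cohort <- function(config) {
  if (!inherits(config, "cohort_config"))
    stop_config("'config' must be created by cohort_config()")
  set.seed(config$seed)
  np <- config$n_patients

  two_eyes <- stats::runif(np) < config$second_eye_prob
  n_eyes_pp <- ifelse(two_eyes, 2L, 1L)
  patient_id <- sprintf("P%05d", seq_len(np))

  # patient-level covariates
  age <- pmin(pmax(stats::rnorm(np, config$age_mean, config$age_sd), 50), 100)
  sex <- ifelse(stats::runif(np) < 0.62, "F", "M")
  ethnicity <- sample(c("White", "South Asian", "Other"), np, replace = TRUE,
                      prob = c(0.915, 0.005, 0.08))
  clinic <- sprintf("C%02d", sample.int(config$n_clinics, np, replace = TRUE))
  protocol <- ifelse(stats::runif(np) < config$short_protocol_prob,
                     "short", "standard")

  idx <- rep(seq_len(np), n_eyes_pp)
  eye_no <- sequence(n_eyes_pp)
  n <- length(idx)
  eye_id <- paste0(patient_id[idx], "-", c("OD", "OS")[eye_no])

  # eye-level baseline measurements
  log_cst <- stats::rnorm(n, log(350), 0.25)
  cst <- exp(log_cst)
  trv <- pmax(stats::rnorm(n, 9.5, 1.5), 3)
  va <- pmin(pmax(round_half_up(stats::rnorm(n, 58, 13)), 0), 100)
  n_scans <- sample(c(19L, 25L, 31L, 49L), n, replace = TRUE,
                    prob = c(0.15, 0.35, 0.2, 0.3))

  # outcome model on standardised covariates (population scale, not sample)
  z_age <- (age[idx] - config$age_mean) / config$age_sd
  z_lcst <- (log_cst - log(350)) / 0.25
  eta <- config$effect_age * z_age +
    config$effect_sex_female * (sex[idx] == "F") +
    config$effect_logcst * z_lcst
  prot_eye <- protocol[idx]
  outcome <- integer(n)
  for (p in c("standard", "short")) {
    sel <- prot_eye == p
    if (!any(sel)) next
    target <- if (p == "standard") config$prevalence_standard else
      config$prevalence_short
    b0 <- solve_logit_intercept(eta[sel], target)
    outcome[sel] <- as.integer(stats::runif(sum(sel)) < sigmoid(b0 + eta[sel]))
  }

  # dates: baseline within the recruitment window, protocol-consistent course
  start <- as.Date("2019-12-18"); end <- as.Date("2021-08-04")
  baseline <- start + sample.int(as.integer(end - start), n, replace = TRUE)
  course <- gap <- integer(n)
  for (p in c("standard", "short")) {
    sel <- prot_eye == p
    if (!any(sel)) next
    w <- protocol_windows[[p]]
    course[sel] <- draw_in_window(sum(sel), w$course_mean, w$course_sd, w$course)
    gap[sel] <- draw_in_window(sum(sel), w$gap_mean, w$gap_sd, w$gap)
  }
  inj1 <- baseline
  final <- inj1 + course
  inj3 <- final - gap
  inj2 <- inj1 + as.integer(round((as.integer(inj3 - inj1)) / 2))

  out <- data.frame(
    patient_id = patient_id[idx], eye_id = eye_id,
    clinic = clinic[idx], age = age[idx], sex = sex[idx],
    ethnicity = ethnicity[idx], va_letters = va, cst = cst, trv = trv,
    injection_date_1 = inj1, injection_date_2 = inj2, injection_date_3 = inj3,
    baseline_date = baseline, final_date = final,
    protocol = prot_eye, outcome = outcome, n_scans = n_scans,
    has_imaging = TRUE,
    stringsAsFactors = FALSE
  )
  class(out) <- c("eye_cohort", "data.frame")
  out
}

#' Write / read an eye cohort as CSV (ISO-8601 dates)
#'
#' @param cohort an `eye_cohort` data frame.
#' @param path CSV file path.
#' @return `read_eye_cohort` returns an `eye_cohort` data frame.
#' @export
write_eye_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_eye_cohort
#' @export
read_eye_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in grep("date", names(df), value = TRUE))
    df[[col]] <- as.Date(df[[col]])
  class(df) <- c("eye_cohort", "data.frame")
  df
}
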