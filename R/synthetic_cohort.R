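#' Synthetic cohort configuration
#'
#' Parameters of the synthetic adolescent cohort generator. Distribution
#' defaults are invented for testing — they produce internally consistent
#' records skewed toward overweight/obesity, not epidemiological estimates.
#'
#' @param n Number of patients, >= 1.
#' @param seed Integer RNG seed.
#' @param age_range_months Inclusive age range (default 144-239 months,
#'   i.e. 12-19 years).
#' @param sex_ratio Probability a patient is female.
#' @param bmi_z_mean,bmi_z_sd Normal distribution of the sampled BMI-for-age
#'   z-score (default mean 1.5, sd 0.6, skewing toward overweight/obese).
#' @param availability Per-factor probability that a lab/exam factor (blood
#'   pressure, cholesterol, glucose, smoking) is recorded.
#' @param diet_problem_prev Probability each screener behavior is a problem.
#' @param mvpa_meanlog,mvpa_sdlog Log-normal MVPA minutes/week (default
#'   median 90 min/week).
#' @param bbox Home-address bounding box, c(lat_min, lat_max, lon_min,
#'   lon_max).
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n, seed = 1L,
                          age_range_months = c(144, 239),
                          sex_ratio = 0.5,
                          bmi_z_mean = 1.5, bmi_z_sd = 0.6,
                          availability = 0.9,
                          diet_problem_prev = 0.5,
                          mvpa_meanlog = log(90), mvpa_sdlog = 0.8,
                          bbox = c(38.50, 38.80, -90.50, -90.10)) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  for (p in c(sex_ratio, availability, diet_problem_prev)) {
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (age_range_months[1] < 144 || age_range_months[2] > 240) {
    stop("age range must lie within the LMS reference coverage (144-240 months)",
         call. = FALSE)
  }
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 age_range_months = age_range_months, sex_ratio = sex_ratio,
                 bmi_z_mean = bmi_z_mean, bmi_z_sd = bmi_z_sd,
                 availability = availability,
                 diet_problem_prev = diet_problem_prev,
                 mvpa_meanlog = mvpa_meanlog, mvpa_sdlog = mvpa_sdlog,
                 bbox = bbox),
            class = "cohort_config")
}

# Deterministic per-patient substream seed; record i is independent of how
# many other records are drawn.
patient_seed <- function(seed, i) {
  as.integer((abs(as.numeric(seed)) * 1009 + i * 7919) %% 2147483562)
}

#' Generate a synthetic adolescent cohort
#'
#' Draws reproducible synthetic patients: ages uniform over the configured
#' range, sex by ratio, BMI-for-age z-scores from the configured normal,
#' heights from sex/age-typical curves, and weights back-solved from the
#' sampled z through the LMS reference — so downstream weight-status
#' classification recovers the sampled z exactly. Lab factors are masked
#' unavailable at the configured rate. Each patient uses its own counter-
#' derived RNG substream, making records order-independent.
#'
#' @param config A `cohort_config`.
#' @param lms An `lms_table` (default the shipped synthetic reference).
#' @return Data frame in the documented patient schema, one row per patient.
#' @export
generate_cohort <- function(config, lms = synthetic_lms_table()) {
  stopifnot(inherits(config, "cohort_config"))
  rows <- lapply(seq_len(config$n), function(i) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(patient_seed(config$seed, i))
    age <- sample(seq(config$age_range_months[1], config$age_range_months[2]), 1)
    sex <- if (stats::runif(1) < config$sex_ratio) "female" else "male"
    z <- stats::rnorm(1, config$bmi_z_mean, config$bmi_z_sd)
    u <- (age - 144) / 96
    height <- if (sex == "male") stats::rnorm(1, 149 + 26 * u, 7)
              else stats::rnorm(1, 151 + 12 * u, 6)
    height <- min(max(height, 120), 210)
    par <- lms_at_age(lms, sex, age)
    # truncate extreme z: |z| capped at 3.5, and kept strictly inside the
    # Box-Cox representable range when L and z have opposite signs
    z_lim <- if (abs(par$L) > 1e-12) 0.98 / abs(par$L * par$S) else Inf
    z <- max(min(z, min(3.5, z_lim)), -min(3.5, z_lim))
    bmi <- lms_inverse(z, par$L, par$M, par$S)
    weight <- bmi * (height / 100)^2
    avail <- stats::runif(4) < config$availability
    systolic <- round(stats::rnorm(1, 112, 10), 0)
    diastolic <- round(stats::rnorm(1, 68, 8), 0)
    cholesterol <- round(stats::rnorm(1, 165, 25), 0)
    glucose <- round(stats::rnorm(1, 92, 10), 0)
    smoking <- sample(c("never", "former", "current"), 1,
                      prob = c(0.90, 0.07, 0.03))
    mvpa <- round(stats::rlnorm(1, config$mvpa_meanlog, config$mvpa_sdlog), 1)
    diet <- stats::runif(5) >= config$diet_problem_prev  # TRUE = healthy
    lat <- stats::runif(1, config$bbox[1], config$bbox[2])
    lon <- stats::runif(1, config$bbox[3], config$bbox[4])
    data.frame(
      id = sprintf("synth-%04d", i),
      age_months = age, sex = sex,
      height_cm = height, weight_kg = weight,
      systolic = if (avail[1]) systolic else NA_real_,
      diastolic = if (avail[1]) diastolic else NA_real_,
      cholesterol = if (avail[2]) cholesterol else NA_real_,
      glucose = if (avail[3]) glucose else NA_real_,
      smoking = if (avail[4]) smoking else NA_character_,
      mvpa_min_per_week = mvpa,
      diet_fruit = diet[1], diet_vegetable = diet[2],
      diet_whole_grains = diet[3], diet_ssb = diet[4],
      diet_snacking = diet[5],
      pa_willingness = sample(1:5, 1), diet_willingness = sample(1:5, 1),
      lat = lat, lon = lon,
      preferred_channel = sample(c("email", "sms"), 1),
      stringsAsFactors = FALSE
    )
  })
  cohort <- do.call(rbind, rows)
  rownames(cohort) <- NULL
  cohort
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Write a cohort to the patient CSV schema
#'
#' @param cohort Data frame from [generate_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Eligibility check
#'
#' Eligible patients are adolescents (144-239 months, i.e. 12-19 years) with
#' BMI-for-age percentile at or above the 85th (overweight or obese).
#'
#' @param patient A `patient_record` (or one cohort row as a list).
#' @param lms An `lms_table`.
#' @return List with `eligible` (logical), `reasons` (character; empty when
#'   eligible) and the computed `weight_status`.
#' @export
check_eligibility <- function(patient, lms = synthetic_lms_table()) {
  if (!inherits(patient, "patient_record")) {
    patient <- patient_record_from_row(patient)
  }
  m <- patient$measurement
  reasons <- character()
  if (m$age_months < 144 || m$age_months > 239) {
    reasons <- c(reasons, "age outside 12-19 years")
  }
  # ages past the reference coverage are already ineligible by age; weight
  # status is reported only where the reference can classify it
  ws <- tryCatch(
    classify_weight_status(m$age_months, m$sex, m$height_cm, m$weight_kg, lms),
    error = function(e) if (length(reasons)) NULL else stop(e))
  if (!is.null(ws) && ws$percentile < 85) {
    reasons <- c(reasons, "BMI percentile below 85th")
  }
  list(eligible = !length(reasons), reasons = reasons, weight_status = ws)
}

#' Build a seven-factor risk profile from a patient record
#'
#' BMI percentile is computed from the measurement through the LMS
#' reference; other factors carry over with their availability flags; the
#' diet factor is the count of healthy screener components (0-5).
#'
#' @param patient A `patient_record` (or one cohort row as a list).
#' @param lms An `lms_table`.
#' @return A `risk_profile`.
#' @export
risk_profile_from_patient <- function(patient, lms = synthetic_lms_table()) {
  if (!inherits(patient, "patient_record")) {
    patient <- patient_record_from_row(patient)
  }
  m <- patient$measurement
  ws <- classify_weight_status(m$age_months, m$sex, m$height_cm, m$weight_kg,
                               lms)
  risk_profile(
    bmi_percentile = ws$percentile,
    blood_pressure = patient$blood_pressure,
    cholesterol = patient$cholesterol,
    glucose = patient$glucose,
    smoking = patient$smoking,
    physical_activity = patient$mvpa_min_per_week,
    diet = if (is.null(patient$diet_survey)) NULL else
      sum(unclass(patient$diet_survey))
  )
}
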