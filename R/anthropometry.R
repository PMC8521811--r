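#' Body mass index from height and weight
#'
#' @param height_cm Height in centimetres, > 0.
#' @param weight_kg Weight in kilograms, > 0.
#' @return BMI in kg/m^2.
#' @examples
#' compute_bmi(160, 50)
#' @export
compute_bmi <- function(height_cm, weight_kg) {
  if (!is.numeric(height_cm) || !is.numeric(weight_kg) ||
      any(!is.finite(height_cm)) || any(!is.finite(weight_kg)) ||
      any(height_cm <= 0) || any(weight_kg <= 0)) {
    stop("height_cm and weight_kg must be finite and positive", call. = FALSE)
  }
  weight_kg / (height_cm / 100)^2
}

#' LMS z-score
#'
#' Converts a measurement into a standard-deviation score against a growth
#' reference parameterised by the Box-Cox power L, median M and coefficient of
#' variation S. For L = 0 the log-limit form ln(x/M)/S is used.
#'
#' @param x Measurement (e.g. BMI in kg/m^2), > 0.
#' @param L Box-Cox power (unitless).
#' @param M Reference median, > 0.
#' @param S Coefficient of variation, > 0.
#' @return z-score (unitless).
#' @export
lms_zscore <- function(x, L, M, S) {
  stopifnot(is.numeric(x), is.numeric(L), is.numeric(M), is.numeric(S))
  if (any(!is.finite(x)) || any(x <= 0) || any(M <= 0) || any(S <= 0)) {
    stop("x, M and S must be finite and positive", call. = FALSE)
  }
  ifelse(abs(L) < 1e-12,
         log(x / M) / S,
         ((x / M)^L - 1) / (L * S))
}

#' Inverse of the LMS transform
#'
#' Returns the measurement value corresponding to a z-score under an LMS
#' reference; used to locate percentile cut-offs (e.g. the 95th-percentile BMI)
#' and to back-solve synthetic weights from sampled z-scores.
#'
#' @inheritParams lms_zscore
#' @param z z-score.
#' @return Measurement on the original scale.
#' @export
lms_inverse <- function(z, L, M, S) {
  stopifnot(is.numeric(z), M > 0, S > 0)
  if (abs(L) < 1e-12) return(M * exp(S * z))
  base <- 1 + L * S * z
  if (any(base <= 0)) {
    stop("z outside the representable range for these LMS parameters", call. = FALSE)
  }
  M * base^(1 / L)
}

#' z-score to percentile
#'
#' @param z Finite z-score.
#' @return Standard-normal percentile on the 0-100 scale.
#' @export
zscore_to_percentile <- function(z) {
  if (!is.numeric(z) || any(!is.finite(z))) {
    stop("z must be finite", call. = FALSE)
  }
  stats::pnorm(z) * 100
}

#' Read an LMS growth-reference table
#'
#' The CSV must have columns sex, agemos, L, M, S, with rows ordered by
#' (sex, agemos). The package ships a synthetic reference covering ages
#' 144-240 months (see [synthetic_lms_table()]); a real CDC table with the
#' same schema can be supplied instead.
#'
#' @param path CSV file path.
#' @return Validated data frame of class `lms_table`.
#' @export
read_lms_table <- function(path) {
  if (!file.exists(path)) stop("LMS table not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_lms_table(tab)
}

#' Validate an LMS table data frame
#'
#' @param tab Data frame with columns sex, agemos, L, M, S.
#' @return The validated table with class `lms_table`.
#' @export
as_lms_table <- function(tab) {
  required <- c("sex", "agemos", "L", "M", "S")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("LMS table missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tab$sex <- tolower(as.character(tab$sex))
  if (!all(tab$sex %in% c("male", "female"))) {
    stop("LMS table sex must be 'male' or 'female'", call. = FALSE)
  }
  if (any(tab$M <= 0) || any(tab$S <= 0)) {
    stop("LMS table requires M > 0 and S > 0", call. = FALSE)
  }
  ord <- order(tab$sex, tab$agemos)
  if (!identical(ord, seq_len(nrow(tab)))) tab <- tab[ord, , drop = FALSE]
  if (any(duplicated(tab[c("sex", "agemos")]))) {
    stop("LMS table has duplicated (sex, agemos) rows", call. = FALSE)
  }
  rownames(tab) <- NULL
  class(tab) <- c("lms_table", "data.frame")
  tab
}

#' The package's synthetic LMS reference
#'
#' A smooth, physiologically plausible BMI-for-age reference for ages 144-240
#' months, both sexes. It is synthetic: generated from simple parametric
#' curves, not fitted to population data, and is intended for testing and
#' demonstration only. Supply a real CDC 2000 table for clinical use.
#'
#' @return An `lms_table` data frame.
#' @export
synthetic_lms_table <- function() {
  path <- system.file("extdata", "lms_reference_synthetic.csv",
                      package = "cvhrx", mustWork = TRUE)
  read_lms_table(path)
}

#' Interpolate LMS parameters at an age
#'
#' Linear interpolation in age (months) within one sex; exact at table knots.
#'
#' @param lms An `lms_table`.
#' @param sex "male" or "female".
#' @param age_months Age in months; must lie within the table's coverage.
#' @return Named list with L, M, S.
#' @export
lms_at_age <- function(lms, sex, age_months) {
  sex <- match.arg(tolower(sex), c("male", "female"))
  sub <- lms[lms$sex == sex, , drop = FALSE]
  if (!nrow(sub)) stop("LMS table has no rows for sex ", sex, call. = FALSE)
  if (age_months < min(sub$agemos) || age_months > max(sub$agemos)) {
    stop(sprintf("age %s months outside LMS coverage [%s, %s]",
                 age_months, min(sub$agemos), max(sub$agemos)), call. = FALSE)
  }
  list(
    L = stats::approx(sub$agemos, sub$L, xout = age_months)$y,
    M = stats::approx(sub$agemos, sub$M, xout = age_months)$y,
    S = stats::approx(sub$agemos, sub$S, xout = age_months)$y
  )
}

validate_measurement <- function(age_months, sex, height_cm, weight_kg) {
  sex <- match.arg(tolower(sex), c("male", "female"))
  if (!is.numeric(age_months) || age_months < 24) {
    stop("age_months must be numeric and >= 24", call. = FALSE)
  }
  if (!is.numeric(height_cm) || height_cm <= 40 || height_cm >= 250) {
    stop("height_cm must lie in (40, 250)", call. = FALSE)
  }
  if (!is.numeric(weight_kg) || weight_kg <= 10 || weight_kg >= 400) {
    stop("weight_kg must lie in (10, 400)", call. = FALSE)
  }
  list(age_months = age_months, sex = sex,
       height_cm = height_cm, weight_kg = weight_kg)
}

#' Classify pediatric weight status
#'
#' Computes BMI, the BMI-for-age z-score and percentile via the LMS method,
#' and assigns a weight-status category: underweight (<5th percentile),
#' healthy (5th to <85th), overweight (85th to <95th), obese (>=95th), and
#' severe obesity when BMI is at or above 120% of the 95th-percentile BMI for
#' age and sex.
#'
#' @param age_months Age in months.
#' @param sex "male" or "female".
#' @param height_cm Height in cm.
#' @param weight_kg Weight in kg.
#' @param lms An `lms_table`; defaults to the shipped synthetic reference.
#' @return List of class `weight_status` with bmi, z, percentile, p95_bmi and
#'   category.
#' @export
classify_weight_status <- function(age_months, sex, height_cm, weight_kg,
                                   lms = synthetic_lms_table()) {
  m <- validate_measurement(age_months, sex, height_cm, weight_kg)
  par <- lms_at_age(lms, m$sex, m$age_months)
  bmi <- compute_bmi(m$height_cm, m$weight_kg)
  z <- lms_zscore(bmi, par$L, par$M, par$S)
  pct <- zscore_to_percentile(z)
  p95 <- lms_inverse(stats::qnorm(0.95), par$L, par$M, par$S)
  category <- if (bmi >= 1.2 * p95) {
    "severe_obese"
  } else if (pct >= 95) {
    "obese"
  } else if (pct >= 85) {
    "overweight"
  } else if (pct >= 5) {
    "healthy"
  } else {
    "underweight"
  }
  structure(list(bmi = bmi, z = z, percentile = pct, p95_bmi = p95,
                 category = category),
            class = "weight_status")
}

#' @export
print.weight_status <- function(x, ...) {
  cat(sprintf("BMI %.1f kg/m^2, z = %+.2f, percentile %.1f -> %s\n",
              x$bmi, x$z, x$percentile, x$category))
  invisible(x)
}
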