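CVH_FACTORS <- c("bmi_percentile", "blood_pressure", "cholesterol", "glucose",
                 "smoking", "physical_activity", "diet")

CVH_CATEGORIES <- c("ideal", "intermediate", "poor")

category_points <- c(ideal = 2L, intermediate = 1L, poor = 0L)
category_color <- c(ideal = "green", intermediate = "yellow", poor = "red")

#' Load a risk-factor cut-point configuration
#'
#' Reads a YAML (or JSON) cut-point table defining, per factor, either ordered
#' ideal/intermediate/poor boundaries with a direction, a systolic/diastolic
#' band pair, or a categorical map. Validates that all seven factors are
#' defined with exactly three categories.
#'
#' @param path Path to a YAML/JSON cut-point file.
#' @return A validated cut-point list of class `cvh_cutpoints`.
#' @export
load_cutpoints <- function(path) {
  if (!file.exists(path)) stop("cut-point config not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  validate_cutpoints(cfg)
}

#' Default pediatric cut-points
#'
#' @return The shipped AHA-style pediatric default cut-point table.
#' @export
default_cutpoints <- function() {
  load_cutpoints(system.file("extdata", "cutpoints_default.yaml",
                             package = "cvhrx", mustWork = TRUE))
}

validate_cutpoints <- function(cfg) {
  missing <- setdiff(CVH_FACTORS, names(cfg))
  if (length(missing)) {
    stop("cut-point config missing factors: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (f in CVH_FACTORS) {
    spec <- cfg[[f]]
    type <- spec$type %||% "range"
    if (type == "range") {
      if (identical(spec$direction, "lower_better")) {
        if (!(spec$ideal_max < spec$intermediate_max)) {
          stop("cut-points for ", f, " not strictly ordered", call. = FALSE)
        }
      } else if (identical(spec$direction, "higher_better")) {
        if (!(spec$poor_max < spec$ideal_min)) {
          stop("cut-points for ", f, " not strictly ordered", call. = FALSE)
        }
      } else {
        stop("unknown direction for ", f, call. = FALSE)
      }
    } else if (type == "categorical") {
      if (!all(unlist(spec$map) %in% CVH_CATEGORIES)) {
        stop("categorical map for ", f, " has unknown categories", call. = FALSE)
      }
      if (!all(CVH_CATEGORIES %in% unlist(spec$map))) {
        stop("categorical map for ", f, " must cover ideal/intermediate/poor",
             call. = FALSE)
      }
    } else if (type == "blood_pressure") {
      for (band in c("systolic", "diastolic")) {
        b <- spec[[band]]
        if (is.null(b) || !(b$ideal_max < b$intermediate_max)) {
          stop("blood-pressure bands for ", f, " invalid", call. = FALSE)
        }
      }
    } else {
      stop("unknown cut-point type '", type, "' for ", f, call. = FALSE)
    }
  }
  class(cfg) <- c("cvh_cutpoints", "list")
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a seven-factor risk profile
#'
#' A factor given as `NULL` (or `NA`) is recorded as unavailable and excluded
#' from scoring; the score denominator shrinks accordingly.
#'
#' @param bmi_percentile BMI-for-age percentile, 0-100.
#' @param blood_pressure Length-2 numeric, c(systolic, diastolic) mmHg.
#' @param cholesterol Total cholesterol, mg/dL.
#' @param glucose Fasting glucose, mg/dL.
#' @param smoking One of "never", "former", "current".
#' @param physical_activity MVPA minutes per week.
#' @param diet Count of healthy diet components, 0-5.
#' @return A named list of class `risk_profile`; each element has `value` and
#'   `available`.
#' @export
risk_profile <- function(bmi_percentile = NULL, blood_pressure = NULL,
                         cholesterol = NULL, glucose = NULL, smoking = NULL,
                         physical_activity = NULL, diet = NULL) {
  vals <- list(bmi_percentile = bmi_percentile, blood_pressure = blood_pressure,
               cholesterol = cholesterol, glucose = glucose, smoking = smoking,
               physical_activity = physical_activity, diet = diet)
  prof <- lapply(vals, function(v) {
    available <- !is.null(v) && !all(is.na(v))
    list(value = if (available) v else NULL, available = available)
  })
  class(prof) <- c("risk_profile", "list")
  prof
}

#' Categorize a single risk factor
#'
#' Assigns ideal/intermediate/poor (green/yellow/red; 2/1/0 points) to one
#' factor value using a cut-point table. Blood pressure takes the worse of
#' the systolic and diastolic bands.
#'
#' @param factor One of the seven factor names.
#' @param value The factor's value in its native units.
#' @param cutpoints A `cvh_cutpoints` table.
#' @return List of class `factor_assessment` with factor, category, points,
#'   color.
#' @export
categorize_factor <- function(factor, value, cutpoints = default_cutpoints()) {
  if (!factor %in% CVH_FACTORS) {
    stop("unknown factor '", factor, "'; valid factors: ",
         paste(CVH_FACTORS, collapse = ", "), call. = FALSE)
  }
  spec <- cutpoints[[factor]]
  type <- spec$type %||% "range"
  category <- switch(
    type,
    range = {
      if (!is.numeric(value) || length(value) != 1 || !is.finite(value)) {
        stop("factor ", factor, " requires a single finite numeric value",
             call. = FALSE)
      }
      if (identical(spec$direction, "lower_better")) {
        if (value < spec$ideal_max) "ideal"
        else if (value < spec$intermediate_max) "intermediate"
        else "poor"
      } else {
        if (value >= spec$ideal_min) "ideal"
        else if (value <= spec$poor_max) "poor"
        else "intermediate"
      }
    },
    categorical = {
      value <- as.character(value)
      if (!value %in% names(spec$map)) {
        stop("unknown level '", value, "' for ", factor, "; valid: ",
             paste(names(spec$map), collapse = ", "), call. = FALSE)
      }
      spec$map[[value]]
    },
    blood_pressure = {
      if (!is.numeric(value) || length(value) != 2 || any(!is.finite(value))) {
        stop("blood_pressure requires c(systolic, diastolic) mmHg",
             call. = FALSE)
      }
      band <- function(v, b) {
        if (v < b$ideal_max) "ideal"
        else if (v < b$intermediate_max) "intermediate"
        else "poor"
      }
      worse <- max(match(band(value[1], spec$systolic), CVH_CATEGORIES),
                   match(band(value[2], spec$diastolic), CVH_CATEGORIES))
      CVH_CATEGORIES[worse]
    }
  )
  structure(list(factor = factor, category = category,
                 points = category_points[[category]],
                 color = category_color[[category]]),
            class = "factor_assessment")
}

#' Compute the cardiovascular health score
#'
#' Each available factor is rated ideal (2 points), intermediate (1) or poor
#' (0); points are summed and divided by the maximum attainable (2 per
#' available factor, 14 when all seven are present), giving a normalized
#' score in \[0, 1\].
#'
#' @param profile A `risk_profile`.
#' @param cutpoints A `cvh_cutpoints` table.
#' @return List of class `cvh_score` with `assessments` (data frame),
#'   `total_points`, `max_points` and `score`.
#' @export
compute_cvh_score <- function(profile, cutpoints = default_cutpoints()) {
  stopifnot(inherits(profile, "risk_profile"))
  avail <- names(profile)[vapply(profile, function(p) isTRUE(p$available),
                                 logical(1))]
  if (!length(avail)) {
    stop("no available risk factors: cannot compute a score", call. = FALSE)
  }
  cats <- vapply(avail, function(f) {
    categorize_factor(f, profile[[f]]$value, cutpoints)$category
  }, character(1))
  # direct construction: this runs inside exhaustive what-if enumerations
  assessments <- structure(
    list(factor = avail, category = unname(cats),
         points = unname(category_points[cats]),
         color = unname(category_color[cats])),
    class = "data.frame", row.names = seq_along(avail))
  total <- sum(assessments$points)
  maxp <- 2L * nrow(assessments)
  structure(list(assessments = assessments,
                 total_points = as.integer(total),
                 max_points = as.integer(maxp),
                 score = total / maxp),
            class = "cvh_score")
}

#' @export
print.cvh_score <- function(x, ...) {
  cat(sprintf("Cardiovascular health score: %d/%d (%.0f%%)\n",
              x$total_points, x$max_points, 100 * x$score))
  print(x$assessments, row.names = FALSE)
  invisible(x)
}

#' What-if ("slider") recalculation
#'
#' Recomputes the score with one factor set to a hypothetical value, leaving
#' the input profile untouched — the interactive slider a clinician moves to
#' show a patient the effect of a change.
#'
#' @param profile A `risk_profile`.
#' @param factor Name of the factor to vary; must be available in the profile.
#' @param new_value Hypothetical value for that factor.
#' @param cutpoints A `cvh_cutpoints` table.
#' @return A fresh `cvh_score`.
#' @export
what_if <- function(profile, factor, new_value,
                    cutpoints = default_cutpoints()) {
  stopifnot(inherits(profile, "risk_profile"))
  if (!factor %in% names(profile) || !isTRUE(profile[[factor]]$available)) {
    stop("factor '", factor, "' not available in this profile", call. = FALSE)
  }
  tweaked <- profile
  tweaked[[factor]]$value <- new_value
  compute_cvh_score(tweaked, cutpoints)
}

#' Willingness-to-change profile
#'
#' Two ordinal Likert items (physical activity and eating habits), displayed
#' alongside the score to steer the conversation; they never alter scoring or
#' auto-prioritize recommendations.
#'
#' @param pa_willingness,diet_willingness Integer 1 (not at all willing) to 5
#'   (very willing).
#' @return List of class `willingness_profile`.
#' @export
willingness_profile <- function(pa_willingness, diet_willingness) {
  for (v in c(pa_willingness, diet_willingness)) {
    if (!is.numeric(v) || length(v) != 1 || !v %in% 1:5) {
      stop("willingness items must be integers 1..5", call. = FALSE)
    }
  }
  structure(list(pa_willingness = as.integer(pa_willingness),
                 diet_willingness = as.integer(diet_willingness)),
            class = "willingness_profile")
}
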