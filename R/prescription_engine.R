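WEIGHT_STATUS_LEVELS <- c("overweight", "obese", "severe_obese")
ACTIVITY_STATUS_LEVELS <- c("inactive", "somewhat_active",
                            "moderately_active", "active")
DIET_BEHAVIORS <- c("fruit", "vegetable", "whole_grains", "ssb", "snacking")

#' Classify current physical-activity status
#'
#' Four-level status from weekly MVPA minutes: inactive (0), somewhat active
#' (1-149), moderately active (150-299), active (>= 300). Thresholds echo the
#' 150/300 min/week guideline landmarks and are config concerns, not clinical
#' constants.
#'
#' @param mvpa_min_per_week Non-negative MVPA minutes per week.
#' @param thresholds Length-2 numeric c(moderate, active) boundaries.
#' @return One of "inactive", "somewhat_active", "moderately_active", "active".
#' @export
classify_activity_status <- function(mvpa_min_per_week,
                                     thresholds = c(150, 300)) {
  if (!is.numeric(mvpa_min_per_week) || length(mvpa_min_per_week) != 1 ||
      !is.finite(mvpa_min_per_week) || mvpa_min_per_week < 0) {
    stop("mvpa_min_per_week must be a single non-negative number", call. = FALSE)
  }
  if (mvpa_min_per_week == 0) "inactive"
  else if (mvpa_min_per_week < thresholds[1]) "somewhat_active"
  else if (mvpa_min_per_week < thresholds[2]) "moderately_active"
  else "active"
}

#' Classify activity intensity from a MET value
#'
#' Standard MET bands: light < 3.0, moderate 3.0 to < 6.0, vigorous >= 6.0.
#'
#' @param met MET value, > 0.
#' @return One of "light", "moderate", "vigorous".
#' @export
classify_intensity <- function(met) {
  if (!is.numeric(met) || length(met) != 1 || !is.finite(met) || met <= 0) {
    stop("met must be a single positive number", call. = FALSE)
  }
  if (met < 3) "light" else if (met < 6) "moderate" else "vigorous"
}

#' Load a physical-activity dose matrix
#'
#' A 3 x 4 grid (obesity level x activity status) of starting doses:
#' minutes per session, sessions per week and an intensity target. The
#' clinical ordering constraint — the severely obese, inactive cell must start
#' with fewer minutes and no more sessions than the overweight, inactive cell
#' — is enforced at load time for any user-supplied matrix.
#'
#' @param path YAML file; defaults to the shipped matrix.
#' @return A nested list of class `pa_dose_matrix`.
#' @export
load_dose_matrix <- function(path = NULL) {
  path <- path %||% system.file("extdata", "dose_matrix_default.yaml",
                                package = "cvhrx", mustWork = TRUE)
  mat <- yaml::read_yaml(path)
  validate_dose_matrix(mat)
}

validate_dose_matrix <- function(mat) {
  for (ws in WEIGHT_STATUS_LEVELS) {
    if (is.null(mat[[ws]])) stop("dose matrix missing row: ", ws, call. = FALSE)
    for (as_ in ACTIVITY_STATUS_LEVELS) {
      cell <- mat[[ws]][[as_]]
      if (is.null(cell) || !is.numeric(cell$minutes) || !is.numeric(cell$sessions) ||
          cell$minutes <= 0 || cell$sessions <= 0) {
        stop("dose matrix cell (", ws, ", ", as_, ") missing or non-positive",
             call. = FALSE)
      }
    }
  }
  so <- mat$severe_obese$inactive
  ow <- mat$overweight$inactive
  if (!(so$minutes < ow$minutes && so$sessions <= ow$sessions)) {
    stop("dose matrix violates the starting-dose ordering: the ",
         "(severe_obese, inactive) cell must have fewer minutes and no more ",
         "sessions than (overweight, inactive)", call. = FALSE)
  }
  class(mat) <- c("pa_dose_matrix", "list")
  mat
}

#' Progression configuration
#'
#' @param weekly_multiplier Weekly goal growth factor; the default 1.10 steps
#'   activity up by 10% each week.
#' @param horizon_weeks Number of weeks planned.
#' @param weekly_cap_min_per_week Ceiling on weekly minutes (default 420,
#'   the 60 min/day youth guideline).
#' @return List of class `progression_config`.
#' @export
progression_config <- function(weekly_multiplier = 1.10, horizon_weeks = 12,
                               weekly_cap_min_per_week = 420) {
  if (weekly_multiplier < 1) stop("weekly_multiplier must be >= 1", call. = FALSE)
  if (weekly_cap_min_per_week <= 0) stop("cap must be positive", call. = FALSE)
  if (horizon_weeks < 1) stop("horizon_weeks must be >= 1", call. = FALSE)
  structure(list(weekly_multiplier = weekly_multiplier,
                 horizon_weeks = as.integer(horizon_weeks),
                 weekly_cap_min_per_week = weekly_cap_min_per_week),
            class = "progression_config")
}

#' Load the activity menu
#'
#' @param path YAML file of activities (name, met, intensity, tags); defaults
#'   to the shipped menu. Each entry's stated intensity must match its
#'   MET-band classification (checked at load).
#' @param exclude_tags Character vector of tags to drop (region filtering,
#'   e.g. coastal activities for an inland clinic).
#' @return Data frame with columns name, met, intensity and a list column
#'   tags.
#' @export
load_activity_menu <- function(path = NULL, exclude_tags = character()) {
  path <- path %||% system.file("extdata", "activity_menu_default.yaml",
                                package = "cvhrx", mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  menu <- data.frame(
    name = vapply(raw, `[[`, character(1), "name"),
    met = vapply(raw, `[[`, numeric(1), "met"),
    intensity = vapply(raw, `[[`, character(1), "intensity"),
    stringsAsFactors = FALSE
  )
  menu$tags <- lapply(raw, function(a) as.character(a$tags %||% character()))
  for (i in seq_len(nrow(menu))) {
    expect <- classify_intensity(menu$met[i])
    if (!identical(menu$intensity[i], expect)) {
      stop("activity '", menu$name[i], "' labelled ", menu$intensity[i],
           " but MET ", menu$met[i], " classifies as ", expect, call. = FALSE)
    }
  }
  if (length(exclude_tags)) {
    keep <- !vapply(menu$tags, function(t) any(t %in% exclude_tags), logical(1))
    menu <- menu[keep, , drop = FALSE]
    rownames(menu) <- NULL
  }
  menu
}

#' Generate a progressive physical-activity plan
#'
#' Week 1 minutes equal the dose-matrix starting cell (minutes x sessions)
#' for the patient's obesity level and activity status; each later week is
#' the previous week times the weekly multiplier (default +10%), rounded to
#' 0.1 min and capped at the weekly ceiling. Patient-selected activities are
#' mandatory — choice is part of the intervention design — and recorded
#' verbatim.
#'
#' @param weight_status "overweight", "obese" or "severe_obese".
#' @param activity_status One of the four activity-status levels.
#' @param chosen_activities Non-empty character vector of activity names.
#' @param dose_matrix A `pa_dose_matrix`.
#' @param progression A `progression_config`.
#' @return List of class `pa_plan` with `weeks` (data frame: week,
#'   minutes_per_week, sessions_per_week), the starting cell and the
#'   selections.
#' @export
generate_pa_plan <- function(weight_status, activity_status, chosen_activities,
                             dose_matrix = load_dose_matrix(),
                             progression = progression_config()) {
  weight_status <- match.arg(weight_status, WEIGHT_STATUS_LEVELS)
  activity_status <- match.arg(activity_status, ACTIVITY_STATUS_LEVELS)
  if (!length(chosen_activities)) {
    stop("at least one patient-chosen activity is required", call. = FALSE)
  }
  cell <- dose_matrix[[weight_status]][[activity_status]]
  cap <- progression$weekly_cap_min_per_week
  r <- progression$weekly_multiplier
  n <- progression$horizon_weeks
  minutes <- numeric(n)
  minutes[1] <- min(cell$minutes * cell$sessions, cap)
  for (w in seq_len(n - 1)) {
    minutes[w + 1] <- min(round(minutes[w] * r, 1), cap)
  }
  weeks <- data.frame(week = seq_len(n),
                      minutes_per_week = minutes,
                      sessions_per_week = cell$sessions)
  structure(list(weight_status = weight_status,
                 activity_status = activity_status,
                 start_minutes_per_session = cell$minutes,
                 sessions_per_week = cell$sessions,
                 intensity_target = cell$intensity %||% "moderate",
                 weeks = weeks,
                 selected_activities = as.character(chosen_activities)),
            class = "pa_plan")
}

#' @export
print.pa_plan <- function(x, ...) {
  cat(sprintf("Physical-activity plan (%s, %s): start %g min x %g/wk, %s intensity\n",
              x$weight_status, x$activity_status,
              x$start_minutes_per_session, x$sessions_per_week,
              x$intensity_target))
  cat("Activities:", paste(x$selected_activities, collapse = ", "), "\n")
  print(utils::head(x$weeks, 4), row.names = FALSE)
  if (nrow(x$weeks) > 4) cat("...", nrow(x$weeks), "weeks total\n")
  invisible(x)
}

#' Five-item diet screener responses
#'
#' One logical per target eating behavior; `TRUE` means the screener's
#' healthy criterion is met (e.g. "Do you eat 2 or more vegetables a day?" —
#' yes). For sugar-sweetened beverages and snacking the items are phrased so
#' that `TRUE` likewise means healthy (drinks are usually avoided; snacks are
#' usually healthy ones).
#'
#' @param fruit,vegetable,whole_grains,ssb,snacking Logical, healthy yes/no.
#' @return Named logical vector of class `diet_survey`.
#' @export
diet_survey <- function(fruit, vegetable, whole_grains, ssb, snacking) {
  ans <- c(fruit = fruit, vegetable = vegetable, whole_grains = whole_grains,
           ssb = ssb, snacking = snacking)
  if (!is.logical(ans) || anyNA(ans) || length(ans) != 5) {
    stop("all five screener items must be TRUE/FALSE", call. = FALSE)
  }
  class(ans) <- c("diet_survey", "logical")
  ans
}

#' Flag problem eating behaviors
#'
#' A behavior is flagged iff its screener answer fails the healthy criterion;
#' recommendations are generated only for flagged behaviors.
#'
#' @param survey A `diet_survey`.
#' @return Character vector of flagged behaviors (subset of the five, in
#'   survey order).
#' @export
flag_problem_behaviors <- function(survey) {
  if (!inherits(survey, "diet_survey")) {
    survey <- do.call(diet_survey, as.list(survey))
  }
  DIET_BEHAVIORS[!unclass(survey)[DIET_BEHAVIORS]]
}

#' Load the Stoplight food-list library
#'
#' @param path YAML file mapping each behavior to a goal statement and
#'   green/yellow/red food tiers; defaults to the shipped library.
#' @return Named list keyed by behavior.
#' @export
load_food_lists <- function(path = NULL) {
  path <- path %||% system.file("extdata", "food_lists_default.yaml",
                                package = "cvhrx", mustWork = TRUE)
  lib <- yaml::read_yaml(path)
  missing <- setdiff(DIET_BEHAVIORS, names(lib))
  if (length(missing)) {
    stop("food-list library missing behaviors: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (b in names(lib)) {
    tiers <- c("green", "yellow", "red")
    if (!all(tiers %in% names(lib[[b]]))) {
      stop("food lists for '", b, "' must have green, yellow and red tiers",
           call. = FALSE)
    }
  }
  lib
}

#' Generate Stoplight-Diet recommendations
#'
#' Exactly one recommendation per flagged behavior, each carrying that
#' behavior's green "anytime", yellow "sometimes" and red "rarely" food lists
#' and an autonomy-supportive goal statement. The care team and patient may
#' choose to focus on fewer behaviors via `max_behaviors` (selection keeps
#' survey order).
#'
#' @param flags Character vector of flagged behaviors.
#' @param food_lists Library from [load_food_lists()].
#' @param max_behaviors Optional cap on the number of behaviors targeted.
#' @return List of `diet_recommendation` objects.
#' @export
generate_diet_recs <- function(flags, food_lists = load_food_lists(),
                               max_behaviors = NULL) {
  flags <- as.character(flags)
  unknown <- setdiff(flags, DIET_BEHAVIORS)
  if (length(unknown)) {
    stop("unknown behaviors: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  flags <- DIET_BEHAVIORS[DIET_BEHAVIORS %in% flags]  # survey order
  if (!is.null(max_behaviors)) flags <- utils::head(flags, max_behaviors)
  lapply(flags, function(b) {
    entry <- food_lists[[b]]
    if (is.null(entry)) stop("behavior '", b, "' missing from food-list library",
                             call. = FALSE)
    structure(list(behavior = b,
                   goal_statement = entry$goal %||% "",
                   food_lists = list(green = as.character(entry$green),
                                     yellow = as.character(entry$yellow),
                                     red = as.character(entry$red))),
              class = "diet_recommendation")
  })
}
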