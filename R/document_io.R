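#' Load the education library
#'
#' @param path YAML file of titled text blocks keyed by topic; defaults to
#'   the shipped library.
#' @return Named list of blocks, each with `title` and `body`.
#' @export
load_education <- function(path = NULL) {
  path <- path %||% system.file("extdata", "education_default.yaml",
                                package = "cvhrx", mustWork = TRUE)
  yaml::read_yaml(path)
}

#' Assemble the behavior-change prescription document
#'
#' Builds the patient-facing "prescription": four sections — goals (the
#' physical-activity plan plus diet recommendations), selected activities,
#' nearby community resources, and education blocks (one per flagged diet
#' behavior, plus the general physical-activity and family blocks). A
#' section may be empty but is always present.
#'
#' @param patient_id Patient identifier.
#' @param pa_plan A `pa_plan` (required).
#' @param diet_recs List of `diet_recommendation`s (possibly empty).
#' @param resource_hits Data frame from [find_nearby()], or NULL.
#' @param education Library from [load_education()].
#' @param preferred_channel "email", "sms" or "print".
#' @param max_resources Resources kept in the document (default 5).
#' @return List of class `prescription_document`.
#' @export
assemble_prescription <- function(patient_id, pa_plan, diet_recs = list(),
                                  resource_hits = NULL,
                                  education = load_education(),
                                  preferred_channel = "email",
                                  max_resources = 5) {
  if (missing(pa_plan) || !inherits(pa_plan, "pa_plan")) {
    stop("a valid pa_plan is required", call. = FALSE)
  }
  if (!preferred_channel %in% c("email", "sms", "print")) {
    stop("preferred_channel must be email, sms or print", call. = FALSE)
  }
  flagged <- vapply(diet_recs, function(r) r$behavior, character(1))
  edu_keys <- c("general_pa",
                if (length(flagged)) "stoplight_overview",
                flagged,
                "tips_for_families")
  edu_blocks <- lapply(intersect(edu_keys, names(education)), function(k) {
    list(topic = k, title = education[[k]]$title, body = education[[k]]$body)
  })
  resources <- if (is.null(resource_hits) || !nrow(resource_hits)) {
    list()
  } else {
    hits <- utils::head(resource_hits, max_resources)
    lapply(seq_len(nrow(hits)), function(i) {
      list(name = hits$name[i], category = hits$category[i],
           address = hits$address[i], hours = hits$hours[i],
           distance_km = hits$distance_km[i])
    })
  }
  doc <- list(
    patient_id = as.character(patient_id),
    preferred_channel = preferred_channel,
    sections = list(
      goals = list(
        physical_activity = list(
          weight_status = pa_plan$weight_status,
          activity_status = pa_plan$activity_status,
          intensity_target = pa_plan$intensity_target,
          sessions_per_week = pa_plan$sessions_per_week,
          weekly_minutes = pa_plan$weeks$minutes_per_week
        ),
        diet = lapply(diet_recs, function(r) {
          list(behavior = r$behavior, goal_statement = r$goal_statement,
               food_lists = r$food_lists)
        })
      ),
      activities = as.character(pa_plan$selected_activities),
      resources = resources,
      education = edu_blocks
    )
  )
  class(doc) <- c("prescription_document", "list")
  doc
}

#' Render a prescription document
#'
#' Deterministic projection of the JSON-first document model into one of
#' three formats: `json` (canonical, round-trippable), `text` (plain,
#' autonomy-supportive wording throughout) or `html` (stoplight food tables
#' use the green/yellow/red tiering).
#'
#' @param doc A `prescription_document`.
#' @param format "text", "html" or "json".
#' @return A single character string.
#' @export
render_document <- function(doc, format = c("text", "html", "json")) {
  stopifnot(inherits(doc, "prescription_document"))
  format <- match.arg(format)
  switch(format,
         json = render_doc_json(doc),
         text = render_doc_text(doc),
         html = render_doc_html(doc))
}

render_doc_json <- function(doc) {
  as.character(jsonlite::toJSON(unclass(doc), auto_unbox = TRUE, digits = NA,
                                pretty = TRUE))
}

#' Parse a prescription document from its JSON render
#'
#' @param json JSON string produced by [render_document()] with
#'   `format = "json"`.
#' @return A `prescription_document` whose JSON render is identical to the
#'   input.
#' @export
parse_prescription <- function(json) {
  doc <- jsonlite::fromJSON(json, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  # scalar leaves come back length-1; weekly_minutes must stay a vector
  wm <- doc$sections$goals$physical_activity$weekly_minutes
  doc$sections$goals$physical_activity$weekly_minutes <- as.numeric(unlist(wm))
  class(doc) <- c("prescription_document", "list")
  doc
}

render_doc_text <- function(doc) {
  pa <- doc$sections$goals$physical_activity
  lines <- c(
    sprintf("Behavior-change plan for patient %s", doc$patient_id),
    "",
    "== Goals ==",
    sprintf("Physical activity: you may work toward %.1f minutes this week (%s intensity, about %d sessions).",
            pa$weekly_minutes[1], pa$intensity_target,
            as.integer(pa$sessions_per_week)),
    sprintf("Over %d weeks the weekly goal could grow to %.1f minutes.",
            length(pa$weekly_minutes),
            pa$weekly_minutes[length(pa$weekly_minutes)])
  )
  for (d in doc$sections$goals$diet) {
    lines <- c(lines, sprintf("Diet (%s): %s", gsub("_", " ", d$behavior),
                              d$goal_statement),
               sprintf("  green (anytime): %s",
                       paste(d$food_lists$green, collapse = ", ")),
               sprintf("  yellow (sometimes): %s",
                       paste(d$food_lists$yellow, collapse = ", ")),
               sprintf("  red (rarely): %s",
                       paste(d$food_lists$red, collapse = ", ")))
  }
  lines <- c(lines, "", "== Activities you chose ==",
             paste0("- ", unlist(doc$sections$activities)))
  lines <- c(lines, "", "== Community resources near you ==")
  if (length(doc$sections$resources)) {
    for (r in doc$sections$resources) {
      lines <- c(lines, sprintf("- %s (%s), %.2f km away%s", r$name,
                                gsub("_", " ", r$category), r$distance_km,
                                if (nzchar(r$address %||% "")) paste0(", ", r$address) else ""))
    }
  } else {
    lines <- c(lines, "(none selected)")
  }
  lines <- c(lines, "", "== Learn more ==")
  for (e in doc$sections$education) {
    lines <- c(lines, paste0("* ", e$title), paste0("  ", e$body))
  }
  paste(lines, collapse = "\n")
}

render_doc_html <- function(doc) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  pa <- doc$sections$goals$physical_activity
  parts <- c(
    "<html><body>",
    sprintf("<h1>Behavior-change plan for patient %s</h1>", esc(doc$patient_id)),
    "<h2>Goals</h2>",
    sprintf("<p>Physical activity: you may work toward %.1f minutes this week (%s intensity, about %d sessions per week).</p>",
            pa$weekly_minutes[1], esc(pa$intensity_target),
            as.integer(pa$sessions_per_week))
  )
  for (d in doc$sections$goals$diet) {
    parts <- c(parts,
      sprintf("<h3>%s</h3><p>%s</p>", esc(gsub("_", " ", d$behavior)),
              esc(d$goal_statement)),
      "<table class=\"stoplight\">",
      sprintf("<tr class=\"green\"><th>Anytime</th><td>%s</td></tr>",
              esc(paste(d$food_lists$green, collapse = ", "))),
      sprintf("<tr class=\"yellow\"><th>Sometimes</th><td>%s</td></tr>",
              esc(paste(d$food_lists$yellow, collapse = ", "))),
      sprintf("<tr class=\"red\"><th>Rarely</th><td>%s</td></tr>",
              esc(paste(d$food_lists$red, collapse = ", "))),
      "</table>")
  }
  parts <- c(parts, "<h2>Activities you chose</h2><ul>",
             sprintf("<li>%s</li>", esc(unlist(doc$sections$activities))),
             "</ul>", "<h2>Community resources</h2><ul>")
  for (r in doc$sections$resources) {
    parts <- c(parts, sprintf("<li>%s (%s), %.2f km</li>", esc(r$name),
                              esc(gsub("_", " ", r$category)), r$distance_km))
  }
  parts <- c(parts, "</ul>", "<h2>Learn more</h2>")
  for (e in doc$sections$education) {
    parts <- c(parts, sprintf("<h3>%s</h3><p>%s</p>", esc(e$title), esc(e$body)))
  }
  paste(c(parts, "</body></html>"), collapse = "\n")
}

#' Summarize Likert satisfaction items
#'
#' Unweighted arithmetic mean of per-item means on a 1-5 scale, reported to
#' one decimal.
#'
#' @param item_means Numeric vector of item means, each in \[1, 5\].
#' @return Overall mean, rounded to one decimal.
#' @export
summarize_likert_items <- function(item_means) {
  if (!is.numeric(item_means) || !length(item_means)) {
    stop("item_means must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(item_means)) || any(item_means < 1 | item_means > 5)) {
    stop("item means must lie in [1, 5]", call. = FALSE)
  }
  round(mean(item_means), 1)
}

PATIENT_REQUIRED_COLS <- c("id", "age_months", "sex", "height_cm", "weight_kg",
                           "mvpa_min_per_week", "lat", "lon",
                           "preferred_channel")

#' Read patient records
#'
#' Reads the documented patient schema from CSV (one row per patient) or
#' JSON (array of objects). Required fields: id, age_months, sex, height_cm,
#' weight_kg, mvpa_min_per_week, lat, lon, preferred_channel; optional
#' risk-factor fields (systolic, diastolic, cholesterol, glucose, smoking;
#' NA = unavailable), five diet_* screener items and two willingness items.
#' Rows violating field-level constraints are rejected with per-row
#' diagnostics; eligibility is not filtered here.
#'
#' @param path CSV or JSON file.
#' @return List with `patients` (list of `patient_record`s), `n_loaded`,
#'   `n_rejected`, `diagnostics`.
#' @export
read_patients <- function(path) {
  if (!file.exists(path)) stop("patient file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  tab <- if (ext == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else if (ext == "json") {
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  } else {
    stop("unsupported patient file format: .", ext, call. = FALSE)
  }
  miss <- setdiff(PATIENT_REQUIRED_COLS, names(tab))
  if (length(miss)) {
    stop("patient file missing required columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  patients <- list(); diagnostics <- character()
  for (i in seq_len(nrow(tab))) {
    row <- as.list(tab[i, , drop = FALSE])
    rec <- tryCatch(patient_record_from_row(row),
                    error = function(e) conditionMessage(e))
    if (is.character(rec)) {
      diagnostics <- c(diagnostics, sprintf("row %d: %s", i, rec))
    } else {
      patients[[length(patients) + 1]] <- rec
    }
  }
  list(patients = patients, n_loaded = length(patients),
       n_rejected = length(diagnostics), diagnostics = diagnostics)
}

patient_record_from_row <- function(row) {
  m <- validate_measurement(row$age_months, row$sex, row$height_cm,
                            row$weight_kg)
  if (!row$preferred_channel %in% c("email", "sms", "print")) {
    stop("preferred_channel must be email, sms or print", call. = FALSE)
  }
  if (!is.numeric(row$mvpa_min_per_week) || is.na(row$mvpa_min_per_week) ||
      row$mvpa_min_per_week < 0) {
    stop("mvpa_min_per_week must be non-negative", call. = FALSE)
  }
  home <- geo_point(row$lat, row$lon)
  num_or_null <- function(x) if (is.null(x) || is.na(x)) NULL else as.numeric(x)
  diet_items <- paste0("diet_", DIET_BEHAVIORS)
  survey <- if (all(diet_items %in% names(row)) &&
                !anyNA(unlist(row[diet_items]))) {
    do.call(diet_survey, stats::setNames(lapply(row[diet_items], as.logical),
                                         DIET_BEHAVIORS))
  } else NULL
  smoking <- row$smoking
  if (!is.null(smoking) && (is.na(smoking) || !nzchar(smoking))) smoking <- NULL
  bp <- if (!is.null(num_or_null(row$systolic)) &&
            !is.null(num_or_null(row$diastolic))) {
    c(as.numeric(row$systolic), as.numeric(row$diastolic))
  } else NULL
  willingness <- if (!is.null(row$pa_willingness) &&
                     !is.na(row$pa_willingness) &&
                     !is.null(row$diet_willingness) &&
                     !is.na(row$diet_willingness)) {
    willingness_profile(row$pa_willingness, row$diet_willingness)
  } else NULL
  structure(list(id = as.character(row$id), measurement = m,
                 blood_pressure = bp,
                 cholesterol = num_or_null(row$cholesterol),
                 glucose = num_or_null(row$glucose),
                 smoking = smoking,
                 mvpa_min_per_week = as.numeric(row$mvpa_min_per_week),
                 diet_survey = survey,
                 willingness = willingness,
                 home = home,
                 preferred_channel = as.character(row$preferred_channel)),
            class = "patient_record")
}
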