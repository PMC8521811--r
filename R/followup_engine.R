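#' Add whole months to a date, clamping at month end
#'
#' 2021-01-31 plus one month is 2021-02-28: when the target month is shorter
#' than the starting day, the result clamps to the last day of that month.
#'
#' @param date A `Date`.
#' @param k Integer number of months.
#' @return A `Date`.
#' @export
add_months_clamped <- function(date, k) {
  date <- tryCatch(as.Date(date), error = function(e) NA)
  if (is.na(date)) stop("invalid date", call. = FALSE)
  lt <- as.POSIXlt(date)
  total <- lt$mon + k
  year <- lt$year + 1900 + total %/% 12
  month <- total %% 12 + 1
  day <- lt$mday
  last <- days_in_month(year, month)
  as.Date(sprintf("%04d-%02d-%02d", year, month, min(day, last)))
}

days_in_month <- function(year, month) {
  lengths <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  leap <- (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
  if (month == 2 && leap) 29L else lengths[month]
}

#' Schedule post-visit check-ins
#'
#' Emits the automated follow-up schedule: by default three monthly check-ins
#' after the clinic visit, on the patient's preferred channel.
#'
#' @param visit_date Clinic visit date.
#' @param n_checkins Number of check-ins (default 3).
#' @param cadence_months Months between check-ins (default 1).
#' @param channel "email" or "sms", per patient preference.
#' @return List of class `checkin_schedule` with `visit_date`,
#'   `checkin_dates` (strictly increasing, all after the visit) and `channel`.
#' @export
schedule_checkins <- function(visit_date, n_checkins = 3, cadence_months = 1,
                              channel = c("email", "sms")) {
  channel <- match.arg(channel)
  visit_date <- tryCatch(as.Date(visit_date), error = function(e) NA)
  if (is.na(visit_date)) stop("invalid visit_date", call. = FALSE)
  dates <- as.Date(vapply(seq_len(n_checkins), function(i) {
    as.character(add_months_clamped(visit_date, i * cadence_months))
  }, character(1)))
  structure(list(visit_date = visit_date, checkin_dates = dates,
                 channel = channel),
            class = "checkin_schedule")
}

#' Goal-update rule
#'
#' Maps a 5-point Likert adherence response (never ... always) to a goal
#' multiplier: responses at or above the advance threshold step the goal up
#' (default +10%, matching the weekly progression), the midpoint holds, and
#' responses at or below the ease threshold step it down (default -10%).
#' Updated goals never leave \[floor, cap\]: the floor is the initial week-1
#' goal, the cap the progression ceiling.
#'
#' @param floor Minimum weekly goal (min/week).
#' @param cap Maximum weekly goal (min/week).
#' @param advance_threshold Likert value at/above which the goal advances.
#' @param ease_threshold Likert value at/below which the goal eases.
#' @param advance_mult,ease_mult Multipliers for advance/ease.
#' @return List of class `goal_update_rule`.
#' @export
goal_update_rule <- function(floor, cap, advance_threshold = 4,
                             ease_threshold = 2, advance_mult = 1.10,
                             ease_mult = 0.90) {
  if (!(ease_mult < 1 && 1 < advance_mult)) {
    stop("require ease_mult < 1 < advance_mult", call. = FALSE)
  }
  if (floor > cap) stop("floor must not exceed cap", call. = FALSE)
  if (ease_threshold >= advance_threshold) {
    stop("ease_threshold must be below advance_threshold", call. = FALSE)
  }
  structure(list(floor = floor, cap = cap,
                 advance_threshold = advance_threshold,
                 ease_threshold = ease_threshold,
                 advance_mult = advance_mult, ease_mult = ease_mult),
            class = "goal_update_rule")
}

#' Update a weekly goal from a check-in response
#'
#' @param current_goal Current weekly goal, min/week, within \[floor, cap\].
#' @param response Likert 1-5 (never ... always).
#' @param rule A `goal_update_rule`.
#' @return New weekly goal, rounded to 0.1 min, clamped to \[floor, cap\].
#' @export
update_goal <- function(current_goal, response, rule) {
  stopifnot(inherits(rule, "goal_update_rule"))
  if (!is.numeric(response) || length(response) != 1 || !response %in% 1:5) {
    stop("response must be a Likert value 1..5", call. = FALSE)
  }
  if (current_goal < rule$floor || current_goal > rule$cap) {
    stop("current_goal outside [floor, cap]", call. = FALSE)
  }
  mult <- if (response >= rule$advance_threshold) rule$advance_mult
          else if (response <= rule$ease_threshold) rule$ease_mult
          else 1.0
  new <- round(current_goal * mult, 1)
  min(max(new, rule$floor), rule$cap)
}

#' Autonomy-supportive language lint
#'
#' Flags controlling words that undermine patient autonomy. The default
#' lexicon is should, must, have to, need to; matching is case-insensitive on
#' word boundaries, so "shoulder" passes.
#'
#' @param text Character string to lint.
#' @param lexicon Forbidden phrases.
#' @return Character vector of offending tokens (empty when clean).
#' @export
autonomy_lint <- function(text,
                          lexicon = c("should", "must", "have to", "need to")) {
  stopifnot(is.character(text))
  found <- character()
  for (phrase in lexicon) {
    pattern <- paste0("\\b", gsub(" ", "\\\\s+", phrase), "\\b")
    if (any(grepl(pattern, text, ignore.case = TRUE, perl = TRUE))) {
      found <- c(found, phrase)
    }
  }
  found
}

#' Load check-in message templates
#'
#' @param path YAML file of templates (id, tone_class, body); defaults to the
#'   shipped set. Every template must pass the autonomy lint; a violating
#'   template aborts the load.
#' @return List of `message_template` objects.
#' @export
load_message_templates <- function(path = NULL) {
  path <- path %||% system.file("extdata", "message_templates_default.yaml",
                                package = "cvhrx", mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  lapply(raw, function(t) {
    if (is.null(t$id) || is.null(t$body) ||
        !t$tone_class %in% c("advance", "hold", "ease")) {
      stop("template must have id, body and tone_class in advance/hold/ease",
           call. = FALSE)
    }
    bad <- autonomy_lint(t$body)
    if (length(bad)) {
      stop("template '", t$id, "' violates the autonomy lint: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    structure(t, class = "message_template")
  })
}

#' Render a check-in message
#'
#' Substitutes `{placeholder}` fields from the context, then applies the
#' autonomy lint to the rendered text. An unresolved placeholder or a
#' controlling-language token is an error.
#'
#' @param template A `message_template` (or list with a `body`).
#' @param context Named list of placeholder values.
#' @return Rendered message text.
#' @export
render_message <- function(template, context = list()) {
  body <- if (is.character(template)) template else template$body
  stopifnot(is.character(body), length(body) == 1)
  text <- body
  for (key in names(context)) {
    text <- gsub(paste0("{", key, "}"), as.character(context[[key]]),
                 text, fixed = TRUE)
  }
  leftover <- regmatches(text, gregexpr("\\{[A-Za-z_][A-Za-z0-9_]*\\}", text))[[1]]
  if (length(leftover)) {
    stop("unresolved placeholders: ", paste(leftover, collapse = ", "),
         call. = FALSE)
  }
  bad <- autonomy_lint(text)
  if (length(bad)) {
    stop("message violates the autonomy lint: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  text
}

#' Record a (stub) message delivery
#'
#' Transport is a stub: appends one JSON line per delivery to a log file and
#' performs no network I/O.
#'
#' @param document_id Identifier of the delivered document/message.
#' @param channel "email", "sms" or "print".
#' @param log_path JSON-lines log file (appended; created if absent).
#' @param timestamp Delivery time (default now, UTC).
#' @return The delivery record, invisibly.
#' @export
record_delivery <- function(document_id, channel = c("email", "sms", "print"),
                            log_path, timestamp = Sys.time()) {
  channel <- match.arg(channel)
  rec <- list(document_id = document_id, channel = channel,
              timestamp = format(timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
              status = "delivered_stub")
  line <- jsonlite::toJSON(rec, auto_unbox = TRUE)
  cat(line, "\n", sep = "", file = log_path, append = TRUE)
  invisible(rec)
}
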