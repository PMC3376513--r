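PSYCHOSOCIAL_SCORES <- c("attitude", "self_efficacy", "social_support",
                         "knowledge", "perceived_benefits",
                         "perceived_barriers")

INTENTION_LEVELS <- c("within_1_month", "within_6_months", "none")

#' Diagnostic questionnaire response
#'
#' The tailoring inputs: demographics, the participant's baseline step
#' level, intention to take more steps, how long the 10,000 steps/day goal
#' has already been maintained, psychosocial scores on 1-5 ordinal scales,
#' and the advice-request history.
#'
#' @param age Years.
#' @param gender Free label (e.g. "female").
#' @param height_cm,weight_kg Body measures.
#' @param baseline_step_level Steps/day reported at the diagnostic
#'   assessment; used when no raw log is supplied.
#' @param intention One of `"within_1_month"`, `"within_6_months"`,
#'   `"none"`, or `NA` (only allowed for participants already at goal).
#' @param goal_maintenance_duration Months the goal has already been met
#'   (0 when not at goal).
#' @param attitude,self_efficacy,social_support,knowledge,perceived_benefits,perceived_barriers
#'   Psychosocial scores, ordinal 1-5.
#' @param request_number How many times advice has been requested,
#'   counting this request (>= 1).
#' @param previous_step_level Steps/day at the previous request; required
#'   iff `request_number >= 2`.
#' @param preferred_weekly_increment Weekly schedule increment the
#'   participant chose (steps/week), one of the configured set.
#'
#' @return A `questionnaire_response` object.
#' @export
questionnaire_response <- function(age, gender, height_cm, weight_kg,
                                   baseline_step_level,
                                   intention,
                                   goal_maintenance_duration = 0,
                                   attitude = 3, self_efficacy = 3,
                                   social_support = 3, knowledge = 3,
                                   perceived_benefits = 3,
                                   perceived_barriers = 3,
                                   request_number = 1,
                                   previous_step_level = NULL,
                                   preferred_weekly_increment = 500) {
  stopifnot(is.numeric(age), age > 0,
            is.numeric(baseline_step_level), baseline_step_level >= 0,
            is.numeric(goal_maintenance_duration),
            goal_maintenance_duration >= 0,
            is.numeric(request_number), request_number >= 1)
  if (!is.na(intention) && !intention %in% INTENTION_LEVELS) {
    stop("intention must be one of ",
         paste(INTENTION_LEVELS, collapse = ", "), call. = FALSE)
  }
  scores <- list(attitude = attitude, self_efficacy = self_efficacy,
                 social_support = social_support, knowledge = knowledge,
                 perceived_benefits = perceived_benefits,
                 perceived_barriers = perceived_barriers)
  for (nm in names(scores)) {
    s <- scores[[nm]]
    if (!is.numeric(s) || length(s) != 1L || s < 1 || s > 5) {
      stop(nm, " must be an ordinal score between 1 and 5", call. = FALSE)
    }
  }
  request_number <- as.integer(request_number)
  if (request_number >= 2L && is.null(previous_step_level)) {
    stop("previous_step_level is required from the second request onward",
         call. = FALSE)
  }
  if (request_number == 1L && !is.null(previous_step_level)) {
    stop("previous_step_level must be absent on a first request",
         call. = FALSE)
  }
  structure(
    c(list(age = age, gender = gender, height_cm = height_cm,
           weight_kg = weight_kg,
           baseline_step_level = as.numeric(baseline_step_level),
           intention = intention,
           goal_maintenance_duration = goal_maintenance_duration),
      scores,
      list(request_number = request_number,
           previous_step_level = previous_step_level,
           preferred_weekly_increment = preferred_weekly_increment)),
    class = "questionnaire_response"
  )
}

#' Read a questionnaire response from JSON
#'
#' Expects a flat JSON object with snake_case keys matching the arguments
#' of [questionnaire_response()].
#'
#' @param path JSON file path.
#' @return A `questionnaire_response`.
#' @export
read_questionnaire <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.list(raw)) {
    stop("questionnaire JSON must be a flat object: ", path, call. = FALSE)
  }
  known <- names(formals(questionnaire_response))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown questionnaire fields: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!is.null(raw$intention) && is.null(raw$intention)) raw$intention <- NA
  do.call(questionnaire_response, raw)
}

#' @export
print.questionnaire_response <- function(x, ...) {
  cat(sprintf(
    "Questionnaire response: %s steps/day baseline, intention %s, request #%d\n",
    format(round(x$baseline_step_level), big.mark = ","),
    if (is.na(x$intention)) "(none recorded)" else x$intention,
    x$request_number))
  invisible(x)
}
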