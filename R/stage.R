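#' Transtheoretical-model stages recognised by the tailoring engine
#' @export
STAGES <- c("precontemplation", "contemplation", "preparation",
            "action", "maintenance")

#' Classify a participant's stage of change
#'
#' Deterministic rule table combining goal status, stated intention, and
#' how long the goal has already been maintained:
#' \itemize{
#'   \item below goal, no intention: precontemplation
#'   \item below goal, intention within 6 months: contemplation
#'   \item below goal, intention within 1 month: preparation
#'   \item at/above goal, maintained < `maintenance_months`: action
#'   \item at/above goal, maintained >= `maintenance_months`: maintenance
#' }
#'
#' @param resp A [questionnaire_response()].
#' @param summary A `step_summary` giving the current mean step level.
#' @param goal Daily step goal.
#' @param maintenance_months Months of sustained attainment separating
#'   action from maintenance (default 6).
#' @return One of [STAGES].
#' @export
classify_stage <- function(resp, summary, goal = 10000,
                           maintenance_months = 6) {
  stopifnot(inherits(resp, "questionnaire_response"),
            inherits(summary, "step_summary"))
  if (meets_step_goal(summary, goal)) {
    if (resp$goal_maintenance_duration >= maintenance_months) {
      return("maintenance")
    }
    return("action")
  }
  if (is.na(resp$intention)) {
    stop("intention is required to stage a participant below the goal",
         call. = FALSE)
  }
  switch(resp$intention,
         none = "precontemplation",
         within_6_months = "contemplation",
         within_1_month = "preparation")
}

#' Address mode for a stage of change
#'
#' Each stage is addressed in a fixed voice: precontemplators impersonally
#' ("people could..."), contemplators personally ("you could..."),
#' preparators decisively ("you should..."), and participants in action or
#' maintenance supportively ("you do...").
#'
#' @param stage One of [STAGES].
#' @return One of `"impersonal"`, `"personal"`, `"decisive"`,
#'   `"supportive"`.
#' @export
address_mode <- function(stage) {
  stage <- match.arg(stage, STAGES)
  switch(stage,
         precontemplation = "impersonal",
         contemplation = "personal",
         preparation = "decisive",
         action = ,
         maintenance = "supportive")
}
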