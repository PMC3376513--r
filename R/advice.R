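#' Normative feedback against the daily step goal
#'
#' Relates a participant's measured step level to the goal and selects the
#' below-goal or at-goal message variant, filling in the mean and the gap
#' to goal.
#'
#' @param summary A `step_summary`.
#' @param goal Daily step goal.
#' @param library Message library; `NULL` loads the packaged one.
#' @param stage Stage used for message filtering (default `"any"`-safe).
#' @return List with `variant` (`"below_goal"`/`"at_goal"`), `gap`
#'   (steps/day, 0 at or above goal), and `messages`.
#' @export
normative_feedback <- function(summary, goal = 10000, library = NULL,
                               stage = "preparation") {
  stopifnot(inherits(summary, "step_summary"))
  if (is.null(library)) library <- read_message_library()
  at_goal <- meets_step_goal(summary, goal)
  gap <- if (at_goal) 0 else goal - summary$mean_steps_per_day
  data <- list(stage = stage,
               below_goal = !at_goal, at_goal = at_goal,
               mean_steps = fmt_steps(summary$mean_steps_per_day),
               gap = fmt_steps(gap), goal = fmt_steps(goal))
  list(variant = if (at_goal) "at_goal" else "below_goal",
       gap = gap,
       messages = select_messages(library, "normative_feedback", data))
}

#' Weekly schedule towards the step goal
#'
#' Weekly targets `baseline + k * increment`, with the final week capped
#' at the goal; a participant already at or above the goal gets an empty
#' schedule.
#'
#' @param baseline Current mean steps/day (>= 0).
#' @param increment Weekly increment in steps (> 0; the published choices
#'   are 500 or 1000).
#' @param goal Daily step goal.
#' @return A `goal_schedule`: list with `increment`, `weekly_targets`,
#'   `weeks_to_goal`, `baseline`, `goal`.
#' @examples
#' build_schedule(8609, 500)
#' @export
build_schedule <- function(baseline, increment, goal = 10000) {
  if (!is.numeric(increment) || length(increment) != 1L || increment <= 0) {
    stop("increment must be a single positive number of steps/week",
         call. = FALSE)
  }
  stopifnot(is.numeric(baseline), length(baseline) == 1L, baseline >= 0,
            goal > 0)
  if (baseline >= goal) {
    targets <- numeric(0)
  } else {
    weeks <- ceiling((goal - baseline) / increment)
    targets <- pmin(baseline + increment * seq_len(weeks), goal)
  }
  structure(
    list(increment = increment, weekly_targets = targets,
         weeks_to_goal = length(targets), baseline = baseline,
         goal = goal),
    class = "goal_schedule"
  )
}

#' @export
print.goal_schedule <- function(x, ...) {
  if (!x$weeks_to_goal) {
    cat("Goal schedule: already at goal, nothing to build up\n")
    return(invisible(x))
  }
  cat(sprintf("Goal schedule: +%d steps/week, %d week(s) to %s steps/day\n",
              as.integer(x$increment), x$weeks_to_goal, fmt_steps(x$goal)))
  for (k in seq_along(x$weekly_targets)) {
    cat(sprintf("  week %d: %s steps/day\n", k,
                fmt_steps(x$weekly_targets[k])))
  }
  invisible(x)
}

#' Progress feedback between two advice requests
#'
#' Compares the step level at the previous request with the current one.
#' Changes larger than `stable_band` in either direction count as positive
#' or negative evolution; anything inside the band is stable. The three
#' categories partition all pairs of levels.
#'
#' @param previous,current Steps/day at the previous and current request
#'   (>= 0).
#' @param stable_band Half-width of the stable band (steps/day).
#' @param library Optional message library; when given, the matching
#'   progress message is rendered.
#' @param stage Stage used for message filtering.
#' @return List with `category` (`"positive"`/`"negative"`/`"stable"`),
#'   `change` (current - previous), and `messages` (possibly empty).
#' @export
progress_feedback <- function(previous, current, stable_band = 500,
                              library = NULL, stage = "preparation") {
  stopifnot(is.numeric(previous), previous >= 0,
            is.numeric(current), current >= 0, stable_band >= 0)
  change <- current - previous
  category <- if (change > stable_band) {
    "positive"
  } else if (-change > stable_band) {
    "negative"
  } else {
    "stable"
  }
  messages <- list()
  if (!is.null(library)) {
    data <- list(stage = stage, evolution = category,
                 previous_steps = fmt_steps(previous),
                 mean_steps = fmt_steps(current),
                 change = fmt_steps(abs(change)))
    messages <- select_messages(library, "progress_feedback", data)
  }
  list(category = category, change = change, messages = messages)
}

tailoring_data <- function(resp, summary, stage, config) {
  at_goal <- meets_step_goal(summary, config$goal)
  list(
    stage = stage,
    address = address_mode(stage),
    below_goal = !at_goal,
    at_goal = at_goal,
    mean_steps = fmt_steps(summary$mean_steps_per_day),
    mean_steps_raw = summary$mean_steps_per_day,
    gap = fmt_steps(max(0, config$goal - summary$mean_steps_per_day)),
    goal = fmt_steps(config$goal),
    request_number = resp$request_number,
    high_barriers = resp$perceived_barriers >= config$barrier_threshold,
    low_self_efficacy =
      resp$self_efficacy <= config$self_efficacy_threshold,
    attitude = resp$attitude,
    self_efficacy = resp$self_efficacy,
    social_support = resp$social_support,
    knowledge = resp$knowledge,
    perceived_benefits = resp$perceived_benefits,
    perceived_barriers = resp$perceived_barriers
  )
}

#' Stage- and profile-filtered tips grouped by life domain
#'
#' Returns tips for the five life domains (work, household chores,
#' gardening, leisure time, transport) plus, for below-goal participants
#' reporting high barriers, a barrier-coping group. Below-goal stages get
#' step-increase tips in the stage's address mode; action and maintenance
#' get relapse-prevention framing instead of a push to step more.
#'
#' @param stage One of [STAGES].
#' @param resp A [questionnaire_response()].
#' @param library Message library; `NULL` loads the packaged one.
#' @param config A [step_config()] (thresholds, goal).
#' @param summary Optional `step_summary`; defaults to the questionnaire's
#'   baseline step level.
#' @return Named list of message lists, one per non-empty domain.
#' @export
select_tips <- function(stage, resp, library = NULL,
                        config = step_config(), summary = NULL) {
  stage <- match.arg(stage, STAGES)
  if (is.null(library)) library <- read_message_library()
  if (is.null(summary)) summary <- step_summary(resp$baseline_step_level)
  data <- tailoring_data(resp, summary, stage, config)
  domains <- c(TIP_DOMAINS, "coping")
  tips <- lapply(domains, function(d) {
    select_messages(library, "tips", data, domain = d)
  })
  names(tips) <- domains
  if (all(!lengths(tips[TIP_DOMAINS]))) {
    stop("message library has no satisfiable tips for stage '", stage,
         "'", call. = FALSE)
  }
  tips[lengths(tips) > 0L]
}

#' Compose a tailored advice document
#'
#' Runs the full tailoring chain: stage classification, then the ordered
#' sections -- introduction (the stage's canonical text), normative
#' feedback, progress feedback (second and later requests only), goal
#' schedule (below-goal stages only), tips by life domain, and standing
#' information blocks. Every emitted message carries its library id and
#' the predicate that admitted it, so the document is auditable.
#'
#' @param resp A [questionnaire_response()].
#' @param summary A `step_summary` of the current step level; `NULL`
#'   falls back to the questionnaire's `baseline_step_level`.
#' @param library Message library; `NULL` loads the packaged one.
#' @param config A [step_config()].
#' @return An `advice_document`.
#' @export
compose_advice <- function(resp, summary = NULL, library = NULL,
                           config = step_config()) {
  stopifnot(inherits(resp, "questionnaire_response"))
  if (is.null(summary)) summary <- step_summary(resp$baseline_step_level)
  if (is.null(library)) {
    library <- read_message_library(config$library_path)
  }
  stage <- classify_stage(resp, summary, config$goal,
                          config$maintenance_months)
  data <- tailoring_data(resp, summary, stage, config)

  intro <- select_messages(library, "introduction", data)
  if (!length(intro)) {
    stop("message library has no introduction for stage '", stage, "'",
         call. = FALSE)
  }

  norm <- normative_feedback(summary, config$goal, library, stage)

  progress <- list()
  progress_meta <- NULL
  if (resp$request_number >= 2L) {
    progress_meta <- progress_feedback(resp$previous_step_level,
                                       summary$mean_steps_per_day,
                                       config$stable_band, library, stage)
    progress <- progress_meta$messages
  }

  schedule_msgs <- list()
  schedule <- NULL
  if (stage %in% c("precontemplation", "contemplation", "preparation")) {
    increment <- resp$preferred_weekly_increment
    if (!increment %in% config$increments) increment <- config$increments[1]
    schedule <- build_schedule(summary$mean_steps_per_day, increment,
                               config$goal)
    sched_data <- c(data, list(
      increment = fmt_steps(schedule$increment),
      weeks_to_goal = schedule$weeks_to_goal,
      schedule_lines = paste(
        sprintf("  Week %d: %s steps a day", seq_along(schedule$weekly_targets),
                vapply(schedule$weekly_targets, fmt_steps, character(1))),
        collapse = "\n")))
    schedule_msgs <- select_messages(library, "schedule", sched_data)
  }

  tips <- select_tips(stage, resp, library, config, summary)

  info <- list()
  for (blk in INFO_BLOCKS) {
    info <- c(info, select_messages(library, "info_blocks", data,
                                    block = blk))
  }

  sections <- list(
    introduction = intro,
    normative_feedback = norm$messages,
    progress_feedback = progress,
    schedule = schedule_msgs,
    tips = unlist(tips, recursive = FALSE, use.names = FALSE),
    info_blocks = info
  )
  trace <- do.call(rbind, lapply(names(sections), function(sec) {
    msgs <- sections[[sec]]
    if (!length(msgs)) return(NULL)
    data.frame(section = sec,
               id = vapply(msgs, `[[`, character(1), "id"),
               when = vapply(msgs, `[[`, character(1), "when"),
               canonical = vapply(msgs, `[[`, logical(1), "canonical"))
  }))
  structure(
    list(participant_id = summary$participant_id,
         stage = stage,
         address_mode = address_mode(stage),
         gap_to_goal = norm$gap,
         evolution = progress_meta$category,
         schedule = schedule,
         sections = sections,
         trace = trace),
    class = "advice_document"
  )
}

#' @export
print.advice_document <- function(x, ...) {
  cat(sprintf("Advice document: stage %s (%s address), %d message(s)\n",
              x$stage, x$address_mode, nrow(x$trace)))
  for (sec in names(x$sections)) {
    n <- length(x$sections[[sec]])
    if (n) cat(sprintf("  %s: %d\n", sec, n))
  }
  invisible(x)
}

SECTION_TITLES <- c(
  introduction = "Introduction",
  normative_feedback = "Your step level and the goal",
  progress_feedback = "Your progress since last time",
  schedule = "A schedule towards the goal",
  tips = "Tips to take more steps",
  info_blocks = "Good to know"
)

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Render an advice document
#'
#' Deterministic rendering to plain text, Markdown, or a standalone HTML
#' fragment; sections with no messages are omitted entirely. The same
#' document always renders to byte-identical output.
#'
#' @param doc An `advice_document`.
#' @param format One of `"text"`, `"markdown"`, `"html"`.
#' @return A single character string.
#' @export
render_advice <- function(doc, format = c("text", "markdown", "html")) {
  stopifnot(inherits(doc, "advice_document"))
  if (length(format) == 1L && !format %in% c("text", "markdown", "html")) {
    stop("unknown advice format: ", format, call. = FALSE)
  }
  format <- match.arg(format)
  out <- character(0)
  title <- "Your personal step advice"
  if (format == "markdown") {
    out <- c(out, paste0("# ", title), "")
  } else if (format == "html") {
    out <- c(out, "<article class=\"step-advice\">",
             paste0("<h1>", html_escape(title), "</h1>"))
  } else {
    out <- c(out, toupper(title), strrep("=", nchar(title)), "")
  }
  for (sec in names(doc$sections)) {
    msgs <- doc$sections[[sec]]
    if (!length(msgs)) next
    heading <- SECTION_TITLES[[sec]]
    texts <- vapply(msgs, `[[`, character(1), "text")
    if (format == "markdown") {
      out <- c(out, paste0("## ", heading), "",
               unlist(lapply(texts, c, "")))
    } else if (format == "html") {
      out <- c(out, paste0("<h2>", html_escape(heading), "</h2>"),
               paste0("<p>", gsub("\n", "<br/>", html_escape(texts),
                                  fixed = TRUE), "</p>"))
    } else {
      out <- c(out, heading, strrep("-", nchar(heading)),
               unlist(lapply(texts, c, "")))
    }
  }
  if (format == "html") out <- c(out, "</article>")
  paste(out, collapse = "\n")
}
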