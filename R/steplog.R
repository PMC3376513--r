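#' @title Seven-day pedometer step logs
#' @description Construct a step log from per-day records. A log holds one
#'   row per calendar day (pedometer steps; `NA` marks a day the pedometer
#'   was not read, which makes the day invalid) plus zero or more
#'   non-ambulatory activity entries (kind, minutes) attached to days.
#'
#' @param participant_id Opaque participant label.
#' @param days data.frame with columns `date` (Date, unique) and `steps`
#'   (non-negative integer or `NA`).
#' @param activities data.frame with columns `date` (Date, matching a day
#'   in `days`), `activity` (character label), `minutes` (non-negative).
#'   Defaults to no activities.
#'
#' @return A `step_log` object: the validated inputs with `days` sorted by
#'   date.
#' @examples
#' log <- step_log("p1", data.frame(date = as.Date("2010-03-01") + 0:6,
#'                                  steps = c(8000, 9500, 7000, 10000,
#'                                            12000, 6000, 9000)))
#' summarize_log(log)
#' @export
step_log <- function(participant_id, days, activities = NULL) {
  stopifnot(is.data.frame(days), all(c("date", "steps") %in% names(days)))
  days$date <- as.Date(days$date)
  if (anyNA(days$date)) {
    stop("step log ", participant_id, ": unparseable dates", call. = FALSE)
  }
  if (anyDuplicated(days$date)) {
    stop("step log ", participant_id, ": duplicate dates", call. = FALSE)
  }
  if (any(days$steps < 0, na.rm = TRUE)) {
    stop("step log ", participant_id, ": negative step counts",
         call. = FALSE)
  }
  days <- days[order(days$date), c("date", "steps"), drop = FALSE]
  rownames(days) <- NULL
  if (is.null(activities)) {
    activities <- data.frame(date = as.Date(character()),
                             activity = character(),
                             minutes = numeric())
  }
  stopifnot(is.data.frame(activities),
            all(c("date", "activity", "minutes") %in% names(activities)))
  activities$date <- as.Date(activities$date)
  if (any(activities$minutes < 0, na.rm = TRUE)) {
    stop("step log ", participant_id, ": negative activity minutes",
         call. = FALSE)
  }
  if (nrow(activities) && !all(activities$date %in% days$date)) {
    stop("step log ", participant_id,
         ": activity entries on dates absent from the log", call. = FALSE)
  }
  structure(
    list(participant_id = as.character(participant_id),
         days = days,
         activities = activities[, c("date", "activity", "minutes"),
                                 drop = FALSE]),
    class = "step_log"
  )
}

#' Read a step-log CSV
#'
#' The dialect is `date,steps,activity,activity_minutes` with ISO-8601
#' dates, one row per day; additional rows repeating a date with a
#' non-empty `activity` attach further activities to that day. A day row
#' itself may also carry an activity.
#'
#' @param path CSV file path.
#' @param participant_id Label for the log; defaults to the file name
#'   without extension.
#' @return A [step_log()] object.
#' @export
read_step_log <- function(path, participant_id = NULL) {
  if (is.null(participant_id)) {
    participant_id <- tools::file_path_sans_ext(basename(path))
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(date = "character",
                                        activity = "character"),
                         na.strings = "")
  needed <- c("date", "steps", "activity", "activity_minutes")
  if (!all(needed %in% names(raw))) {
    stop("step-log CSV must have header ", paste(needed, collapse = ","),
         ": ", path, call. = FALSE)
  }
  raw$date <- as.Date(raw$date)
  first <- !duplicated(raw$date)
  extra_steps <- !first & !is.na(raw$steps)
  if (any(extra_steps)) {
    stop("step-log CSV ", path, ": repeated dates must leave steps empty",
         call. = FALSE)
  }
  days <- data.frame(date = raw$date[first], steps = raw$steps[first])
  has_act <- !is.na(raw$activity) & nzchar(raw$activity)
  activities <- data.frame(
    date = raw$date[has_act],
    activity = raw$activity[has_act],
    minutes = as.numeric(raw$activity_minutes[has_act])
  )
  if (anyNA(activities$minutes)) {
    stop("step-log CSV ", path, ": activity rows need activity_minutes",
         call. = FALSE)
  }
  step_log(participant_id, days, activities)
}

#' Write a step log in the CSV dialect read by [read_step_log()]
#'
#' @param log A `step_log`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_step_log <- function(log, path) {
  stopifnot(inherits(log, "step_log"))
  rows <- data.frame(date = format(log$days$date), steps = log$days$steps,
                     activity = "", activity_minutes = NA_real_,
                     stringsAsFactors = FALSE)
  acts <- log$activities
  if (nrow(acts)) {
    # first activity per day rides on the day row; the rest repeat the date
    idx <- match(acts$date, log$days$date)
    taken <- rep(FALSE, nrow(rows))
    extra <- list()
    for (i in seq_len(nrow(acts))) {
      j <- idx[i]
      if (!taken[j]) {
        rows$activity[j] <- acts$activity[i]
        rows$activity_minutes[j] <- acts$minutes[i]
        taken[j] <- TRUE
      } else {
        extra[[length(extra) + 1L]] <- data.frame(
          date = format(acts$date[i]), steps = NA_real_,
          activity = acts$activity[i], activity_minutes = acts$minutes[i],
          stringsAsFactors = FALSE)
      }
    }
    if (length(extra)) rows <- rbind(rows, do.call(rbind, extra))
    rows <- rows[order(rows$date, is.na(rows$steps) | rows$steps < 0), ]
  }
  utils::write.csv(rows, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Credit non-ambulatory activity to a day's step total
#'
#' Adds `conversion_rate` steps for every minute of activity whose kind is
#' in the convertible set (by default biking and swimming, at 150
#' steps/minute); other activities contribute nothing.
#'
#' @param steps Ambulatory pedometer steps for the day (>= 0).
#' @param activities data.frame with columns `activity` and `minutes`, or
#'   `NULL` for none.
#' @param conversion_rate Steps credited per convertible minute (> 0).
#' @param convertible_activities Labels of convertible activity kinds.
#' @return The adjusted daily step total.
#' @examples
#' adjust_daily_steps(8000, data.frame(activity = "biking", minutes = 20))
#' @export
adjust_daily_steps <- function(steps, activities = NULL,
                               conversion_rate = 150,
                               convertible_activities = c("biking",
                                                          "swimming")) {
  if (length(steps) != 1L || is.na(steps) || steps < 0) {
    stop("steps must be a single non-negative count", call. = FALSE)
  }
  if (conversion_rate < 0) {
    stop("conversion_rate must be non-negative", call. = FALSE)
  }
  if (is.null(activities) || nrow(activities) == 0L) {
    return(as.numeric(steps))
  }
  if (any(activities$minutes < 0)) {
    stop("activity durations must be non-negative", call. = FALSE)
  }
  convertible <- activities$activity %in% convertible_activities
  as.numeric(steps) + conversion_rate * sum(activities$minutes[convertible])
}

#' Truncate a daily step total at the cap
#'
#' Values over the cap (default 20,000 steps/day) are recorded as the cap,
#' limiting unrealistically high daily totals.
#'
#' @param steps Daily step totals (>= 0); vectorised.
#' @param cap Truncation cap (> 0).
#' @return `pmin(steps, cap)`.
#' @export
truncate_daily <- function(steps, cap = 20000) {
  if (any(steps < 0, na.rm = TRUE)) {
    stop("steps must be non-negative", call. = FALSE)
  }
  if (length(cap) != 1L || cap <= 0) {
    stop("cap must be a single positive count", call. = FALSE)
  }
  pmin(steps, cap)
}

#' Summarise a step log into a mean daily step level
#'
#' Each valid day (a day with a recorded step count) is adjusted for
#' convertible non-ambulatory activity and then truncated at the cap; the
#' summary is the arithmetic mean over valid days. Logs with fewer than
#' `min_valid_days` valid days (default 5) are rejected with an
#' `insufficient-data` error naming the log.
#'
#' @param log A [step_log()].
#' @param min_valid_days Minimum number of valid days (>= 1).
#' @param cap Daily truncation cap.
#' @param conversion_rate,convertible_activities Passed to
#'   [adjust_daily_steps()].
#' @return A `step_summary`: list with `participant_id`,
#'   `mean_steps_per_day`, `n_valid_days`, `any_truncated`.
#' @export
summarize_log <- function(log, min_valid_days = 5, cap = 20000,
                          conversion_rate = 150,
                          convertible_activities = c("biking", "swimming")) {
  stopifnot(inherits(log, "step_log"), min_valid_days >= 1)
  valid <- !is.na(log$days$steps)
  n_valid <- sum(valid)
  if (n_valid < min_valid_days) {
    stop(structure(
      class = c("steptailor_insufficient_data", "error", "condition"),
      list(message = sprintf(
             "step log '%s': %d valid day(s), fewer than the required %d",
             log$participant_id, n_valid, as.integer(min_valid_days)),
           call = NULL)))
  }
  dates <- log$days$date[valid]
  adjusted <- vapply(seq_along(dates), function(i) {
    acts <- log$activities[log$activities$date == dates[i], , drop = FALSE]
    adjust_daily_steps(log$days$steps[valid][i], acts,
                       conversion_rate = conversion_rate,
                       convertible_activities = convertible_activities)
  }, numeric(1))
  capped <- truncate_daily(adjusted, cap)
  structure(
    list(participant_id = log$participant_id,
         mean_steps_per_day = mean(capped),
         n_valid_days = n_valid,
         any_truncated = any(adjusted > cap)),
    class = "step_summary"
  )
}

#' Make a step summary directly from a known mean level
#'
#' Used when a participant's step level arrives already averaged (for
#' example from a questionnaire) rather than as a raw log.
#'
#' @param mean_steps_per_day Mean daily steps (>= 0).
#' @param n_valid_days Number of days behind the mean.
#' @param participant_id Optional label.
#' @return A `step_summary`.
#' @export
step_summary <- function(mean_steps_per_day, n_valid_days = 7,
                         participant_id = NA_character_) {
  stopifnot(is.numeric(mean_steps_per_day), mean_steps_per_day >= 0,
            n_valid_days >= 1)
  structure(
    list(participant_id = participant_id,
         mean_steps_per_day = as.numeric(mean_steps_per_day),
         n_valid_days = as.integer(n_valid_days),
         any_truncated = FALSE),
    class = "step_summary"
  )
}

#' Does a step summary meet the daily goal?
#'
#' @param summary A `step_summary`.
#' @param goal Daily step goal (> 0); the comparison is inclusive.
#' @return `TRUE` iff the mean daily steps reach the goal.
#' @export
meets_step_goal <- function(summary, goal = 10000) {
  stopifnot(inherits(summary, "step_summary"), goal > 0)
  summary$mean_steps_per_day >= goal
}

#' @export
print.step_summary <- function(x, ...) {
  cat(sprintf("Step summary%s: %s steps/day over %d valid day(s)%s\n",
              if (is.na(x$participant_id)) "" else
                paste0(" [", x$participant_id, "]"),
              format(round(x$mean_steps_per_day), big.mark = ","),
              x$n_valid_days,
              if (x$any_truncated) " (daily cap applied)" else ""))
  invisible(x)
}

#' @export
print.step_log <- function(x, ...) {
  cat(sprintf("Step log [%s]: %d day(s), %d activity entr%s\n",
              x$participant_id, nrow(x$days), nrow(x$activities),
              if (nrow(x$activities) == 1L) "y" else "ies"))
  invisible(x)
}
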