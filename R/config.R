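#' Run configuration for the step-advice pipeline
#'
#' Bundles the constants shared across modules. Defaults are the published
#' protocol values: a 10,000 steps/day goal, weekly increments of 500 or
#' 1000 steps, a 20,000 steps/day truncation cap, a minimum of 5 valid
#' registration days, and 150 credited steps per minute of biking or
#' swimming.
#'
#' @param goal Daily step goal (steps/day).
#' @param increments Allowed weekly schedule increments (steps/week).
#' @param cap Daily truncation cap (steps/day).
#' @param min_valid_days Minimum number of valid log days required.
#' @param conversion_rate Steps credited per minute of convertible
#'   non-ambulatory activity.
#' @param convertible_activities Activity labels credited at
#'   `conversion_rate`.
#' @param stable_band Half-width (steps/day) of the "stable" band for
#'   progress feedback; changes within `stable_band` of zero count as
#'   neither positive nor negative evolution.
#' @param barrier_threshold Perceived-barriers score (1-5 ordinal) at or
#'   above which barrier-coping content is included.
#' @param self_efficacy_threshold Self-efficacy score (1-5 ordinal) at or
#'   below which confidence-building content is included.
#' @param maintenance_months Months of sustained goal attainment that
#'   separate the action and maintenance stages.
#' @param library_path Path to a message-library YAML file; `NULL` uses
#'   the library shipped with the package.
#' @param format Default rendering format for advice documents.
#'
#' @return An object of class `step_config` (a validated list).
#' @examples
#' cfg <- step_config()
#' cfg$goal
#' @export
step_config <- function(goal = 10000,
                        increments = c(500, 1000),
                        cap = 20000,
                        min_valid_days = 5,
                        conversion_rate = 150,
                        convertible_activities = c("biking", "swimming"),
                        stable_band = 500,
                        barrier_threshold = 4,
                        self_efficacy_threshold = 2,
                        maintenance_months = 6,
                        library_path = NULL,
                        format = "text") {
  stopifnot(
    is.numeric(goal), length(goal) == 1L, goal > 0,
    is.numeric(increments), length(increments) >= 1L, all(increments > 0),
    is.numeric(cap), length(cap) == 1L, cap > 0,
    is.numeric(min_valid_days), length(min_valid_days) == 1L,
    min_valid_days >= 1,
    is.numeric(conversion_rate), length(conversion_rate) == 1L,
    conversion_rate >= 0,
    is.character(convertible_activities),
    is.numeric(stable_band), length(stable_band) == 1L, stable_band >= 0,
    is.numeric(maintenance_months), maintenance_months >= 0
  )
  format <- match.arg(format, c("text", "markdown", "html", "tsv"))
  structure(
    list(
      goal = goal,
      increments = sort(increments),
      cap = cap,
      min_valid_days = min_valid_days,
      conversion_rate = conversion_rate,
      convertible_activities = convertible_activities,
      stable_band = stable_band,
      barrier_threshold = barrier_threshold,
      self_efficacy_threshold = self_efficacy_threshold,
      maintenance_months = maintenance_months,
      library_path = library_path,
      format = format
    ),
    class = "step_config"
  )
}

#' Load a run configuration from a YAML file
#'
#' Reads a flat YAML mapping whose keys are [step_config()] arguments and
#' merges it over the defaults; keys absent from the file keep their
#' default value.
#'
#' @param path Path to a YAML configuration file.
#' @return A `step_config` object.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) {
    stop("configuration file must contain a YAML mapping: ", path,
         call. = FALSE)
  }
  known <- names(formals(step_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(step_config, raw)
}

#' @export
print.step_config <- function(x, ...) {
  cat("Step-advice configuration\n")
  cat(sprintf("  goal: %s steps/day; cap: %s; min valid days: %d\n",
              format(x$goal, big.mark = ","),
              format(x$cap, big.mark = ","), as.integer(x$min_valid_days)))
  cat(sprintf("  increments: %s steps/week; conversion: %g steps/min (%s)\n",
              paste(x$increments, collapse = "/"), x$conversion_rate,
              paste(x$convertible_activities, collapse = ", ")))
  invisible(x)
}
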