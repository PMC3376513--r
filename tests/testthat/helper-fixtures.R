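# Shared fixture builders; all data are constructed in code.

make_log <- function(steps, start = as.Date("2010-03-01"),
                     activities = NULL, id = "t1") {
  step_log(id, data.frame(date = start + seq_along(steps) - 1L,
                          steps = steps), activities)
}

make_resp <- function(baseline = 8000, intention = "within_1_month",
                      maintenance = 0, request = 1, previous = NULL,
                      barriers = 3, self_efficacy = 3, ...) {
  questionnaire_response(
    age = 47, gender = "female", height_cm = 168, weight_kg = 70,
    baseline_step_level = baseline, intention = intention,
    goal_maintenance_duration = maintenance,
    perceived_barriers = barriers, self_efficacy = self_efficacy,
    request_number = request, previous_step_level = previous, ...)
}

read_golden_intros <- function() {
  path <- test_path("golden-stage-introductions.tsv")
  raw <- readLines(path, encoding = "UTF-8")
  parts <- strsplit(raw, "\t", fixed = TRUE)
  stats::setNames(vapply(parts, `[[`, character(1), 2),
                  vapply(parts, `[[`, character(1), 1))
}

# balanced/unbalanced random two-timepoint dataset for ANOVA checks
make_random_dataset <- function(n1, n2, effect = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- n1 + n2
  cond <- c(rep("tailored", n1), rep("standard", n2))
  base <- stats::rnorm(n, 9000, 3000)
  post <- base + stats::rnorm(n, 500, 2000) +
    ifelse(cond == "tailored", effect, 0)
  records <- data.frame(id = sprintf("R%03d", seq_len(n)),
                        condition = cond, dropout = FALSE)
  for (outcome in c("bmi", "walking", "totalpa", "steps", "sitting")) {
    records[[paste0(outcome, "_base")]] <- base
    records[[paste0(outcome, "_post")]] <- post
  }
  trial_dataset(records)
}

# independent split-plot oracle: explicit cell/subject-mean sums of squares
# over the long-format table (textbook decomposition, no change-score
# shortcut)
anova_oracle <- function(dataset, outcome) {
  records <- dataset$records
  base <- records[[paste0(outcome, "_base")]]
  post <- records[[paste0(outcome, "_post")]]
  keep <- !is.na(base) & !is.na(post)
  long <- data.frame(
    y = c(base[keep], post[keep]),
    time = rep(c("base", "post"), each = sum(keep)),
    cond = rep(records$condition[keep], 2),
    id = rep(records$id[keep], 2))
  n <- sum(keep)
  grand <- mean(long$y)
  subj_mean <- tapply(long$y, long$id, mean)
  # within-subject stratum: deviations from each subject's own mean
  w <- long$y - subj_mean[long$id]
  time_mean <- tapply(w, long$time, mean)
  ss_time <- sum((time_mean[long$time])^2)
  cell_mean <- tapply(w, list(long$cond, long$time), mean)
  fitted_ct <- cell_mean[cbind(long$cond, long$time)]
  ss_int <- sum(fitted_ct^2) - ss_time
  ss_err <- sum((w - fitted_ct)^2)
  df_err <- n - 2
  list(F_time = ss_time / (ss_err / df_err),
       F_interaction = ss_int / (ss_err / df_err),
       df_err = df_err)
}

write_temp_questionnaire <- function(..., path = withr::local_tempfile(
                                       fileext = ".json",
                                       .local_envir = parent.frame())) {
  fields <- list(age = 47, gender = "female", height_cm = 168,
                 weight_kg = 70, baseline_step_level = 8000,
                 intention = "within_1_month")
  extra <- list(...)
  fields[names(extra)] <- extra
  writeLines(jsonlite::toJSON(fields, auto_unbox = TRUE, null = "null"),
             path)
  path
}
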