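TRIAL_OUTCOMES <- c(bmi = "kg/m2", walking = "min/day",
                    totalpa = "min/day", steps = "steps/day",
                    sitting = "h/day")

TRIAL_ARMS <- c("tailored", "standard")

#' Two-arm, two-timepoint trial dataset
#'
#' Wraps a data.frame with columns `id`, `condition`
#' (`tailored`/`standard`), `dropout`, and `<outcome>_base` /
#' `<outcome>_post` for the five outcomes (bmi kg/m2, walking min/day,
#' totalpa min/day, steps steps/day, sitting h/day). Missing values are
#' `NA`; a flagged dropout must be missing at least one postintervention
#' value.
#'
#' @param records The records data.frame.
#' @param arms Arm labels (first label is the intervention arm).
#' @return A `trial_dataset`.
#' @export
trial_dataset <- function(records, arms = TRIAL_ARMS) {
  stopifnot(is.data.frame(records))
  needed <- c("id", "condition", "dropout",
              paste0(rep(names(TRIAL_OUTCOMES), each = 2),
                     c("_base", "_post")))
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stop("cohort is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(records$id)) {
    stop("participant ids must be unique", call. = FALSE)
  }
  if (!all(records$condition %in% arms)) {
    stop("condition must be one of: ", paste(arms, collapse = ", "),
         call. = FALSE)
  }
  if (length(unique(records$condition)) < 2L) {
    stop("both trial arms must be present", call. = FALSE)
  }
  records$dropout <- as.logical(records$dropout)
  post_cols <- paste0(names(TRIAL_OUTCOMES), "_post")
  any_missing_post <- rowSums(is.na(records[post_cols])) > 0L
  bad <- records$dropout & !any_missing_post
  if (any(bad)) {
    stop("dropout flagged but no postintervention value missing for: ",
         paste(records$id[bad], collapse = ", "), call. = FALSE)
  }
  structure(list(records = records, arms = arms,
                 outcomes = TRIAL_OUTCOMES),
            class = "trial_dataset")
}

#' Read a trial cohort CSV
#'
#' Dialect: header `id,condition,dropout,bmi_base,bmi_post,walking_base,
#' walking_post,totalpa_base,totalpa_post,steps_base,steps_post,
#' sitting_base,sitting_post`; empty fields are missing; `dropout` is
#' `TRUE`/`FALSE` or 1/0.
#'
#' @param path CSV file path.
#' @return A [trial_dataset()].
#' @export
read_cohort <- function(path) {
  records <- utils::read.csv(path, stringsAsFactors = FALSE,
                             na.strings = "")
  if ("dropout" %in% names(records)) {
    records$dropout <- as.logical(records$dropout) |
      (records$dropout %in% c(1, "1"))
  }
  trial_dataset(records)
}

#' Write a trial cohort CSV in the dialect read by [read_cohort()]
#'
#' @param dataset A `trial_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(dataset, path) {
  stopifnot(inherits(dataset, "trial_dataset"))
  records <- dataset$records
  records$dropout <- ifelse(records$dropout, "TRUE", "FALSE")
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.trial_dataset <- function(x, ...) {
  tab <- table(x$records$condition)
  cat(sprintf("Trial dataset: %d participants (%s), %d dropout(s)\n",
              nrow(x$records),
              paste(sprintf("%s n=%d", names(tab), tab), collapse = ", "),
              sum(x$records$dropout)))
  invisible(x)
}
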