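default_log_outcomes <- c("walking", "totalpa")

#' Baseline comparison table (group summaries plus tests)
#'
#' Builds a comparison table in the style of a trial's baseline table:
#' one row per outcome with the per-group mean (SD) or n (%), the test
#' statistic with its degrees of freedom, and the p-value. Quantitative
#' outcomes are compared with [welch_t()]; qualitative outcomes with
#' [chi_square()]. Right-skewed minutes/day outcomes can be tested on the
#' log scale while the displayed means and SDs stay untransformed.
#'
#' @param dataset A [trial_dataset()].
#' @param group Grouping column: `"condition"` (the trial arms) or
#'   `"dropout"` (completers vs dropouts).
#' @param outcomes Character vector naming quantitative outcomes (subset
#'   of `names(dataset$outcomes)`); all five by default.
#' @param qualitative Character vector of additional qualitative columns
#'   in the records to compare with a chi-square test.
#' @param time Which timepoint's values to compare (`"base"` or
#'   `"post"`).
#' @param log_outcomes Outcomes whose test (not display) uses
#'   `log(value + 1)`.
#' @return A data.frame of class `comparison_table` with one row per
#'   outcome: `outcome`, `type`, one summary column per group level,
#'   `test`, `statistic`, `df`, `p`.
#' @export
build_comparison_table <- function(dataset, group = "condition",
                                   outcomes = names(dataset$outcomes),
                                   qualitative = character(0),
                                   time = "base",
                                   log_outcomes = default_log_outcomes) {
  stopifnot(inherits(dataset, "trial_dataset"))
  group <- match.arg(group, c("condition", "dropout"))
  time <- match.arg(time, c("base", "post"))
  unknown <- setdiff(outcomes, names(dataset$outcomes))
  if (length(unknown)) {
    stop("unknown outcome(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  records <- dataset$records
  g <- if (group == "condition") {
    factor(records$condition, levels = dataset$arms)
  } else {
    factor(ifelse(records$dropout, "dropout", "completer"),
           levels = c("completer", "dropout"))
  }
  levels_g <- levels(g)
  rows <- list()
  for (outcome in outcomes) {
    values <- records[[paste0(outcome, "_", time)]]
    keep <- !is.na(values)
    summaries <- lapply(levels_g, function(lv) {
      v <- values[keep & g == lv]
      group_summary(length(v), mean(v), stats::sd(v))
    })
    test_values <- if (outcome %in% log_outcomes) {
      log_transform_outcome(values)
    } else {
      values
    }
    test_summaries <- lapply(levels_g, function(lv) {
      v <- test_values[keep & g == lv]
      group_summary(length(v), mean(v), stats::sd(v))
    })
    tt <- welch_t(test_summaries[[1]], test_summaries[[2]])
    cells <- vapply(summaries, function(s) {
      sprintf("%s (%s)", signif(s$mean, 4), signif(s$sd, 4))
    }, character(1))
    names(cells) <- levels_g
    rows[[length(rows) + 1L]] <- data.frame(
      outcome = outcome, type = "quantitative", t(cells),
      test = tt$method, statistic = abs(tt$statistic), df = tt$df,
      p = tt$p, check.names = FALSE)
  }
  for (qual in qualitative) {
    if (!qual %in% names(records)) {
      stop("unknown outcome: ", qual, call. = FALSE)
    }
    tab <- table(records[[qual]], g)
    ct <- chi_square(tab)
    cells <- vapply(levels_g, function(lv) {
      paste(sprintf("%s: %d (%.0f%%)", rownames(tab), tab[, lv],
                    100 * tab[, lv] / sum(tab[, lv])), collapse = "; ")
    }, character(1))
    rows[[length(rows) + 1L]] <- data.frame(
      outcome = qual, type = "qualitative", t(cells),
      test = ct$method, statistic = ct$statistic, df = ct$df, p = ct$p,
      check.names = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("comparison_table", "data.frame")
  out
}

#' Time and time-by-condition effects table
#'
#' One [mixed_anova()] per outcome, laid out with one row per arm:
#' complete-case n, baseline and postintervention mean (SD) on the raw
#' scale, the within-arm change with its 95% CI, and the F statistics and
#' p-values for the time and time x condition effects.
#'
#' @inheritParams build_comparison_table
#' @return A data.frame of class `effects_table`.
#' @export
build_effects_table <- function(dataset,
                                outcomes = names(dataset$outcomes),
                                log_outcomes = default_log_outcomes) {
  stopifnot(inherits(dataset, "trial_dataset"))
  rows <- lapply(outcomes, function(outcome) {
    fit <- mixed_anova(dataset, outcome,
                       log_transform = outcome %in% log_outcomes)
    pa <- fit$per_arm
    data.frame(
      outcome = outcome, condition = pa$condition, n = pa$n,
      baseline = sprintf("%s (%s)", signif(pa$baseline_mean, 4),
                         signif(pa$baseline_sd, 4)),
      postintervention = sprintf("%s (%s)", signif(pa$post_mean, 4),
                                 signif(pa$post_sd, 4)),
      change = sprintf("%s (%s to %s)", signif(pa$change, 4),
                       signif(pa$ci_lower, 4), signif(pa$ci_upper, 4)),
      F_interaction = fit$F_interaction, p_interaction = fit$p_interaction,
      F_time = fit$F_time, p_time = fit$p_time)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("effects_table", "data.frame")
  out
}

#' Format a result table as TSV or Markdown
#'
#' @param table A data.frame (e.g. from [build_comparison_table()] or
#'   [build_effects_table()]).
#' @param format `"tsv"` or `"markdown"`.
#' @return A single character string.
#' @export
format_table <- function(table, format = c("tsv", "markdown")) {
  format <- match.arg(format)
  df <- as.data.frame(table)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) as.character(signif(x, 4)))
  if (format == "tsv") {
    con <- textConnection("out", "w", local = TRUE)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
    return(paste(out, collapse = "\n"))
  }
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(df, 1, function(r) {
    paste0("| ", paste(r, collapse = " | "), " |")
  })
  paste(c(header, sep, body), collapse = "\n")
}
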