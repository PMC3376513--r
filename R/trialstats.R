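#' Group summary (n, mean, SD)
#'
#' The per-arm summary cells of a baseline-comparison table.
#'
#' @param n Group size (>= 2).
#' @param mean Group mean.
#' @param sd Group standard deviation (>= 0).
#' @return A `group_summary`.
#' @export
group_summary <- function(n, mean, sd) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 2,
            is.numeric(mean), length(mean) == 1L,
            is.numeric(sd), length(sd) == 1L, sd >= 0)
  structure(list(n = as.integer(n), mean = mean, sd = sd),
            class = "group_summary")
}

test_result <- function(statistic, df, p, method) {
  structure(list(statistic = statistic, df = df, p = p, method = method),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic %.3f, df %s, p = %.4g\n", x$method,
              x$statistic,
              paste(signif(x$df, 4), collapse = ", "), x$p))
  invisible(x)
}

#' Two-sample t test from group summaries
#'
#' Computes the independent-samples t statistic directly from (n, mean,
#' sd) summaries. The default is the unequal-variance (Welch) form with
#' Satterthwaite degrees of freedom; `pooled = TRUE` gives the classic
#' equal-variance test.
#'
#' @param a,b [group_summary()] objects (or lists with `n`, `mean`, `sd`).
#' @param pooled Use the pooled-variance test instead of Welch.
#' @return A `test_result` with the signed t statistic, df, and two-sided
#'   p-value.
#' @examples
#' welch_t(group_summary(45, 46.6, 10.9), group_summary(47, 47.7, 11.4))
#' @export
welch_t <- function(a, b, pooled = FALSE) {
  for (g in list(a, b)) {
    if (is.null(g$n) || g$n < 2) {
      stop("both groups need n >= 2", call. = FALSE)
    }
  }
  va <- a$sd^2 / a$n
  vb <- b$sd^2 / b$n
  if (pooled) {
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
    df <- a$n + b$n - 2
  } else {
    se <- sqrt(va + vb)
    df <- if (va + vb == 0) {
      a$n + b$n - 2  # formula limit when both variances vanish
    } else {
      (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
    }
  }
  t <- if (se == 0) 0 else (a$mean - b$mean) / se
  test_result(t, df, 2 * stats::pt(-abs(t), df),
              if (pooled) "pooled t" else "Welch t")
}

#' Pearson chi-square test on a contingency table
#'
#' Uncorrected Pearson chi-square (no Yates continuity correction) on an
#' r x c table of counts, with expected counts from the margins and
#' df = (r-1)(c-1).
#'
#' @param table Matrix of non-negative counts, at least 2 x 2.
#' @return A `test_result`.
#' @examples
#' chi_square(matrix(c(17, 28, 21, 26), 2, byrow = TRUE))
#' @export
chi_square <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2L || ncol(table) < 2L) {
    stop("contingency table must be at least 2 x 2", call. = FALSE)
  }
  if (any(table < 0) || anyNA(table)) {
    stop("counts must be non-negative and complete", call. = FALSE)
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero row or column margin: expected counts undefined",
         call. = FALSE)
  }
  fit <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  test_result(unname(fit$statistic), unname(fit$parameter),
              unname(fit$p.value), "Pearson chi-square")
}

#' Log-transform a non-negative outcome
#'
#' Natural log of `value + offset`, used to normalise right-skewed
#' minutes/day outcomes before testing. Reporting stays on the raw scale;
#' only test statistics use the transformed values.
#'
#' @param values Non-negative numeric vector (`NA` passed through).
#' @param offset Added before the log (default 1, so zeros map to 0).
#' @return `log(values + offset)`.
#' @export
log_transform_outcome <- function(values, offset = 1) {
  if (any(values < 0, na.rm = TRUE)) {
    stop("values must be non-negative", call. = FALSE)
  }
  log(values + offset)
}

#' Carry baseline forward for dropouts (intent-to-treat)
#'
#' Replaces every missing postintervention value with that participant's
#' baseline value, so dropouts contribute a change of zero; complete
#' records are untouched. The operation is idempotent.
#'
#' @param dataset A [trial_dataset()].
#' @return A `trial_dataset` with no missing postintervention values.
#' @export
intent_to_treat <- function(dataset) {
  stopifnot(inherits(dataset, "trial_dataset"))
  records <- dataset$records
  for (outcome in names(dataset$outcomes)) {
    base_col <- paste0(outcome, "_base")
    post_col <- paste0(outcome, "_post")
    fill <- is.na(records[[post_col]])
    if (any(fill & is.na(records[[base_col]]))) {
      bad <- records$id[fill & is.na(records[[base_col]])]
      stop("cannot impute '", outcome, "': baseline missing for ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    records[[post_col]][fill] <- records[[base_col]][fill]
  }
  records$dropout <- FALSE
  trial_dataset(records, dataset$arms)
}

#' Two-condition x two-timepoint mixed repeated-measures ANOVA
#'
#' Splits the within-subject stratum of a split-plot design with
#' condition as the between-participants factor and time (baseline,
#' postintervention) as the within-participants factor. With two
#' timepoints the within-subject stratum reduces to the change scores
#' d = post - base, giving sequential sums of squares
#' \deqn{SS_{time} = N \bar d^2 / 2,\quad
#'       SS_{time \times cond} = \sum_g n_g (\bar d_g - \bar d)^2 / 2,\quad
#'       SS_{err} = \sum_i (d_i - \bar d_{g(i)})^2 / 2,}
#' each F on (1, N - 2) df. Per-arm mean changes carry 95% t-based
#' confidence intervals from the within-arm change distribution.
#'
#' @param dataset A [trial_dataset()]; only participants with both
#'   timepoints for `outcome` enter (a retained-sample analysis; apply
#'   [intent_to_treat()] first for the ITT analysis).
#' @param outcome One of `names(dataset$outcomes)`.
#' @param log_transform Test on `log(value + offset)`; descriptive means,
#'   changes and CIs stay on the raw scale.
#' @param offset Offset for the log transform.
#' @param conf_level Confidence level for the per-arm change intervals.
#' @return An `anova_result`: F and p for time and time x condition, df,
#'   and a per-arm data.frame (`n`, baseline/post mean and sd, `change`,
#'   `ci_lower`, `ci_upper`).
#' @export
mixed_anova <- function(dataset, outcome, log_transform = FALSE,
                        offset = 1, conf_level = 0.95) {
  stopifnot(inherits(dataset, "trial_dataset"))
  if (!outcome %in% names(dataset$outcomes)) {
    stop("unknown outcome: ", outcome, call. = FALSE)
  }
  records <- dataset$records
  base <- records[[paste0(outcome, "_base")]]
  post <- records[[paste0(outcome, "_post")]]
  keep <- !is.na(base) & !is.na(post)
  records <- records[keep, , drop = FALSE]
  base <- base[keep]
  post <- post[keep]
  g <- factor(records$condition, levels = dataset$arms)
  n_g <- table(g)
  if (any(n_g < 2)) {
    stop("need at least 2 complete participants per arm for '", outcome,
         "'", call. = FALSE)
  }
  tb <- if (log_transform) log_transform_outcome(base, offset) else base
  tp <- if (log_transform) log_transform_outcome(post, offset) else post
  d <- tp - tb
  n <- length(d)
  d_bar <- mean(d)
  d_arm <- tapply(d, g, mean)
  ss_time <- n * d_bar^2 / 2
  ss_int <- sum(as.numeric(n_g) * (d_arm - d_bar)^2) / 2
  ss_err <- sum((d - d_arm[g])^2) / 2
  df_err <- n - 2L
  ms_err <- ss_err / df_err
  f_time <- if (ms_err == 0) ifelse(ss_time == 0, 0, Inf) else
    ss_time / ms_err
  f_int <- if (ms_err == 0) ifelse(ss_int == 0, 0, Inf) else
    ss_int / ms_err
  # raw-scale per-arm descriptives and change CIs
  d_raw <- post - base
  alpha <- 1 - conf_level
  per_arm <- do.call(rbind, lapply(levels(g), function(arm) {
    idx <- g == arm
    di <- d_raw[idx]
    se <- stats::sd(di) / sqrt(length(di))
    tq <- stats::qt(1 - alpha / 2, length(di) - 1)
    data.frame(condition = arm, n = length(di),
               baseline_mean = mean(base[idx]),
               baseline_sd = stats::sd(base[idx]),
               post_mean = mean(post[idx]),
               post_sd = stats::sd(post[idx]),
               change = mean(di),
               ci_lower = mean(di) - tq * se,
               ci_upper = mean(di) + tq * se)
  }))
  structure(
    list(outcome = outcome, log_transformed = log_transform,
         F_time = f_time, F_interaction = f_int,
         df = c(effect = 1L, error = df_err),
         p_time = stats::pf(f_time, 1, df_err, lower.tail = FALSE),
         p_interaction = stats::pf(f_int, 1, df_err, lower.tail = FALSE),
         ss = c(time = ss_time, interaction = ss_int, error = ss_err),
         per_arm = per_arm),
    class = "anova_result"
  )
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf(
    "Mixed ANOVA on %s%s: F_time(1,%d) = %.2f (p = %.3g), F_time:cond = %.2f (p = %.3g)\n",
    x$outcome, if (x$log_transformed) " (log scale)" else "",
    x$df["error"], x$F_time, x$p_time, x$F_interaction, x$p_interaction))
  print(x$per_arm, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Percentage from a count and a denominator
#'
#' @param numerator Count, `0 <= numerator <= denominator`.
#' @param denominator Positive count.
#' @return `100 * numerator / denominator` (unrounded; round when
#'   reporting).
#' @examples
#' proportion(107, 1737)
#' @export
proportion <- function(numerator, denominator) {
  if (denominator <= 0) stop("denominator must be positive", call. = FALSE)
  if (numerator < 0 || numerator > denominator) {
    stop("numerator must lie between 0 and the denominator",
         call. = FALSE)
  }
  100 * numerator / denominator
}
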