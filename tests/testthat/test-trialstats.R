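test_that("Welch t from summaries matches t.test on raw data", {
  set.seed(31)
  for (i in 1:20) {
    x <- rnorm(sample(5:40, 1), 10, runif(1, 1, 5))
    y <- rnorm(sample(5:40, 1), 11, runif(1, 1, 5))
    mine <- welch_t(group_summary(length(x), mean(x), sd(x)),
                    group_summary(length(y), mean(y), sd(y)))
    ref <- t.test(x, y)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
    pooled <- welch_t(group_summary(length(x), mean(x), sd(x)),
                      group_summary(length(y), mean(y), sd(y)),
                      pooled = TRUE)
    ref_p <- t.test(x, y, var.equal = TRUE)
    expect_equal(pooled$statistic, unname(ref_p$statistic),
                 tolerance = 1e-10)
    expect_equal(pooled$df, unname(ref_p$parameter))
  }
})

test_that("Welch t handles symmetry, group swap, and degenerate input", {
  a <- group_summary(20, 10, 2)
  expect_equal(welch_t(a, a)$statistic, 0)
  b <- group_summary(31, 12, 3)
  ab <- welch_t(a, b)
  ba <- welch_t(b, a)
  expect_equal(ab$statistic, -ba$statistic)
  expect_equal(abs(ab$statistic), abs(ba$statistic))
  expect_equal(ab$df, ba$df)
  zero <- welch_t(group_summary(5, 3, 0), group_summary(5, 3, 0))
  expect_equal(zero$statistic, 0)
  expect_equal(zero$df, 8)
  expect_error(welch_t(group_summary(2, 1, 1), list(n = 1, mean = 0,
                                                    sd = 1)), "n >= 2")
})

test_that("chi-square is uncorrected Pearson with margin-based E", {
  equal <- matrix(c(10, 20, 10, 20), 2)
  expect_equal(chi_square(equal)$statistic, 0)
  # permutation invariance
  m <- matrix(c(23, 11, 9, 19, 8, 15), 2, byrow = TRUE)
  base <- chi_square(m)
  expect_equal(chi_square(m[, c(2, 1, 3)])$statistic, base$statistic)
  expect_equal(chi_square(m[c(2, 1), ])$statistic, base$statistic)
  expect_equal(base$df, 2)
  # 2x2 equals the squared two-proportion z statistic
  t22 <- matrix(c(17, 28, 21, 26), 2, byrow = TRUE)
  p1 <- 17 / 45; p2 <- 21 / 47; pp <- 38 / 92
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / 45 + 1 / 47))
  expect_equal(chi_square(t22)$statistic, z^2, tolerance = 1e-10)
  expect_error(chi_square(matrix(c(0, 0, 1, 2), 2)), "margin")
  expect_error(chi_square(matrix(1:3, 1)), "2 x 2")
})

test_that("log transform is invertible and guards its domain", {
  expect_equal(log_transform_outcome(0), 0)
  v <- c(0, 3.5, 120, NA)
  expect_equal(exp(log_transform_outcome(v)) - 1, v)
  expect_error(log_transform_outcome(-1), "non-negative")
})

test_that("p-values fall as |statistic| grows at fixed df", {
  t_ps <- vapply(seq(0, 5, by = 0.5), function(t) {
    2 * pt(-abs(t), 15)
  }, numeric(1))
  expect_true(all(diff(t_ps) < 0))
  mk <- function(shift) welch_t(group_summary(20, 10 + shift, 2),
                                group_summary(20, 10, 2))$p
  expect_true(all(diff(vapply(c(0, 0.5, 1, 2), mk, numeric(1))) < 0))
})

test_that("mixed ANOVA matches the independent SS oracle and aov", {
  set.seed(41)
  for (i in 1:10) {
    ds <- make_random_dataset(sample(5:25, 1), sample(5:25, 1),
                              effect = runif(1, -2000, 2000))
    fit <- mixed_anova(ds, "steps")
    oracle <- anova_oracle(ds, "steps")
    expect_equal(fit$F_time, oracle$F_time, tolerance = 1e-8)
    expect_equal(fit$F_interaction, oracle$F_interaction,
                 tolerance = 1e-8)
    expect_equal(unname(fit$df["error"]), oracle$df_err)
    expect_true(all(fit$ss >= 0))
  }
  # cross-check against stats::aov on one unbalanced dataset
  ds <- make_random_dataset(9, 13, effect = 1000, seed = 43)
  fit <- mixed_anova(ds, "steps")
  records <- ds$records
  long <- data.frame(
    y = c(records$steps_base, records$steps_post),
    time = factor(rep(c("base", "post"), each = nrow(records))),
    cond = factor(rep(records$condition, 2)),
    id = factor(rep(records$id, 2)))
  ref <- summary(aov(y ~ cond * time + Error(id), data = long))
  within <- ref[["Error: Within"]][[1]]
  expect_equal(fit$F_time, within["time", "F value"], tolerance = 1e-8)
  expect_equal(fit$F_interaction, within["cond:time", "F value"],
               tolerance = 1e-8)
})

test_that("mixed ANOVA degenerate designs behave as forced", {
  ds <- make_random_dataset(8, 8, seed = 47)
  rec <- ds$records
  # both arms change identically -> zero interaction
  rec$steps_post <- rec$steps_base + 500
  fit <- mixed_anova(trial_dataset(rec), "steps")
  expect_equal(fit$F_interaction, 0)
  expect_gt(fit$F_time, 0)
  # nobody changes -> zero time effect
  rec$steps_post <- rec$steps_base
  fit2 <- mixed_anova(trial_dataset(rec), "steps")
  expect_equal(fit2$F_time, 0)
  expect_equal(fit2$F_interaction, 0)
  # per-arm change CI brackets the estimate
  fit3 <- mixed_anova(make_random_dataset(10, 12, seed = 53), "steps")
  expect_true(all(fit3$per_arm$ci_lower <= fit3$per_arm$change))
  expect_true(all(fit3$per_arm$change <= fit3$per_arm$ci_upper))
  # balanced case: interaction F equals the squared pooled change-score t
  bal <- make_random_dataset(12, 12, effect = 800, seed = 59)
  d <- bal$records$steps_post - bal$records$steps_base
  tt <- t.test(d ~ bal$records$condition, var.equal = TRUE)
  expect_equal(mixed_anova(bal, "steps")$F_interaction,
               unname(tt$statistic)^2, tolerance = 1e-8)
})

test_that("intent-to-treat carries baseline forward and is idempotent", {
  ds <- make_random_dataset(6, 6, seed = 61)
  rec <- ds$records
  rec$steps_post[1] <- NA
  rec$bmi_post[1] <- NA
  rec$walking_post[c(1, 3)] <- NA
  rec$totalpa_post[3] <- NA
  rec$sitting_post[3] <- NA
  rec$dropout[c(1, 3)] <- TRUE
  ds <- trial_dataset(rec)
  itt <- intent_to_treat(ds)
  expect_equal(itt$records$steps_post[1], rec$steps_base[1])
  expect_equal(itt$records$walking_post[3], rec$walking_base[3])
  expect_equal(itt$records$steps_post[-1], rec$steps_post[-1])
  expect_false(anyNA(itt$records[paste0(names(itt$outcomes), "_post")]))
  expect_identical(intent_to_treat(itt)$records, itt$records)
  # imputed participants contribute zero change downstream
  fit <- mixed_anova(itt, "walking")
  expect_equal(sum(fit$per_arm$n), 12)
  rec$steps_base[1] <- NA
  expect_error(intent_to_treat(trial_dataset(rec)), rec$id[1])
})

test_that("proportions reproduce printed percentages", {
  expect_equal(round(proportion(107, 1737), 1), 6.2)
  expect_equal(round(proportion(30, 43)), 70)
  expect_equal(proportion(0, 50), 0)
  expect_error(proportion(1, 0), "positive")
  expect_error(proportion(5, 4), "between")
})

test_that("comparison tables assign the right test per outcome type", {
  ds <- generate_cohort(cohort_spec(n_per_arm = 25, rng_seed = 67))
  tab <- build_comparison_table(ds, qualitative = "dropout")
  expect_equal(nrow(tab), 6)
  expect_true(all(tab$test[tab$type == "quantitative"] == "Welch t"))
  expect_equal(tab$test[tab$outcome == "dropout"], "Pearson chi-square")
  expect_true(all(tab$p >= 0 & tab$p <= 1))
  expect_error(build_comparison_table(ds, outcomes = "vo2max"),
               "unknown")
  eff <- build_effects_table(ds)
  expect_equal(nrow(eff), 10)  # five outcomes x two arms
  md <- format_table(tab, "markdown")
  expect_match(md, "^\\| outcome")
  tsv <- format_table(tab, "tsv")
  expect_equal(length(strsplit(tsv, "\n")[[1]]), 7)
})
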