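default_baseline_marginals <- function() {
  # per-arm baseline mean/SD for each outcome (intervention trial of this
  # design: mostly inactive middle-aged adults recruited via primary care)
  list(
    bmi     = list(tailored = c(mean = 25.8, sd = 4.3),
                   standard = c(mean = 26.3, sd = 4.6)),
    walking = list(tailored = c(mean = 33.2, sd = 60.3),
                   standard = c(mean = 44.9, sd = 57.4)),
    totalpa = list(tailored = c(mean = 142.7, sd = 123.8),
                   standard = c(mean = 163.6, sd = 120.8)),
    steps   = list(tailored = c(mean = 8609, sd = 3370),
                   standard = c(mean = 8933, sd = 3367)),
    sitting = list(tailored = c(mean = 7.0, sd = 3.1),
                   standard = c(mean = 7.0, sd = 3.4))
  )
}

outcome_bounds <- function(outcome, cap = 20000) {
  if (outcome == "steps") c(0, cap) else c(0, Inf)
}

#' Specification of a synthetic two-arm cohort
#'
#' Describes the generative model: per-arm baseline marginals (normal,
#' truncated at 0 and, for steps, at the 20,000/day cap), a shared
#' secular time effect, an additive per-arm postintervention effect on
#' steps/day, a baseline-post correlation, a dropout process, and a seed.
#' Defaults describe a cohort of 46 per arm whose baseline step level
#' averages about 8600-8900 steps/day (SD about 3400), a secular step
#' increase of 2639 steps/day, no differential condition effect, and a
#' dropout probability of 0.25.
#'
#' @param n_per_arm Participants per arm (>= 2).
#' @param baseline Per-outcome, per-arm list of `c(mean, sd)` baseline
#'   marginals; see `steptailor:::default_baseline_marginals()`.
#' @param condition_effect Named additive postintervention effect on
#'   steps/day, one value per arm.
#' @param secular_change Named per-outcome shared time effect added to
#'   every participant's postintervention value.
#' @param correlation Baseline-postintervention correlation (0-1).
#' @param dropout_rate Probability a participant drops out (all
#'   postintervention values missing).
#' @param cap Daily step cap used as the upper truncation bound.
#' @param rng_seed Integer seed; `NULL` continues the current RNG stream.
#' @return A `cohort_spec`.
#' @export
cohort_spec <- function(n_per_arm = 46,
                        baseline = default_baseline_marginals(),
                        condition_effect = c(tailored = 0, standard = 0),
                        secular_change = c(bmi = 0, walking = 0,
                                           totalpa = 0, steps = 2639,
                                           sitting = 0),
                        correlation = 0.7,
                        dropout_rate = 23 / 92,
                        cap = 20000,
                        rng_seed = NULL) {
  stopifnot(is.numeric(n_per_arm), n_per_arm >= 2,
            is.numeric(correlation), correlation >= 0, correlation <= 1,
            is.numeric(dropout_rate), dropout_rate >= 0,
            dropout_rate <= 1, cap > 0)
  if (!setequal(names(condition_effect), TRIAL_ARMS)) {
    stop("condition_effect needs one value per arm: ",
         paste(TRIAL_ARMS, collapse = ", "), call. = FALSE)
  }
  if (!all(names(TRIAL_OUTCOMES) %in% names(baseline))) {
    stop("baseline marginals must cover all outcomes", call. = FALSE)
  }
  for (outcome in names(baseline)) {
    for (arm in TRIAL_ARMS) {
      m <- baseline[[outcome]][[arm]]
      if (length(m) != 2L || anyNA(m) || m["sd"] < 0) {
        stop("invalid baseline marginal for ", outcome, "/", arm,
             call. = FALSE)
      }
    }
  }
  if (!all(names(TRIAL_OUTCOMES) %in% names(secular_change))) {
    stop("secular_change must name every outcome", call. = FALSE)
  }
  structure(
    list(n_per_arm = as.integer(n_per_arm), baseline = baseline,
         condition_effect = condition_effect,
         secular_change = secular_change, correlation = correlation,
         dropout_rate = dropout_rate, cap = cap, rng_seed = rng_seed),
    class = "cohort_spec"
  )
}

#' Read a cohort spec from YAML or JSON
#'
#' @param path File whose flat mapping supplies [cohort_spec()]
#'   arguments; `baseline` entries may override individual outcomes.
#' @return A `cohort_spec`.
#' @export
read_cohort_spec <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(raw)) stop("cohort spec must be a mapping: ", path,
                          call. = FALSE)
  if (!is.null(raw$baseline)) {
    base <- default_baseline_marginals()
    for (outcome in names(raw$baseline)) {
      for (arm in names(raw$baseline[[outcome]])) {
        base[[outcome]][[arm]] <- unlist(raw$baseline[[outcome]][[arm]])
      }
    }
    raw$baseline <- base
  }
  for (nm in c("condition_effect", "secular_change")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  do.call(cohort_spec, raw)
}

rnorm_trunc <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(pmin(pmax(mean, lower), upper), n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Generate a synthetic two-arm trial cohort
#'
#' Baseline values are drawn per arm from the spec's truncated-normal
#' marginals. Postintervention values follow
#' `mu + rho * (base - mu) + secular + effect + e` with
#' `e ~ N(0, sd * sqrt(1 - rho^2))`, so the postintervention SD matches
#' the baseline SD and the baseline-post correlation equals `rho`; values
#' are then clipped to the outcome's bounds. Dropouts (Bernoulli per
#' participant) lose all postintervention values. A fixed `rng_seed`
#' makes the dataset fully reproducible.
#'
#' @param spec A [cohort_spec()].
#' @return A [trial_dataset()].
#' @examples
#' ds <- generate_cohort(cohort_spec(n_per_arm = 10, rng_seed = 1))
#' ds
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(spec$rng_seed)) set.seed(spec$rng_seed)
  n <- spec$n_per_arm
  arms <- rep(TRIAL_ARMS, each = n)
  records <- data.frame(
    id = sprintf("P%03d", seq_len(2L * n)),
    condition = arms,
    dropout = stats::runif(2L * n) < spec$dropout_rate
  )
  rho <- spec$correlation
  for (outcome in names(TRIAL_OUTCOMES)) {
    bounds <- outcome_bounds(outcome, spec$cap)
    base <- post <- numeric(2L * n)
    for (arm in TRIAL_ARMS) {
      idx <- which(arms == arm)
      m <- spec$baseline[[outcome]][[arm]]
      b <- rnorm_trunc(length(idx), m["mean"], m["sd"],
                       bounds[1], bounds[2])
      shift <- spec$secular_change[[outcome]] +
        if (outcome == "steps") spec$condition_effect[[arm]] else 0
      e <- stats::rnorm(length(idx), 0, m["sd"] * sqrt(1 - rho^2))
      p <- m["mean"] + rho * (b - m["mean"]) + shift + e
      base[idx] <- b
      post[idx] <- pmin(pmax(p, bounds[1]), bounds[2])
    }
    records[[paste0(outcome, "_base")]] <- round(base, 2)
    records[[paste0(outcome, "_post")]] <- round(post, 2)
  }
  post_cols <- paste0(names(TRIAL_OUTCOMES), "_post")
  records[records$dropout, post_cols] <- NA_real_
  trial_dataset(records)
}

#' Generate a synthetic daily step log
#'
#' Daily steps are drawn from a normal distribution truncated at zero;
#' each day independently carries a biking entry (with uniform random
#' minutes) with probability `biking_prob`, and half as often a swimming
#' entry.
#'
#' @param mean_level Mean daily steps.
#' @param day_sd Day-to-day SD of steps (default 2500, typical
#'   within-person variability for adults).
#' @param n_days Number of log days (the protocol uses 7).
#' @param biking_prob Per-day probability of a biking entry.
#' @param start_date First log date.
#' @param participant_id Label.
#' @param rng_seed Integer seed; `NULL` continues the RNG stream.
#' @return A [step_log()].
#' @export
generate_step_log <- function(mean_level, day_sd = 2500, n_days = 7,
                              biking_prob = 0.15,
                              start_date = as.Date("2010-03-01"),
                              participant_id = "synthetic",
                              rng_seed = NULL) {
  stopifnot(n_days >= 1, day_sd >= 0, mean_level >= 0,
            biking_prob >= 0, biking_prob <= 1)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  dates <- as.Date(start_date) + seq_len(n_days) - 1L
  steps <- round(rnorm_trunc(n_days, mean_level, day_sd, 0, Inf))
  bike <- stats::runif(n_days) < biking_prob
  swim <- stats::runif(n_days) < biking_prob / 2
  acts <- rbind(
    if (any(bike)) data.frame(date = dates[bike], activity = "biking",
                              minutes = round(stats::runif(sum(bike), 10,
                                                           45))),
    if (any(swim)) data.frame(date = dates[swim], activity = "swimming",
                              minutes = round(stats::runif(sum(swim), 15,
                                                           40)))
  )
  step_log(participant_id, data.frame(date = dates, steps = steps), acts)
}

#' Rejection rate of the time-by-condition test over replicates
#'
#' Repeatedly generates cohorts from `spec` and runs [mixed_anova()] on
#' the chosen outcome, returning the proportion of replicates whose
#' interaction p-value falls below `alpha`. With a zero condition effect
#' this estimates the test's type-I error rate.
#'
#' @param n_reps Number of replicate cohorts.
#' @param spec A [cohort_spec()] (its own `rng_seed` is ignored; the
#'   stream is governed by `seed`).
#' @param outcome Outcome analysed.
#' @param alpha Significance level.
#' @param seed Seed for the whole simulation.
#' @return List with `rate`, `n_reps`, `alpha`.
#' @export
simulate_interaction_rejection <- function(n_reps = 1000,
                                           spec = cohort_spec(
                                             dropout_rate = 0),
                                           outcome = "steps",
                                           alpha = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  spec$rng_seed <- NULL
  reject <- vapply(seq_len(n_reps), function(i) {
    ds <- generate_cohort(spec)
    mixed_anova(ds, outcome)$p_interaction < alpha
  }, logical(1))
  list(rate = mean(reject), n_reps = n_reps, alpha = alpha)
}

#' Recovery of an injected condition effect on steps
#'
#' Injects an additive postintervention step effect into the intervention
#' arm, generates replicate cohorts, and measures the between-arm
#' difference in mean step change estimated by [mixed_anova()].
#'
#' @param effect Injected steps/day effect (tailored arm).
#' @param n_reps Number of replicate cohorts.
#' @param spec Base [cohort_spec()]; its condition effect is overwritten.
#' @param seed Seed for the whole simulation.
#' @return List with `injected`, `estimate` (mean recovered difference),
#'   `se` (simulation standard error), `n_reps`.
#' @export
simulate_effect_recovery <- function(effect = 1500, n_reps = 200,
                                     spec = cohort_spec(dropout_rate = 0),
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  spec$rng_seed <- NULL
  spec$condition_effect <- c(tailored = effect, standard = 0)
  diffs <- vapply(seq_len(n_reps), function(i) {
    fit <- mixed_anova(generate_cohort(spec), "steps")
    pa <- fit$per_arm
    pa$change[pa$condition == "tailored"] -
      pa$change[pa$condition == "standard"]
  }, numeric(1))
  list(injected = effect, estimate = mean(diffs),
       se = stats::sd(diffs) / sqrt(n_reps), n_reps = n_reps)
}
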