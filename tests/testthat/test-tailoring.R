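test_that("stage classification follows the rule table and is total", {
  goal <- 10000
  below <- step_summary(8000)
  above <- step_summary(11500)
  expect_equal(classify_stage(make_resp(intention = "none"), below),
               "precontemplation")
  expect_equal(classify_stage(make_resp(intention = "within_6_months"),
                              below), "contemplation")
  expect_equal(classify_stage(make_resp(intention = "within_1_month"),
                              below), "preparation")
  expect_equal(classify_stage(make_resp(maintenance = 2), above),
               "action")
  expect_equal(classify_stage(make_resp(maintenance = 8), above),
               "maintenance")
  # totality and determinism across the full rule cross-product
  for (intention in c("within_1_month", "within_6_months", "none")) {
    for (mean_steps in c(0, 5000, 9999, 10000, 15000)) {
      for (months in c(0, 3, 6, 24)) {
        resp <- make_resp(intention = intention, maintenance = months)
        s <- step_summary(mean_steps)
        stage1 <- classify_stage(resp, s, goal)
        expect_true(stage1 %in% STAGES)
        expect_identical(stage1, classify_stage(resp, s, goal))
        if (mean_steps >= goal) {
          expect_equal(stage1,
                       if (months >= 6) "maintenance" else "action")
        }
      }
    }
  }
  expect_error(classify_stage(make_resp(intention = NA), below),
               "intention")
  # intention is irrelevant (and may be missing) once the goal is met
  expect_equal(classify_stage(make_resp(intention = NA, maintenance = 8),
                              above), "maintenance")
})

test_that("each stage maps to its fixed address mode", {
  expect_equal(address_mode("precontemplation"), "impersonal")
  expect_equal(address_mode("contemplation"), "personal")
  expect_equal(address_mode("preparation"), "decisive")
  expect_equal(address_mode("action"), "supportive")
  expect_equal(address_mode("maintenance"), "supportive")
  expect_error(address_mode("relapse"))
})

test_that("normative feedback picks the right variant and gap", {
  lib <- read_message_library()
  below <- normative_feedback(step_summary(9237), library = lib)
  expect_equal(below$variant, "below_goal")
  expect_equal(below$gap, 763)
  expect_match(below$messages[[1]]$text, "763")

  at <- normative_feedback(step_summary(10000), library = lib)
  expect_equal(at$variant, "at_goal")
  expect_equal(at$gap, 0)

  post <- normative_feedback(step_summary(11876), library = lib)
  expect_equal(post$variant, "at_goal")
})

test_that("goal schedules step up weekly and cap at the goal", {
  s <- build_schedule(8609, 500)
  expect_equal(s$weekly_targets, c(9109, 9609, 10000))
  expect_equal(s$weeks_to_goal, 3)

  expect_equal(build_schedule(10730, 1000)$weeks_to_goal, 0)
  expect_length(build_schedule(10730, 1000)$weekly_targets, 0)

  expect_equal(build_schedule(9500, 1000)$weekly_targets, 10000)
  expect_error(build_schedule(9000, 0), "positive")
  expect_error(build_schedule(9000, -500), "positive")
})

test_that("schedules match a brute-force loop oracle", {
  loop_oracle <- function(baseline, increment, goal) {
    targets <- numeric(0)
    level <- baseline
    while (level < goal) {
      level <- min(level + increment, goal)
      targets <- c(targets, level)
    }
    targets
  }
  set.seed(101)
  for (i in 1:500) {
    baseline <- runif(1, 0, 13000)
    increment <- sample(c(250, 500, 1000, 1500), 1)
    s <- build_schedule(baseline, increment)
    expect_equal(s$weekly_targets, loop_oracle(baseline, increment, 10000))
    expect_equal(s$weeks_to_goal,
                 if (baseline >= 10000) 0 else
                   ceiling((10000 - baseline) / increment))
    if (s$weeks_to_goal > 0) {
      expect_true(all(diff(s$weekly_targets) >= 0))
      expect_equal(s$weekly_targets[s$weeks_to_goal], 10000)
    }
  }
})

test_that("progress categories partition all level pairs", {
  expect_equal(progress_feedback(8609, 10668)$category, "positive")
  expect_equal(progress_feedback(9000, 9000)$category, "stable")
  expect_equal(progress_feedback(10000, 8000)$category, "negative")
  # band boundary: exactly stable_band away is still stable
  expect_equal(progress_feedback(9000, 9500)$category, "stable")
  expect_equal(progress_feedback(9000, 9501)$category, "positive")
  set.seed(7)
  for (i in 1:200) {
    prev <- runif(1, 0, 20000)
    cur <- runif(1, 0, 20000)
    cat1 <- progress_feedback(prev, cur)$category
    expect_true(cat1 %in% c("positive", "negative", "stable"))
  }
})

test_that("tips are stage- and profile-filtered per domain", {
  lib <- read_message_library()
  prep <- select_tips("preparation", make_resp(barriers = 5), lib)
  expect_true("coping" %in% names(prep))
  expect_match(prep$coping[[1]]$id, "barrier")
  # low barriers: no coping group
  prep2 <- select_tips("preparation", make_resp(barriers = 2), lib)
  expect_false("coping" %in% names(prep2))

  maint <- select_tips("maintenance",
                       make_resp(baseline = 12000, maintenance = 12), lib)
  ids <- vapply(unlist(maint, recursive = FALSE), `[[`, character(1),
                "id")
  expect_true(all(grepl("relapse", ids)))

  pre <- select_tips("precontemplation", make_resp(intention = "none"),
                     lib)
  texts <- vapply(unlist(pre[TIP_DOMAINS[TIP_DOMAINS %in% names(pre)]],
                         recursive = FALSE),
                  `[[`, character(1), "text")
  expect_true(all(grepl("people", tolower(texts))))  # impersonal voice
})

test_that("advice documents keep the fixed section order and rules", {
  order_expected <- c("introduction", "normative_feedback",
                      "progress_feedback", "schedule", "tips",
                      "info_blocks")
  doc <- compose_advice(make_resp())
  expect_equal(names(doc$sections), order_expected)
  expect_length(doc$sections$progress_feedback, 0)  # first request
  expect_gt(length(doc$sections$schedule), 0)       # below goal

  doc2 <- compose_advice(make_resp(request = 2, previous = 7200))
  expect_gt(length(doc2$sections$progress_feedback), 0)
  expect_equal(doc2$evolution, "positive")

  maint <- compose_advice(make_resp(baseline = 12000, maintenance = 12))
  expect_length(maint$sections$schedule, 0)
  expect_null(maint$schedule)

  action <- compose_advice(make_resp(baseline = 10500, maintenance = 1))
  expect_length(action$sections$schedule, 0)
})

test_that("every stage's introduction matches the golden text verbatim", {
  golden <- read_golden_intros()
  cases <- list(
    precontemplation = make_resp(intention = "none"),
    contemplation = make_resp(intention = "within_6_months"),
    preparation = make_resp(intention = "within_1_month"),
    action = make_resp(baseline = 11000, maintenance = 1),
    maintenance = make_resp(baseline = 11000, maintenance = 12))
  for (stage in names(cases)) {
    doc <- compose_advice(cases[[stage]])
    expect_equal(doc$stage, stage)
    expect_identical(doc$sections$introduction[[1]]$text,
                     unname(golden[stage]))
    expect_true(doc$sections$introduction[[1]]$canonical)
  }
})

test_that("every emitted message carries an auditable trace", {
  doc <- compose_advice(make_resp(barriers = 5, self_efficacy = 1,
                                  request = 2, previous = 9000))
  n_msgs <- sum(lengths(doc$sections))
  expect_equal(nrow(doc$trace), n_msgs)
  expect_true(all(nzchar(doc$trace$id)))
  lib <- read_message_library()
  lib_ids <- vapply(lib$entries, `[[`, character(1), "id")
  expect_true(all(doc$trace$id %in% lib_ids))
})

test_that("rendering is deterministic and placeholder-free", {
  doc <- compose_advice(make_resp(barriers = 5, request = 2,
                                  previous = 9000))
  for (fmt in c("text", "markdown", "html")) {
    r1 <- render_advice(doc, fmt)
    r2 <- render_advice(doc, fmt)
    expect_identical(r1, r2)
    expect_false(grepl("\\{[a-z0-9_]+\\}", r1))
  }
  html <- render_advice(doc, "html")
  expect_match(html, "<h2>")
  expect_error(render_advice(doc, "pdf"), "unknown")
  # empty sections leave no heading behind
  txt <- render_advice(compose_advice(make_resp()), "text")
  expect_false(grepl(SECTION_TITLES[["progress_feedback"]], txt,
                     fixed = TRUE))
})

test_that("unresolved placeholders and empty stages raise clear errors", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(paste(
    "- id: broken",
    "  section: introduction",
    "  stage: any",
    "  template: Hello {missing_name}!",
    sep = "\n"), path)
  lib <- read_message_library(path)
  expect_error(compose_advice(make_resp(), library = lib),
               "missing_name")
  # a library with introductions but no tips for the stage
  path2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines(paste(
    "- id: only_intro",
    "  section: introduction",
    "  stage: any",
    "  template: Hello.",
    sep = "\n"), path2)
  expect_error(compose_advice(make_resp(),
                              library = read_message_library(path2)),
               "tips")
})

test_that("questionnaire invariants are enforced", {
  expect_error(make_resp(request = 2), "previous_step_level")
  expect_error(make_resp(previous = 9000), "absent")
  expect_error(make_resp(intention = "someday"), "intention")
  expect_error(make_resp(barriers = 6), "ordinal")
  path <- write_temp_questionnaire(request_number = 2,
                                   previous_step_level = 8200)
  resp <- read_questionnaire(path)
  expect_s3_class(resp, "questionnaire_response")
  expect_equal(resp$request_number, 2L)
})
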