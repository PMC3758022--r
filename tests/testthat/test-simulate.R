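test_that("configuration invariants are enforced", {
  expect_error(cohort_config(mixture = c(nonuser = 0.5, low = 0.4,
                                         high = 0.2)), "sum to 1")
  expect_error(cohort_config(weeks = 0), "weeks")
  expect_error(cohort_config(n_users = 0), "n_users")
  expect_error(cohort_config(start_date = as.Date("2010-11-02")),
               "unlock day")
  expect_error(archetype_params("low", usefulness_probs = c(0.5, 0.2, 0.2)),
               "sum to 1")
  expect_error(archetype_params("nonuser", opens_per_session = 2),
               "nonuser")
})

test_that("the same seed reproduces the cohort byte for byte", {
  a <- sample_cohort(cohort_config(n_users = 15, seed = 99))
  b <- sample_cohort(cohort_config(n_users = 15, seed = 99))
  expect_identical(a$events, b$events)
  expect_identical(a$roster, b$roster)
  expect_identical(a$truth, b$truth)
  pa <- withr::local_tempfile(fileext = ".csv")
  pb <- withr::local_tempfile(fileext = ".csv")
  write_events(a$events, pa); write_events(b$events, pb)
  expect_identical(readLines(pa), readLines(pb))
  c_ <- sample_cohort(cohort_config(n_users = 15, seed = 100))
  expect_false(identical(a$events, c_$events))
})

test_that("growing the cohort never reshuffles existing users", {
  small <- sample_cohort(cohort_config(n_users = 10, seed = 7))
  big <- sample_cohort(cohort_config(n_users = 30, seed = 7))
  sub <- big$events[big$events$user_id %in% small$roster$user_id, ]
  rownames(sub) <- NULL
  expect_identical(sub, small$events)
  expect_identical(big$truth$archetype[1:10], small$truth$archetype)
})

test_that("an all-nonuser cohort opens nothing", {
  coh <- sample_cohort(cohort_config(
    n_users = 25, seed = 3,
    mixture = c(nonuser = 1, low = 0, high = 0)))
  expect_false(any(coh$events$event_type == "open_ingredient"))
  # the one-in-4.5 single-login nonusers produce a short login each
  expect_true(all(coh$events$event_type %in% c("login", "logout")))
})

test_that("the stepwise weekly lock is never violated", {
  coh <- small_cohort(25, seed = 19)
  catalog <- coh$config$catalog
  opens <- coh$events[coh$events$event_type == "open_ingredient", ]
  wk <- floor(as.numeric(difftime(
    opens$timestamp, as.POSIXct("2010-11-01 00:00", tz = "UTC"),
    units = "days")) / 7) + 1
  planned <- catalog$planned_week[match(opens$ingredient_id,
                                        catalog$ingredient_id)]
  expect_true(all(wk >= planned))
})

test_that("all events fall inside the observation window", {
  coh <- small_cohort(25, seed = 23)
  t0 <- as.POSIXct("2010-11-01 00:00", tz = "UTC")
  t1 <- t0 + 16 * 7 * 86400
  expect_true(all(coh$events$timestamp >= t0))
  expect_true(all(coh$events$timestamp < t1))
})

test_that("thermometers respect the one-per-day and 13-total caps", {
  coh <- small_cohort(40, seed = 29)
  th <- coh$events[coh$events$event_type == "distress_thermometer", ]
  per_day <- table(th$user_id, as.Date(th$timestamp, tz = "UTC"))
  expect_true(all(per_day <= 1))
  expect_true(all(table(factor(th$user_id)) <= 13))
})

test_that("generated streams re-sessionize to the drawn sessions", {
  # no intra-session idle stretch exceeds the timeout, so every session is
  # bounded by login...logout and counts as one login
  coh <- small_cohort(20, seed = 31)
  sess <- sessionize_cohort(coh$events)
  expect_true(all(sess$n_events >= 2 | sess$duration_min == 0))
  by_user <- split(sess, sess$user_id)
  for (s in by_user) {
    ev <- coh$events[coh$events$user_id == s$user_id[1], ]
    expect_equal(sum(ev$event_type == "login"), nrow(s))
    expect_equal(sum(ev$event_type == "logout"), nrow(s))
  }
})

test_that("covariates are drawn independently of archetype", {
  # roster-only mode: no event stream is generated
  coh <- sample_cohort(cohort_config(n_users = 40, seed = 37),
                       events = FALSE)
  expect_null(coh$events)
  expect_equal(nrow(coh$roster), 40)
  # identical to the roster of a full run under the same seed
  full <- sample_cohort(cohort_config(n_users = 40, seed = 37))
  expect_identical(coh$roster, full$roster)
  expect_identical(coh$truth, full$truth)
})

test_that("archetype separation yields the reported usage contrasts", {
  coh <- sample_cohort(cohort_config(seed = 41))
  res <- suppressWarnings(usage_evaluation(coh$events, coh$roster))
  tab <- res$profile_table
  lab <- stats::setNames(coh$truth$archetype, coh$truth$user_id)[tab$user_id]
  expect_gt(mean(tab$frequency[lab == "high"]),
            mean(tab$frequency[lab == "low"]))
  expect_gt(mean(tab$activity[lab == "high"]), 78)
  expect_lt(mean(tab$activity[lab == "low"]), 52)
  # low users leave their structure later than high users
  expect_gt(mean(tab$late_open_fraction[lab == "low"], na.rm = TRUE),
            mean(tab$late_open_fraction[lab == "high"], na.rm = TRUE))
})
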