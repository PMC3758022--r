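catalog <- default_catalog()
start <- as.Date("2010-11-01")  # Monday

profile_of <- function(ev, ...) {
  ev <- validate_events(ev, catalog)
  compute_profile(ev, sessionize(ev), catalog, start, ...)
}

test_that("activity counts distinct ingredients, re-opens ignored", {
  # same ingredient opened in three separate sessions
  ev <- make_events(c(0, 100, 2000), types = rep("open_ingredient", 3),
                    ingredients = rep("I01", 3))
  p <- profile_of(ev)
  expect_equal(p$activity, 1)
  expect_equal(p$n_sessions, 3)
  expect_equal(unname(p$per_kind_counts["information"]), 1)
  expect_equal(sum(p$per_kind_counts), p$activity)
  expect_equal(p$activity_fraction, 1 / 104)
})

test_that("an event-free user gets an all-zero profile", {
  p <- profile_of(make_events(numeric(0), types = character(0),
                              ingredients = character(0)))
  expect_equal(p$frequency, 0)
  expect_equal(p$activity, 0)
  expect_equal(p$total_duration, 0L)
  expect_true(all(is.na(p$usefulness)))
  expect_equal(length(p$weeks_active), 0)
  expect_equal(sum(p$weekday_login_counts), 0)
})

test_that("late opens are those in a later phase than planned", {
  # I01 is planned week 1 (phase 1); open it in week 9 (phase 3)
  stopifnot(catalog$planned_week[catalog$ingredient_id == "I01"] == 1)
  ev <- make_events(0, types = "open_ingredient", ingredients = "I01",
                    origin = as.POSIXct("2011-01-03 10:00", tz = "UTC"))
  # 2011-01-03 is 63 days after start: week 10, phase 3
  p <- profile_of(ev)
  expect_equal(p$late_open_fraction, 1)

  # same-phase open in a different week is on time
  ev2 <- make_events(0, types = "open_ingredient", ingredients = "I01",
                     origin = as.POSIXct("2010-11-15 10:00", tz = "UTC"))
  expect_equal(profile_of(ev2)$late_open_fraction, 0)
})

test_that("write without a logged open counts as an open, with a warning", {
  ev <- make_events(c(0, 5), types = c("login", "write_ingredient"),
                    ingredients = c(NA, "A01"))
  expect_warning(p <- profile_of(ev), "write_ingredient without")
  expect_equal(p$activity, 1)
})

test_that("usefulness proportions use opened prompts as denominator", {
  # 10 opened prompt-bearing ingredients: 6 useful, 2 not useful, 2 silent
  ids <- sprintf("A%02d", 1:10)
  opens <- make_events(0:9, types = rep("open_ingredient", 10),
                       ingredients = ids)
  resp <- make_events(10:17, types = rep("usefulness_response", 8),
                      ingredients = ids[1:8],
                      values = c(rep(1L, 6), rep(2L, 2)))
  p <- profile_of(rbind(opens, resp))
  expect_equal(unname(p$usefulness), c(0.6, 0.2, 0.2))
  expect_equal(sum(p$usefulness), 1)
  expect_equal(p$n_prompts_opened, 10)

  # all useful
  resp_all <- make_events(10:19, types = rep("usefulness_response", 10),
                          ingredients = ids, values = rep(1L, 10))
  expect_equal(unname(profile_of(rbind(opens, resp_all))$usefulness),
               c(1, 0, 0))

  # response for an ingredient never opened is a validation error
  bad <- make_events(c(0, 1),
                     types = c("open_ingredient", "usefulness_response"),
                     ingredients = c("A01", "A02"), values = c(NA, 1L))
  expect_error(profile_of(bad), "never opened")

  # a video open contributes to activity but not the usefulness denominator
  p <- profile_of(make_events(0, types = "open_ingredient",
                              ingredients = "V01"))
  expect_true(all(is.na(p$usefulness)))
  expect_equal(p$n_prompts_opened, 0)
})

test_that("weekday codes use the Sunday=1..Saturday=7 scale", {
  # 2011-03-07 is a Monday -> code 2
  ev <- make_events(c(0, 5), types = c("login", "logout"),
                    origin = as.POSIXct("2011-03-07 10:15", tz = "UTC"))
  ev <- validate_events(ev)
  counts <- weekday_login_counts(sessionize(ev))
  expect_equal(unname(counts["2"]), 1)
  expect_equal(sum(counts), 1)
  h <- weekday_histogram(sessionize(ev))
  expect_equal(h$modal_day, 2)
  expect_equal(h$modal_share, 1)
})

test_that("events outside the window follow the configured policy", {
  early <- make_events(0, types = "open_ingredient", ingredients = "I01",
                       origin = as.POSIXct("2010-10-01 10:00", tz = "UTC"))
  expect_error(profile_of(early), "outside")
  expect_equal(profile_of(early, out_of_window = "drop")$activity, 0)
  expect_equal(profile_of(early, out_of_window = "clamp")$activity, 1)
})

test_that("removing opens zeroes activity but leaves frequency unchanged", {
  set.seed(21)
  coh <- small_cohort(12)
  sess <- sessionize_cohort(coh$events)
  profs <- compute_profiles(coh$events, sess, catalog, coh$roster)
  no_opens <- coh$events[coh$events$event_type != "open_ingredient", ,
                         drop = FALSE]
  # usefulness responses reference opens, so strip them too
  no_opens <- no_opens[no_opens$event_type != "usefulness_response", ,
                       drop = FALSE]
  no_opens <- no_opens[no_opens$event_type != "write_ingredient", ,
                       drop = FALSE]
  # same sessions, opens stripped from the stream: activity collapses,
  # frequency (a session property) is untouched
  profs2 <- compute_profiles(no_opens, sess, catalog, coh$roster)
  for (u in coh$roster$user_id) {
    expect_equal(profs2[[u]]$activity, 0)
    expect_equal(profs2[[u]]$frequency, profs[[u]]$frequency)
  }
})

test_that("per-kind fractions sum to one and conserve activity", {
  coh <- small_cohort(10, seed = 33)
  sess <- sessionize_cohort(coh$events)
  profs <- compute_profiles(coh$events, sess, catalog, coh$roster)
  for (p in profs) {
    expect_equal(sum(p$per_kind_counts), p$activity)
    if (p$activity > 0)
      expect_equal(sum(p$per_kind_fractions), 1)
    expect_equal(p$activity_fraction, p$activity / 104)
    expect_equal(p$frequency, sum(p$weekday_login_counts))
  }
})

test_that("cohort usage table summarises per group", {
  coh <- small_cohort(10, seed = 2)
  sess <- sessionize_cohort(coh$events)
  profs <- compute_profiles(coh$events, sess, catalog, coh$roster)
  one <- cohort_usage_table(profs[1])
  expect_equal(one$mean[one$statistic == "frequency"],
               profs[[1]]$frequency)
  two <- cohort_usage_table(profs[c(1, 1)])
  expect_equal(two$sd[two$statistic == "frequency"], 0)
  glab <- stats::setNames(coh$truth$archetype, coh$truth$user_id)
  tab <- cohort_usage_table(profs, glab)
  expect_true(all(c("overall", unique(glab)) %in% tab$group))
})
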