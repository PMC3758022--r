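test_that("gap rule partitions events into sessions", {
  # one run: gaps 5 and 7 minutes
  s <- sessionize(validate_events(make_events(c(0, 5, 12))))
  expect_equal(nrow(s), 1)
  expect_equal(s$duration_min, 12L)
  expect_true(s$counts_as_login)

  # 35-minute gap splits; trailing singleton has zero duration, not a login
  s <- sessionize(validate_events(make_events(c(0, 10, 45))))
  expect_equal(nrow(s), 2)
  expect_equal(s$duration_min, c(10L, 0L))
  expect_equal(s$counts_as_login, c(TRUE, FALSE))

  # a gap of exactly the timeout stays inside the session
  s <- sessionize(validate_events(make_events(c(0, 30, 60))))
  expect_equal(nrow(s), 1)
  expect_equal(s$duration_min, 60L)
})

test_that("explicit login and logout events override the gap rule", {
  ev <- validate_events(make_events(
    c(0, 5, 6, 20), types = c("login", "open_ingredient", "login", "logout"),
    ingredients = c(NA, "I01", NA, NA)))
  s <- sessionize(ev)
  expect_equal(nrow(s), 2)  # second login starts a new session at minute 6
  expect_equal(s$duration_min, c(5L, 14L))

  ev <- validate_events(make_events(
    c(0, 5, 10), types = c("login", "logout", "open_ingredient"),
    ingredients = c(NA, NA, "I01")))
  s <- sessionize(ev)
  expect_equal(nrow(s), 2)  # logout closes immediately despite 5-min gap
})

test_that("contract violations are rejected", {
  ev <- rbind(make_events(0, user = "u1"), make_events(0, user = "u2"))
  expect_error(sessionize(ev), "single user")
  ev <- make_events(c(10, 0))
  expect_error(sessionize(ev), "sorted")
})

test_that("login frequency applies the one-minute rule", {
  ev <- validate_events(make_events(c(0, 12, 60, 100, 110)))
  s <- sessionize(ev)  # sessions [0,12], [60,60], [100,110]
  expect_equal(s$duration_min, c(12L, 0L, 10L))
  expect_equal(login_frequency(s), 2)
  expect_equal(total_duration(s), 22L)
  expect_equal(login_frequency(empty_sessions_df <- sessionize(
    validate_events(make_events(numeric(0))))), 0)
  expect_equal(total_duration(empty_sessions_df), 0L)
})

test_that("many short visits each count as one login", {
  # 45 separate two-minute visits, one hour apart
  minutes <- as.vector(outer(c(0, 2), (0:44) * 60, "+"))
  s <- sessionize(validate_events(make_events(sort(minutes))))
  expect_equal(nrow(s), 45)
  expect_equal(login_frequency(s), 45)
})

test_that("sessionize matches the brute-force oracle on random streams", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(1:40, 1)
    timeout <- sample(c(0, 5, 30, 120), 1)
    ev <- validate_events(random_events(n, span_min = 400))
    got <- sessionize(ev, timeout_min = timeout)
    sid <- oracle_sessionize(ev, timeout_min = timeout)
    ref <- session_summary_from_ids(ev, sid)
    expect_equal(nrow(got), nrow(ref))
    expect_equal(as.numeric(got$start), as.numeric(ref$start))
    expect_equal(as.numeric(got$end), as.numeric(ref$end))
    expect_equal(got$n_events, ref$n_events)
    # conservation: every event in exactly one session
    expect_equal(sum(got$n_events), n)
    expect_equal(total_duration(got),
                 sum(as.numeric(ref$end - ref$start, units = "mins")))
  }
})

test_that("appending an event never decreases frequency or total duration", {
  set.seed(9)
  for (i in 1:50) {
    ev <- validate_events(random_events(sample(2:30, 1), span_min = 300))
    s_full <- sessionize(ev)
    s_head <- sessionize(ev[-nrow(ev), , drop = FALSE])
    expect_gte(login_frequency(s_full), login_frequency(s_head))
    expect_gte(total_duration(s_full), total_duration(s_head))
  }
})

test_that("timeout extremes give one session, or one per distinct minute", {
  ev <- validate_events(random_events(25, span_min = 5000))
  expect_equal(nrow(sessionize(ev, timeout_min = 1e9)),
               1 + sum(ev$event_type[-nrow(ev)] == "logout" |
                         ev$event_type[-1] == "login"))
  s0 <- sessionize(ev, timeout_min = 0)
  # with no idle tolerance, every distinct minute is its own session
  # (plus login/logout forced breaks)
  expect_gte(nrow(s0), length(unique(ev$timestamp)))
  expect_true(all(s0$duration_min == 0))
})
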