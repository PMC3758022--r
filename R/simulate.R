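#' Synthetic engagement-log generator
#'
#' Generates event logs, rosters and ground-truth archetype labels with the
#' statistical structure of a 70-woman, 16-week self-management
#' intervention cohort, so the whole analysis pipeline can run and be
#' validated without access to trial data. Three engagement archetypes are
#' mixed: nonusers (13%; most emit no events at all, a minority log in once
#' without opening anything), low users (43%; about 3.6 logins
#' concentrated in the first two phases, ~23.5-minute sessions, ~19
#' ingredients opened) and high users (44%; about 21 logins spread over
#' the full period, ~33-minute sessions, ~90% of ingredients opened).
#' Session starts favour the weekly reminder day (Monday, 28% of logins);
#' content respects the stepwise weekly unlock; usefulness prompts,
#' self-help contract use, distress thermometers (at most one per day,
#' at most 13 in total) and support emails are emitted with
#' archetype-specific probabilities. Baseline covariates are drawn
#' independently of archetype.
#'
#' @name synthetic-cohort
NULL

#' Archetype parameters for the generator
#'
#' @param label one of "nonuser", "low", "high".
#' @param weekly_session_rate expected sessions in week 1 (Poisson rate).
#' @param rate_decay exponential decay per week of the session rate; week w
#'   has rate \code{weekly_session_rate * exp(-rate_decay * (w - 1))}.
#' @param session_duration_log_mean,session_duration_log_sd lognormal
#'   parameters of session duration in minutes (durations are rounded to
#'   whole minutes, floored at 1 and capped at 180).
#' @param opens_per_session expected number of distinct ingredient opens
#'   per session (Poisson); 0 for nonusers.
#' @param monday_login_share probability a session starts on the unlock
#'   (reminder) day; remaining mass is uniform over the other six days.
#' @param contract_open_prob,contract_sign_given_open_prob self-help
#'   contract probabilities, applied in the first session.
#' @param usefulness_probs length-3 probabilities (useful, not useful,
#'   blank) for the response emitted after opening a prompt-bearing
#'   ingredient; must sum to 1.
#' @param thermometer_mean Poisson mean of the number of distress
#'   thermometers, capped at 13 and at one per calendar day.
#' @param late_open_prob probability an open draws from the backlog of
#'   earlier-phase ingredients instead of the current phase.
#' @param skip_prob probability that a given ingredient is permanently
#'   skipped by the user (self-tailoring: generic content is used ad
#'   libitum and not every ingredient applies to every user).
#' @param avatar_prob probability the user sets an avatar.
#' @param support_email_prob probability the user sends one support email.
#' @param single_login_prob (nonuser archetype) probability of emitting a
#'   single 1-minute login with no opens instead of no events at all.
#' @return object of class \code{archetype_params}.
#' @export
archetype_params <- function(label,
                             weekly_session_rate = 0,
                             rate_decay = 0,
                             session_duration_log_mean = log(25),
                             session_duration_log_sd = 0.5,
                             opens_per_session = 0,
                             monday_login_share = 0.28,
                             contract_open_prob = 0,
                             contract_sign_given_open_prob = 0,
                             usefulness_probs = c(useful = 0.5,
                                                  not_useful = 0.2,
                                                  blank = 0.3),
                             thermometer_mean = 0,
                             late_open_prob = 0,
                             skip_prob = 0,
                             avatar_prob = 0,
                             support_email_prob = 0,
                             single_login_prob = 0) {
  stopifnot(label %in% c("nonuser", "low", "high"),
            weekly_session_rate >= 0, rate_decay >= 0,
            opens_per_session >= 0, length(usefulness_probs) == 3)
  if (abs(sum(usefulness_probs) - 1) > 1e-9)
    stop("usefulness_probs must sum to 1")
  if (label == "nonuser" && opens_per_session != 0)
    stop("nonuser archetype must have opens_per_session = 0")
  structure(as.list(environment()), class = "archetype_params")
}

#' Default archetype calibration
#'
#' Rates, decays and durations are set so that expected totals over 16
#' weeks reproduce the reference cohort means: high users average 21
#' logins (rate 1.518, decay 0.02/week) with 32.8-minute sessions and open
#' about 5 ingredients per session; low users average 3.6 logins (rate
#' 0.811, decay 0.25/week, concentrating ~88% of their activity in the
#' first two phases) with 23.5-minute sessions and about 5.2 opens per
#' session (~18.8 ingredients in total); nonusers emit nothing except that
#' 2 in 9 log in once for one minute. Contract, usefulness, thermometer,
#' avatar and Monday-share parameters follow the reference cohort's
#' reported engagement markers.
#'
#' @return named list of \code{archetype_params} for nonuser, low, high.
#' @export
default_archetypes <- function() {
  list(
    nonuser = archetype_params("nonuser", single_login_prob = 2 / 9),
    low = archetype_params(
      "low",
      weekly_session_rate = 0.811, rate_decay = 0.25,
      session_duration_log_mean = log(23.5) - 0.5^2 / 2,
      session_duration_log_sd = 0.5,
      opens_per_session = 5.2, monday_login_share = 0.28,
      contract_open_prob = 0.57, contract_sign_given_open_prob = 0.53,
      usefulness_probs = c(useful = 0.44, not_useful = 0.20, blank = 0.36),
      thermometer_mean = 1, late_open_prob = 0.50,
      avatar_prob = 0.14, support_email_prob = 0.10),
    high = archetype_params(
      "high",
      weekly_session_rate = 1.518, rate_decay = 0.02,
      session_duration_log_mean = log(32.8) - 0.5^2 / 2,
      session_duration_log_sd = 0.5,
      opens_per_session = 6.5, monday_login_share = 0.28,
      contract_open_prob = 1.00, contract_sign_given_open_prob = 0.84,
      usefulness_probs = c(useful = 0.66, not_useful = 0.18, blank = 0.16),
      thermometer_mean = 5, late_open_prob = 0.06, skip_prob = 0.05,
      avatar_prob = 0.25, support_email_prob = 0.10)
  )
}

#' Cohort-level generator configuration
#'
#' @param n_users cohort size, default 70.
#' @param mixture named fractions over (nonuser, low, high) summing to 1;
#'   default (0.13, 0.43, 0.44).
#' @param weeks intervention length in weeks, default 16.
#' @param start_date enrollment date, a Monday (all users enroll together);
#'   default 2010-11-01.
#' @param unlock_weekday weekly unlock/reminder day, default Monday.
#' @param seed master seed; per-user substreams are derived by stable
#'   hashing of the user id, so growing the cohort never reshuffles
#'   existing users.
#' @param archetypes named list of \code{\link{archetype_params}}.
#' @param catalog ingredient catalog, default \code{\link{default_catalog}}.
#' @return object of class \code{cohort_config}.
#' @export
cohort_config <- function(n_users = 70,
                          mixture = c(nonuser = 0.13, low = 0.43,
                                      high = 0.44),
                          weeks = 16,
                          start_date = as.Date("2010-11-01"),
                          unlock_weekday = "Monday",
                          seed = 1,
                          archetypes = default_archetypes(),
                          catalog = default_catalog()) {
  if (n_users < 1) stop("n_users must be >= 1")
  if (weeks < 1) stop("weeks must be >= 1")
  if (abs(sum(mixture) - 1) > 1e-9) stop("mixture must sum to 1")
  if (!setequal(names(mixture), c("nonuser", "low", "high")))
    stop("mixture must be named over nonuser, low, high")
  start_date <- as.Date(start_date)
  if (as.integer(format(start_date, "%u")) !=
      weekday_name_to_iso(unlock_weekday))
    stop("start_date must fall on the unlock day (", unlock_weekday, ")")
  structure(list(n_users = as.integer(n_users),
                 mixture = mixture[c("nonuser", "low", "high")],
                 weeks = as.integer(weeks), start_date = start_date,
                 unlock_weekday = unlock_weekday, seed = as.integer(seed),
                 archetypes = archetypes, catalog = catalog),
            class = "cohort_config")
}

user_substream_seed <- function(seed, user_id) {
  h <- 0
  for (ch in utf8ToInt(user_id)) h <- (h * 31 + ch) %% 2147483647
  as.integer((h + as.numeric(seed) * 2654435) %% 2147483647)
}

draw_covariates <- function() {
  # independent of archetype by construction
  list(age = round(stats::rnorm(1, 50.9, 8.31), 1),
       education = sample(1:7, 1,
                          prob = c(0.01, 0.03, 0.10, 0.20, 0.30, 0.22, 0.14)),
       married = stats::rbinom(1, 1, 0.83) == 1,
       children = stats::rbinom(1, 1, 0.87) == 1,
       employment = sample(c("paid", "disablement", "other"), 1,
                           prob = c(0.40, 0.37, 0.23)),
       adjuvant_treatment = sample(c("chemo", "radio", "both"), 1,
                                   prob = c(0.27, 0.04, 0.69)),
       hormonal_therapy = stats::rbinom(1, 1, 0.66) == 1,
       hads_t = max(0, round(stats::rnorm(1, 7, 5.8))))
}

minute_at <- function(day, minute_of_day) {
  as.POSIXct(paste(day, "00:00"), tz = "UTC") + minute_of_day * 60
}

simulate_user_events <- function(user_id, params, start_date, weeks,
                                 catalog) {
  if (params$label == "nonuser") {
    if (stats::runif(1) < params$single_login_prob) {
      day <- start_date + (if (stats::runif(1) <
                               params$monday_login_share) 0
                           else sample(1:6, 1))
      t0 <- minute_at(day, sample(480:1319, 1))
      return(data.frame(user_id = user_id, timestamp = c(t0, t0 + 60),
                        event_type = c("login", "logout"),
                        ingredient_id = NA_character_, value = NA_integer_,
                        stringsAsFactors = FALSE))
    }
    return(empty_events())
  }

  period_end <- as.POSIXct(paste(start_date + weeks * 7, "00:00"),
                           tz = "UTC")
  # draw candidate sessions week by week
  starts <- .POSIXct(numeric(), tz = "UTC"); durs <- integer()
  for (w in seq_len(weeks)) {
    rate <- params$weekly_session_rate * exp(-params$rate_decay * (w - 1))
    for (s in seq_len(stats::rpois(1, rate))) {
      day_off <- if (stats::runif(1) < params$monday_login_share) 0
      else sample(1:6, 1)
      day <- start_date + (w - 1) * 7 + day_off
      t0 <- minute_at(day, sample(480:1319, 1))
      dur <- min(180L, max(1L, as.integer(round(stats::rlnorm(
        1, params$session_duration_log_mean,
        params$session_duration_log_sd)))))
      max_dur <- as.integer(floor(as.numeric(period_end - t0,
                                             units = "mins"))) - 1L
      dur <- min(dur, max_dur)
      starts <- c(starts, t0); durs <- c(durs, dur)
    }
  }
  if (!length(starts)) return(empty_events())
  ord <- order(starts)
  starts <- .POSIXct(as.numeric(starts)[ord], tz = "UTC"); durs <- durs[ord]
  # drop sessions that would merge with the previous one (within timeout)
  keep <- logical(length(starts)); prev_end <- -Inf
  for (i in seq_along(starts)) {
    if (as.numeric(starts[i]) > prev_end + 30 * 60) {
      keep[i] <- TRUE
      prev_end <- as.numeric(starts[i]) + durs[i] * 60
    }
  }
  starts <- starts[keep]; durs <- durs[keep]

  # thermometer days (at most one per calendar day, at most 13 total) and
  # the support-email session are assigned up front
  n_therm <- min(13L, stats::rpois(1, params$thermometer_mean))
  days <- as.Date(starts, tz = "UTC")
  uniq_days <- unique(days)
  therm_sessions <- if (n_therm > 0) {
    chosen <- if (length(uniq_days) <= n_therm) uniq_days
    else uniq_days[sample.int(length(uniq_days), n_therm)]
    match(chosen, days)  # first session of each chosen day
  } else integer(0)
  support_session <- if (stats::runif(1) < params$support_email_prob)
    sample.int(length(starts), 1) else 0L

  opened <- rep(FALSE, nrow(catalog))
  excluded <- stats::runif(nrow(catalog)) < params$skip_prob
  out <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    t0 <- starts[i]; dur <- durs[i]; t_end <- t0 + dur * 60
    w <- week_of(t0, start_date)
    cur_phase <- phase_of_week(w)
    tm <- as.numeric(t0); ty <- "login"
    ig <- NA_character_; va <- NA_integer_
    emit <- function(t, type, ingr = NA_character_, val = NA_integer_) {
      tm <<- c(tm, as.numeric(t)); ty <<- c(ty, type)
      ig <<- c(ig, ingr); va <<- c(va, val)
    }
    if (i == 1L) {
      if (stats::runif(1) < params$contract_open_prob) {
        emit(min(t0 + 60, t_end), "contract_open")
        if (stats::runif(1) < params$contract_sign_given_open_prob)
          emit(min(t0 + 120, t_end), "contract_sign")
      }
      if (stats::runif(1) < params$avatar_prob)
        emit(min(t0 + 180, t_end), "avatar_set")
    }
    k <- stats::rpois(1, params$opens_per_session)
    for (j in seq_len(k)) {
      unlocked <- !opened & !excluded & catalog$planned_week <= w
      current <- which(unlocked & catalog$planned_phase == cur_phase)
      backlog <- which(unlocked & catalog$planned_phase < cur_phase)
      pool <- if (length(backlog) &&
                  (stats::runif(1) < params$late_open_prob ||
                   !length(current))) backlog
      else current
      if (!length(pool)) break
      # users work through content in unlock order (oldest first)
      pick <- pool[which.min(catalog$planned_week[pool])]
      opened[pick] <- TRUE
      t_open <- t0 + sample.int(dur + 1L, 1L) * 60 - 60
      emit(t_open, "open_ingredient", catalog$ingredient_id[pick])
      if (catalog$has_usefulness_prompt[pick])
        emit(min(t_open + 60, t_end), "usefulness_response",
             catalog$ingredient_id[pick],
             sample(c(1L, 2L, 0L), 1, prob = params$usefulness_probs))
    }
    if (i %in% therm_sessions)
      emit(t0 + (sample.int(dur + 1L, 1L) - 1L) * 60, "distress_thermometer")
    if (i == support_session)
      emit(t0 + (sample.int(dur + 1L, 1L) - 1L) * 60, "support_email")

    # browsing keeps the server busy: pad any idle stretch longer than the
    # 30-minute auto-logout with saves of an already-opened ingredient, so
    # the drawn session is exactly what the timeout rule reconstructs
    ord <- order(tm)
    tm <- tm[ord]; ty <- ty[ord]; ig <- ig[ord]; va <- va[ord]
    bounds <- c(tm, as.numeric(t_end))
    if (any(opened)) {
      ka_id <- catalog$ingredient_id[which(opened)[1]]
      for (b in seq_len(length(bounds) - 1L)) {
        gap <- bounds[b + 1L] - bounds[b]
        if (gap > 30 * 60) {
          fill <- seq(bounds[b] + 25 * 60, bounds[b + 1L] - 60, by = 25 * 60)
          tm <- c(tm, fill); ty <- c(ty, rep("write_ingredient", length(fill)))
          ig <- c(ig, rep(ka_id, length(fill)))
          va <- c(va, rep(NA_integer_, length(fill)))
        }
      }
      ord <- order(tm)
      tm <- tm[ord]; ty <- ty[ord]; ig <- ig[ord]; va <- va[ord]
    } else {
      # nothing to keep the connection alive with: the session ends when
      # the timeout fires after the last request
      cut <- which(diff(bounds) > 30 * 60)
      if (length(cut)) {
        t_end <- .POSIXct(bounds[cut[1]] + 30 * 60, tz = "UTC")
        keep_ev <- tm <= as.numeric(t_end)
        tm <- tm[keep_ev]; ty <- ty[keep_ev]; ig <- ig[keep_ev]
        va <- va[keep_ev]
      }
    }
    out[[i]] <- data.frame(
      user_id = user_id, timestamp = .POSIXct(c(tm, as.numeric(t_end)),
                                              tz = "UTC"),
      event_type = c(ty, "logout"),
      ingredient_id = c(ig, NA_character_), value = c(va, NA_integer_),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Sample a synthetic cohort
#'
#' Draws each user's archetype from the mixture, then their baseline
#' covariates (independently of archetype), then — unless
#' \code{events = FALSE} — their full event stream: weekly session counts
#' from a Poisson rate with exponential decay, session start days favouring
#' the reminder Monday, start times uniform over waking hours (08:00-22:00),
#' lognormal durations, per-session ingredient opens restricted to unlocked
#' content with a backlog ("late open") probability, usefulness responses,
#' contract/avatar events in the first session, distress thermometers
#' (max one per day, 13 total) and support emails. All randomness flows
#' through per-user substreams derived from the master seed, so the same
#' seed reproduces the cohort exactly and adding users never changes
#' existing ones. \code{events = FALSE} returns the roster and truth labels
#' only, for covariate-level simulation studies (e.g. type-I-error checks)
#' that never read the event stream.
#'
#' @param config a \code{\link{cohort_config}}.
#' @param events generate event streams (default TRUE).
#' @return list with \code{roster} (user_id, start_date, covariates),
#'   \code{events} (validated event log; NULL when \code{events = FALSE}),
#'   \code{truth} (user_id, archetype), and \code{config}.
#' @export
#' @examples
#' coh <- sample_cohort(cohort_config(n_users = 10, seed = 42))
#' table(coh$truth$archetype)
sample_cohort <- function(config, events = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))

  width <- max(3L, nchar(as.character(config$n_users)))
  user_ids <- sprintf(paste0("u%0", width, "d"), seq_len(config$n_users))
  cum <- cumsum(config$mixture)
  rows <- vector("list", config$n_users)
  ev_list <- vector("list", config$n_users)
  labels <- character(config$n_users)
  for (i in seq_len(config$n_users)) {
    set.seed(user_substream_seed(config$seed, user_ids[i]))
    labels[i] <- names(cum)[which(stats::runif(1) <= cum)[1]]
    cov <- draw_covariates()
    rows[[i]] <- data.frame(user_id = user_ids[i],
                            start_date = config$start_date,
                            as.data.frame(cov, stringsAsFactors = FALSE),
                            stringsAsFactors = FALSE)
    if (events)
      ev_list[[i]] <- simulate_user_events(
        user_ids[i], config$archetypes[[labels[i]]], config$start_date,
        config$weeks, config$catalog)
  }
  roster <- validate_roster(do.call(rbind, rows), config$unlock_weekday)
  ev <- if (events)
    validate_events(do.call(rbind, ev_list), config$catalog, roster)
  else NULL
  list(roster = roster, events = ev,
       truth = data.frame(user_id = user_ids, archetype = labels,
                          stringsAsFactors = FALSE),
       config = config)
}
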