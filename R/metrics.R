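#' Per-user usage statistics
#'
#' The amount of use is captured by three singular statistics: frequency
#' (number of logins over the 16 weeks), duration (per-session and total
#' minutes) and activity (number of distinct ingredients opened, maximum =
#' catalog size). How the intervention was used is captured by the
#' ingredient-kind distribution of opens, conformance to the planned phase
#' structure (late opens), the weekday profile of logins, self-help contract
#' use, avatar use, distress thermometers, support emails, and the
#' proportions of opened prompt-bearing ingredients rated useful, not
#' useful, or left blank.
#'
#' @name usage-metrics
NULL

week_of <- function(ts, start_date) {
  days <- as.numeric(difftime(ts, as.POSIXct(paste(start_date, "00:00"),
                                             tz = "UTC"), units = "days"))
  as.integer(floor(days / 7)) + 1L
}

#' Compute one user's usage profile
#'
#' Activity counts distinct ingredient ids among \code{open_ingredient}
#' events (the platform logged only first opens, so re-opens carry no
#' information); a \code{write_ingredient} with no open on record anywhere
#' in the log is counted as an open at the write's timestamp, with a
#' warning. An ingredient is opened "late" when the phase of its first open
#' (weeks are half-open intervals from \code{start_date}; phase =
#' ceiling(week/4)) is later than its planned phase; the stepwise lock makes
#' early opens impossible and same-phase-different-week opens are on time.
#' Mean session duration averages login-qualifying sessions only; phase and
#' week coverage likewise count login-qualifying sessions.
#'
#' @param events one user's validated events.
#' @param sessions that user's session table from \code{\link{sessionize}}.
#' @param catalog ingredient catalog.
#' @param start_date the user's enrollment Monday (week 1 begins here).
#' @param weeks observation window length in weeks, default 16.
#' @param out_of_window what to do with events before \code{start_date} or
#'   after the window: \code{"reject"} (default, error), \code{"drop"}, or
#'   \code{"clamp"} (assign to the nearest covered week).
#' @return object of class \code{user_usage_profile}: a list of all per-user
#'   statistics (see Details).
#' @export
compute_profile <- function(events, sessions, catalog, start_date,
                            weeks = 16,
                            out_of_window = c("reject", "drop", "clamp")) {
  out_of_window <- match.arg(out_of_window)
  start_date <- as.Date(start_date)
  user_id <- if (nrow(events)) events$user_id[1] else
    if (nrow(sessions)) sessions$user_id[1] else NA_character_

  if (nrow(events)) {
    wk <- week_of(events$timestamp, start_date)
    out <- wk < 1L | wk > weeks
    if (any(out)) {
      if (out_of_window == "reject")
        stop("event(s) outside the ", weeks, "-week window for user ",
             user_id, " (rows ", paste(which(out), collapse = ", "), ")")
      if (out_of_window == "drop") {
        events <- events[!out, , drop = FALSE]
      }
      # clamp: week index clamped below when used
    }
  }

  logins <- sessions[sessions$counts_as_login, , drop = FALSE]
  frequency <- nrow(logins)
  durations <- sessions$duration_min
  total_dur <- as.integer(sum(durations))
  mean_dur <- if (frequency) mean(logins$duration_min) else NA_real_

  # first-open table (write without open counts as an open, defensively)
  opens <- events[events$event_type == "open_ingredient", , drop = FALSE]
  writes <- events[events$event_type == "write_ingredient", , drop = FALSE]
  orphan <- setdiff(writes$ingredient_id, opens$ingredient_id)
  if (length(orphan)) {
    warning("user ", user_id, ": write_ingredient without a logged open for ",
            paste(orphan, collapse = ", "), "; counted as opens")
    opens <- rbind(opens, writes[writes$ingredient_id %in% orphan, ,
                                 drop = FALSE])
  }
  first_open <- if (nrow(opens)) {
    agg <- stats::aggregate(timestamp ~ ingredient_id, data = opens, FUN = min)
    agg[order(agg$ingredient_id), , drop = FALSE]
  } else data.frame(ingredient_id = character(),
                    timestamp = .POSIXct(numeric(), tz = "UTC"))

  activity <- nrow(first_open)
  catalog_size <- nrow(catalog)
  idx <- match(first_open$ingredient_id, catalog$ingredient_id)
  kinds <- catalog$kind[idx]
  per_kind <- vapply(INGREDIENT_KINDS, function(k) sum(kinds == k), integer(1))
  per_kind_frac <- if (activity) per_kind / activity else
    stats::setNames(rep(NA_real_, 4), INGREDIENT_KINDS)

  open_week <- pmin(pmax(week_of(first_open$timestamp, start_date), 1L), weeks)
  late <- phase_of_week(open_week) > catalog$planned_phase[idx]
  late_frac <- if (activity) mean(late) else NA_real_

  login_weeks <- if (frequency)
    sort(unique(pmin(pmax(week_of(logins$start, start_date), 1L), weeks)))
  else integer(0)
  login_phases <- sort(unique(phase_of_week(login_weeks)))
  wd <- weekday_login_counts(logins)

  prompts_opened <- first_open$ingredient_id[
    catalog$has_usefulness_prompt[idx]]
  usefulness <- usefulness_proportions(
    opened_prompts = prompts_opened,
    responses = events[events$event_type == "usefulness_response", ,
                       drop = FALSE],
    catalog = catalog)

  therm_days <- unique(as.Date(
    events$timestamp[events$event_type == "distress_thermometer"], tz = "UTC"))

  structure(list(
    user_id = user_id,
    frequency = frequency,
    n_sessions = nrow(sessions),
    session_durations = durations,
    mean_session_duration = mean_dur,
    total_duration = total_dur,
    activity = activity,
    activity_fraction = activity / catalog_size,
    per_kind_counts = per_kind,
    per_kind_fractions = per_kind_frac,
    late_open_fraction = late_frac,
    phases_active = login_phases,
    weeks_active = login_weeks,
    weekday_login_counts = wd,
    contract_opened = any(events$event_type == "contract_open"),
    contract_signed = any(events$event_type == "contract_sign"),
    avatar_used = any(events$event_type == "avatar_set"),
    n_thermometers = length(therm_days),
    n_support_emails = sum(events$event_type == "support_email"),
    usefulness = usefulness,
    n_prompts_opened = length(prompts_opened)
  ), class = "user_usage_profile")
}

#' Weekday histogram of logins
#'
#' Login sessions are coded by the weekday of their start (sessions crossing
#' midnight belong to the day they started) on the nominal Sunday = 1 ...
#' Saturday = 7 scale.
#'
#' @param sessions session table; only rows with \code{counts_as_login} are
#'   counted.
#' @return named integer vector of length 7 (codes "1".."7").
#' @export
weekday_login_counts <- function(sessions) {
  logins <- sessions[sessions$counts_as_login, , drop = FALSE]
  code <- as.integer(format(logins$start, "%w", tz = "UTC")) + 1L
  stats::setNames(tabulate(code, nbins = 7L), as.character(1:7))
}

#' Weekday histogram with modal-day share
#'
#' @param sessions session table (cohort-wide or per-user).
#' @return list with \code{counts} (Sunday = 1 ... Saturday = 7 coding),
#'   \code{total} logins, \code{modal_day} code, \code{modal_share}, and
#'   \code{shares}.
#' @export
weekday_histogram <- function(sessions) {
  counts <- weekday_login_counts(sessions)
  total <- sum(counts)
  shares <- if (total) counts / total else counts * NA_real_
  modal <- if (total) which.max(counts) else NA_integer_
  list(counts = counts, total = total, modal_day = unname(modal),
       modal_share = if (total) unname(shares[modal]) else NA_real_,
       shares = shares)
}

#' Proportions of opened prompt-bearing ingredients rated useful
#'
#' The denominator is the set of opened prompt-bearing ingredients
#' (assignments and assessments that ask for a usefulness rating). An
#' ingredient with no response record counts as blank, the same as an
#' explicit code 0. With no opened prompt-bearing ingredients the
#' proportions are undefined (NA), which is distinct from (0, 0, 0).
#'
#' @param opened_prompts character vector of opened prompt-bearing
#'   ingredient ids.
#' @param responses usefulness_response event records for this user.
#' @param catalog ingredient catalog.
#' @return named numeric vector \code{c(useful=, not_useful=, blank=)}
#'   summing to 1, or all-NA when undefined.
#' @export
usefulness_proportions <- function(opened_prompts, responses, catalog) {
  if (nrow(responses)) {
    unopened <- setdiff(responses$ingredient_id, opened_prompts)
    if (length(unopened))
      stop("usefulness_response for ingredient(s) never opened: ",
           paste(unopened, collapse = ", "))
  }
  n <- length(opened_prompts)
  if (n == 0)
    return(c(useful = NA_real_, not_useful = NA_real_, blank = NA_real_))
  # last response per ingredient wins; missing record = blank (code 0)
  code <- stats::setNames(rep(0L, n), opened_prompts)
  if (nrow(responses)) {
    responses <- responses[order(responses$timestamp), , drop = FALSE]
    code[responses$ingredient_id] <- responses$value
  }
  c(useful = sum(code == 1L) / n, not_useful = sum(code == 2L) / n,
    blank = sum(code == 0L) / n)
}

#' Compute usage profiles for a whole cohort
#'
#' Users listed in the roster but absent from the log receive an all-zero
#' profile (usefulness undefined).
#'
#' @param events validated cohort event log.
#' @param sessions cohort session table from \code{\link{sessionize_cohort}}.
#' @param catalog ingredient catalog.
#' @param roster validated roster (defines the user set and start dates).
#' @inheritParams compute_profile
#' @return named list of \code{user_usage_profile} objects, one per roster
#'   user.
#' @export
compute_profiles <- function(events, sessions, catalog, roster, weeks = 16,
                             out_of_window = "reject") {
  ev_split <- split(events, factor(events$user_id, levels = roster$user_id))
  se_split <- split(sessions, factor(sessions$user_id,
                                     levels = roster$user_id))
  profiles <- lapply(seq_len(nrow(roster)), function(i) {
    ev <- ev_split[[i]]
    p <- compute_profile(ev, se_split[[i]], catalog, roster$start_date[i],
                         weeks = weeks, out_of_window = out_of_window)
    p$user_id <- roster$user_id[i]
    p
  })
  stats::setNames(profiles, roster$user_id)
}

#' Flatten profiles into one row per user
#'
#' @param profiles list of profiles from \code{\link{compute_profiles}}.
#' @return data frame with scalar profile fields, per-kind counts as
#'   \code{n_<kind>} columns, weekday counts as \code{wd1..wd7}, and
#'   phase/week coverage as comma-separated strings.
#' @export
profiles_table <- function(profiles) {
  rows <- lapply(profiles, function(p) {
    row <- data.frame(
      user_id = p$user_id, frequency = p$frequency,
      n_sessions = p$n_sessions,
      mean_session_duration = p$mean_session_duration,
      total_duration = p$total_duration, activity = p$activity,
      activity_fraction = p$activity_fraction,
      late_open_fraction = p$late_open_fraction,
      n_phases_active = length(p$phases_active),
      phases_active = paste(p$phases_active, collapse = ","),
      weeks_active = paste(p$weeks_active, collapse = ","),
      contract_opened = p$contract_opened,
      contract_signed = p$contract_signed, avatar_used = p$avatar_used,
      n_thermometers = p$n_thermometers,
      n_support_emails = p$n_support_emails,
      n_prompts_opened = p$n_prompts_opened,
      useful_prop = unname(p$usefulness["useful"]),
      not_useful_prop = unname(p$usefulness["not_useful"]),
      blank_prop = unname(p$usefulness["blank"]),
      stringsAsFactors = FALSE)
    for (k in INGREDIENT_KINDS) row[[paste0("n_", k)]] <- p$per_kind_counts[[k]]
    for (d in 1:7) row[[paste0("wd", d)]] <- p$weekday_login_counts[[d]]
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cohort summary of the singular usage statistics
#'
#' Mean, SD, minimum and maximum of frequency, total duration, mean session
#' duration and activity, overall and (when group labels are supplied) per
#' group.
#'
#' @param profiles list of profiles from \code{\link{compute_profiles}}.
#' @param groups optional named character vector mapping user_id to group
#'   label.
#' @return data frame with columns statistic, group, n, mean, sd, min, max.
#' @export
cohort_usage_table <- function(profiles, groups = NULL) {
  if (!length(profiles)) stop("no profiles supplied")
  tab <- profiles_table(profiles)
  stats_cols <- c("frequency", "total_duration", "mean_session_duration",
                  "activity")
  one <- function(values, statistic, group) {
    values <- values[!is.na(values)]
    data.frame(statistic = statistic, group = group, n = length(values),
               mean = mean(values),
               sd = if (length(values) > 1) stats::sd(values) else NA_real_,
               min = if (length(values)) min(values) else NA_real_,
               max = if (length(values)) max(values) else NA_real_,
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(stats_cols, function(s)
    one(tab[[s]], s, "overall")))
  if (!is.null(groups)) {
    g <- groups[tab$user_id]
    for (lev in unique(g)) {
      sub <- tab[g == lev, , drop = FALSE]
      out <- rbind(out, do.call(rbind, lapply(stats_cols, function(s)
        one(sub[[s]], s, lev))))
    }
  }
  rownames(out) <- NULL
  out
}
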