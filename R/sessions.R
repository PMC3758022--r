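#' Session reconstruction from request logs
#'
#' The platform logged one record per user-initiated server request and
#' automatically logged users out after 30 minutes without a request. A
#' session is therefore a maximal run of one user's events in which no two
#' consecutive requests are more than the timeout apart. Because timestamps
#' carry no seconds, session duration is the whole-minute difference between
#' the first and last request of the session; the 30 idle minutes before an
#' auto-logout are never added. A session counts as a login only when it
#' lasts at least 1 minute, the finest duration the minute-resolution log
#' can attest.
#'
#' @name sessions
NULL

#' Split one user's events into sessions
#'
#' Events are partitioned into maximal runs with inter-event gaps no larger
#' than \code{timeout_min} minutes. A gap exactly equal to the timeout stays
#' inside the session (auto-logout fires only after the timeout has been
#' strictly exceeded). Two explicit markers override the gap rule: a
#' \code{logout} event closes its session immediately, and a \code{login}
#' event always starts a new session even if it falls within the timeout of
#' the previous request.
#'
#' @param events one user's events, sorted by timestamp.
#' @param timeout_min inactivity timeout in minutes (default 30).
#' @return data frame with one row per session: \code{user_id},
#'   \code{session_id}, \code{start}, \code{end}, \code{duration_min},
#'   \code{n_events}, \code{counts_as_login}.
#' @export
#' @examples
#' ev <- data.frame(user_id = "u1",
#'                  timestamp = as.POSIXct("2011-03-07 10:00", tz = "UTC") +
#'                    60 * c(0, 10, 45),
#'                  event_type = c("login", "open_ingredient", "open_ingredient"),
#'                  ingredient_id = c(NA, "I01", "I02"), value = NA)
#' sessionize(ev)  # 35-minute gap: two sessions
sessionize <- function(events, timeout_min = 30) {
  if (nrow(events) == 0) return(empty_sessions())
  if (length(unique(events$user_id)) > 1L)
    stop("sessionize() expects events from a single user")
  ts <- as.numeric(events$timestamp) / 60
  if (is.unsorted(ts)) stop("sessionize() expects events sorted by timestamp")
  n <- length(ts)
  gap <- diff(ts)
  breaks <- c(TRUE,
              gap > timeout_min |
                events$event_type[-1] == "login" |
                events$event_type[-n] == "logout")
  sid <- cumsum(breaks)
  start <- events$timestamp[!duplicated(sid)]
  end <- events$timestamp[!duplicated(sid, fromLast = TRUE)]
  dur <- as.integer(round((as.numeric(end) - as.numeric(start)) / 60))
  data.frame(user_id = events$user_id[1], session_id = seq_along(start),
             start = start, end = end, duration_min = dur,
             n_events = as.integer(tabulate(sid)),
             counts_as_login = dur >= 1L, stringsAsFactors = FALSE)
}

empty_sessions <- function() {
  data.frame(user_id = character(), session_id = integer(),
             start = .POSIXct(numeric(), tz = "UTC"),
             end = .POSIXct(numeric(), tz = "UTC"),
             duration_min = integer(), n_events = integer(),
             counts_as_login = logical(), stringsAsFactors = FALSE)
}

#' Sessionize a whole cohort's event log
#'
#' @param events validated event log (any number of users), sorted by
#'   (user_id, timestamp) as \code{\link{validate_events}} produces.
#' @inheritParams sessionize
#' @return row-bound per-user session tables.
#' @export
sessionize_cohort <- function(events, timeout_min = 30) {
  if (nrow(events) == 0) return(empty_sessions())
  parts <- split(events, events$user_id)
  out <- do.call(rbind, lapply(parts, sessionize, timeout_min = timeout_min))
  rownames(out) <- NULL
  out
}

#' Login frequency of one user
#'
#' The number of sessions lasting at least 1 minute, i.e. the number of
#' logins over the observation period.
#'
#' @param sessions one user's session table from \code{\link{sessionize}}.
#' @return nonnegative integer count.
#' @export
login_frequency <- function(sessions) sum(sessions$counts_as_login)

#' Total usage duration of one user
#'
#' The sum of all session durations in minutes. Zero-duration sessions
#' contribute nothing but are included for completeness.
#'
#' @inheritParams login_frequency
#' @return nonnegative integer minutes.
#' @export
total_duration <- function(sessions) as.integer(sum(sessions$duration_min))
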