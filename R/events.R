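#' Event logs and user rosters
#'
#' One event record corresponds to one user-initiated https-server request
#' logged by the intervention platform: logins/logouts, opening or writing
#' an ingredient, answering a usefulness prompt (coded useful = 1,
#' not useful = 2, not filled in = 0), filling a distress thermometer,
#' opening or signing the self-help contract, setting an avatar, or mailing
#' the researchers about a technical problem. The platform logged timestamps
#' at minute resolution (no seconds), so all timestamps are truncated to the
#' minute on ingest.
#'
#' @name events
NULL

EVENT_TYPES <- c("login", "logout", "open_ingredient", "write_ingredient",
                 "usefulness_response", "distress_thermometer",
                 "contract_open", "contract_sign", "avatar_set",
                 "support_email")

INGREDIENT_EVENTS <- c("open_ingredient", "write_ingredient",
                       "usefulness_response")

#' Parse timestamps at minute resolution
#'
#' Accepts ISO 8601 date-times with "T" or space separators, with or without
#' a seconds field. Seconds, when present, are truncated (not rounded), which
#' is order-preserving. Timestamps are stored timezone-naive (UTC).
#'
#' @param x character vector of date-times.
#' @return POSIXct vector (UTC) truncated to whole minutes; NA where
#'   unparseable.
#' @export
parse_minute <- function(x) {
  x <- sub("T", " ", as.character(x), fixed = TRUE)
  t <- as.POSIXct(x, tz = "UTC",
                  tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M"),
                  optional = TRUE)
  trunc_minute(t)
}

trunc_minute <- function(t) {
  .POSIXct(floor(as.numeric(t) / 60) * 60, tz = "UTC")
}

format_minute <- function(t) format(t, "%Y-%m-%dT%H:%M", tz = "UTC")

empty_events <- function() {
  data.frame(user_id = character(), timestamp = .POSIXct(numeric(), tz = "UTC"),
             event_type = character(), ingredient_id = character(),
             value = integer(), stringsAsFactors = FALSE)
}

#' Validate an event log
#'
#' Enforces the event-record invariants: known event types, minute-truncated
#' timestamps, ingredient ids present (and known to the catalog) for
#' open/write/usefulness events, usefulness codes in {0, 1, 2}, and users
#' present in the roster when one is supplied. Records are returned sorted by
#' (user_id, timestamp); ties at the same minute keep their input order
#' (stable sort), since the log carries no sub-minute ordering.
#'
#' @param events data frame with columns \code{user_id}, \code{timestamp},
#'   \code{event_type}, \code{ingredient_id}, \code{value}.
#' @param catalog optional catalog; when given, ingredient ids are checked.
#' @param roster optional roster; when given, user ids are checked.
#' @return validated, sorted event data frame.
#' @export
validate_events <- function(events, catalog = NULL, roster = NULL) {
  required <- c("user_id", "timestamp", "event_type")
  missing <- setdiff(required, names(events))
  if (length(missing))
    stop("event log is missing column(s): ", paste(missing, collapse = ", "))
  if (is.null(events$ingredient_id)) events$ingredient_id <- NA_character_
  if (is.null(events$value)) events$value <- NA_integer_
  events$user_id <- as.character(events$user_id)
  events$event_type <- as.character(events$event_type)
  events$ingredient_id <- as.character(events$ingredient_id)
  events$ingredient_id[!is.na(events$ingredient_id) &
                         events$ingredient_id == ""] <- NA_character_
  events$value <- suppressWarnings(as.integer(events$value))
  if (!inherits(events$timestamp, "POSIXct"))
    events$timestamp <- parse_minute(events$timestamp)
  else events$timestamp <- trunc_minute(events$timestamp)

  bad <- which(is.na(events$timestamp))
  if (length(bad))
    stop("unparseable timestamp in event row(s) ", paste(bad, collapse = ", "))
  bad <- which(!events$event_type %in% EVENT_TYPES)
  if (length(bad))
    stop("unknown event_type in event row(s) ", paste(bad, collapse = ", "),
         ": ", paste(unique(events$event_type[bad]), collapse = ", "))
  bad <- which(events$event_type %in% INGREDIENT_EVENTS &
                 is.na(events$ingredient_id))
  if (length(bad))
    stop("ingredient_id required for open/write/usefulness event row(s) ",
         paste(bad, collapse = ", "))
  bad <- which(events$event_type == "usefulness_response" &
                 (is.na(events$value) | !events$value %in% 0:2))
  if (length(bad))
    stop("usefulness_response value must be 0, 1 or 2 in event row(s) ",
         paste(bad, collapse = ", "))
  if (!is.null(catalog)) {
    bad <- which(!is.na(events$ingredient_id) &
                   !events$ingredient_id %in% catalog$ingredient_id)
    if (length(bad))
      stop("unknown ingredient_id in event row(s) ",
           paste(bad, collapse = ", "), ": ",
           paste(unique(events$ingredient_id[bad]), collapse = ", "))
  }
  if (!is.null(roster)) {
    bad <- which(!events$user_id %in% roster$user_id)
    if (length(bad))
      stop("unknown user_id in event row(s) ", paste(bad, collapse = ", "),
           ": ", paste(unique(events$user_id[bad]), collapse = ", "))
  }
  events <- events[order(events$user_id, events$timestamp, method = "radix"), ,
                   drop = FALSE]
  rownames(events) <- NULL
  events[c("user_id", "timestamp", "event_type", "ingredient_id", "value")]
}

#' Read an event log from CSV or JSON lines
#'
#' The CSV dialect has columns (in order) \code{user_id, timestamp,
#' event_type, ingredient_id, value}, with empty fields for absent
#' ingredient ids and values; the JSONL dialect holds one object per line
#' with the same keys. The format is chosen by file extension
#' (\code{.jsonl}/\code{.json} vs anything else). Ingest truncates seconds
#' and is idempotent: loading an already-minute-truncated file changes
#' nothing.
#'
#' @param path path to the event file.
#' @param catalog optional catalog for ingredient-id validation.
#' @param roster optional roster for user-id validation.
#' @return validated event data frame sorted by (user_id, timestamp).
#' @export
load_events <- function(path, catalog = NULL, roster = NULL) {
  if (!file.exists(path)) stop("event file does not exist: ", path)
  if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) return(validate_events(empty_events(), catalog, roster))
    recs <- lapply(lines, jsonlite::fromJSON)
    grab <- function(key) {
      vapply(recs, function(r) {
        v <- r[[key]]
        if (is.null(v)) NA_character_ else as.character(v)
      }, character(1))
    }
    raw <- data.frame(user_id = grab("user_id"), timestamp = grab("timestamp"),
                      event_type = grab("event_type"),
                      ingredient_id = grab("ingredient_id"),
                      value = grab("value"), stringsAsFactors = FALSE)
  } else {
    raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character")
    if (nrow(raw) == 0) raw <- empty_events()
  }
  validate_events(raw, catalog, roster)
}

#' Write an event log to CSV or JSON lines
#'
#' Round-trip contract: \code{load_events(write_events(x, path))} returns
#' \code{x} for any valid event log, in either dialect.
#'
#' @param events validated event data frame.
#' @param path output path; extension selects the dialect.
#' @return \code{path}, invisibly.
#' @export
write_events <- function(events, path) {
  events <- validate_events(events)
  out <- data.frame(user_id = events$user_id,
                    timestamp = format_minute(events$timestamp),
                    event_type = events$event_type,
                    ingredient_id = ifelse(is.na(events$ingredient_id), "",
                                           events$ingredient_id),
                    value = ifelse(is.na(events$value), "",
                                   as.character(events$value)),
                    stringsAsFactors = FALSE)
  if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) {
    lines <- vapply(seq_len(nrow(out)), function(i) {
      rec <- list(user_id = out$user_id[i], timestamp = out$timestamp[i],
                  event_type = out$event_type[i])
      if (nzchar(out$ingredient_id[i])) rec$ingredient_id <- out$ingredient_id[i]
      if (nzchar(out$value[i])) rec$value <- as.integer(out$value[i])
      as.character(jsonlite::toJSON(rec, auto_unbox = TRUE))
    }, character(1))
    writeLines(lines, path)
  } else {
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

weekday_name_to_iso <- function(day) {
  days <- c("Monday", "Tuesday", "Wednesday", "Thursday", "Friday",
            "Saturday", "Sunday")
  i <- match(day, days)
  if (is.na(i)) stop("unknown weekday name: ", day)
  i
}

#' Validate a user roster
#'
#' A roster lists every enrolled participant with the date their 16-week
#' intervention access began (the weekly unlock day, Monday by default) and
#' optional baseline covariates.
#'
#' @param roster data frame with columns \code{user_id}, \code{start_date},
#'   then optional covariate columns (e.g. age, education on a 1-7 scale,
#'   married/children flags, employment and adjuvant-treatment categories,
#'   hormonal-therapy flag, baseline distress total score).
#' @param unlock_weekday weekday on which weekly content unlocks and start
#'   dates must fall; default "Monday".
#' @return validated roster with \code{start_date} as Date.
#' @export
validate_roster <- function(roster, unlock_weekday = "Monday") {
  missing <- setdiff(c("user_id", "start_date"), names(roster))
  if (length(missing))
    stop("roster is missing column(s): ", paste(missing, collapse = ", "))
  roster$user_id <- as.character(roster$user_id)
  dup <- duplicated(roster$user_id)
  if (any(dup))
    stop("duplicate user_id in roster: ",
         paste(unique(roster$user_id[dup]), collapse = ", "))
  roster$start_date <- as.Date(roster$start_date)
  if (any(is.na(roster$start_date)))
    stop("unparseable start_date in roster row(s) ",
         paste(which(is.na(roster$start_date)), collapse = ", "))
  iso <- as.integer(format(roster$start_date, "%u"))
  bad <- which(iso != weekday_name_to_iso(unlock_weekday))
  if (length(bad))
    stop("start_date must fall on the unlock day (", unlock_weekday,
         ") in roster row(s) ", paste(bad, collapse = ", "))
  if ("education" %in% names(roster)) {
    ed <- roster$education
    bad <- which(!is.na(ed) & (ed != round(ed) | ed < 1 | ed > 7))
    if (length(bad))
      stop("education must be an integer 1-7 in roster row(s) ",
           paste(bad, collapse = ", "))
  }
  roster
}

#' Read a user roster from CSV
#' @inheritParams validate_roster
#' @param path path to a roster CSV with columns \code{user_id},
#'   \code{start_date} (ISO date), then optional covariates.
#' @return validated roster data frame.
#' @export
load_roster <- function(path, unlock_weekday = "Monday") {
  if (!file.exists(path)) stop("roster file does not exist: ", path)
  validate_roster(utils::read.csv(path, stringsAsFactors = FALSE),
                  unlock_weekday)
}

#' Write a user roster to CSV
#' @param roster validated roster data frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_roster <- function(roster, path) {
  utils::write.csv(roster, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
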