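# shared fixture builders (everything generated in code, no stored data)

minute0 <- as.POSIXct("2010-11-01 10:00", tz = "UTC")  # a Monday

# events for one user at the given minute offsets
make_events <- function(minutes, user = "u1", types = NULL, ingredients = NULL,
                        values = NULL, origin = minute0) {
  n <- length(minutes)
  data.frame(user_id = rep(user, length.out = n),
             timestamp = origin + minutes * 60,
             event_type = if (is.null(types)) rep("open_ingredient", n)
             else types,
             ingredient_id = if (is.null(ingredients))
               sprintf("I%02d", seq_len(n)) else ingredients,
             value = if (is.null(values)) rep(NA_integer_, n) else values,
             stringsAsFactors = FALSE)
}

make_roster <- function(user_ids = "u1", start_date = as.Date("2010-11-01")) {
  data.frame(user_id = user_ids, start_date = start_date,
             stringsAsFactors = FALSE)
}

# random valid event stream for round-trip / sessionizer properties
random_events <- function(n, user = "u1", catalog = default_catalog(),
                          span_min = 2000) {
  minutes <- sort(sample.int(span_min, n, replace = TRUE)) - 1L
  types <- sample(c("login", "logout", "open_ingredient",
                    "distress_thermometer", "contract_open"),
                  n, replace = TRUE,
                  prob = c(0.15, 0.1, 0.5, 0.15, 0.1))
  ingr <- ifelse(types == "open_ingredient",
                 sample(catalog$ingredient_id, n, replace = TRUE),
                 NA_character_)
  make_events(minutes, user = user, types = types, ingredients = ingr)
}

# independent brute-force sessionizer: plain event-by-event scan written
# against the timeout/login/logout rules, no vectorized bookkeeping
oracle_sessionize <- function(events, timeout_min = 30) {
  n <- nrow(events)
  if (n == 0) return(integer(0))
  sid <- integer(n)
  sid[1] <- 1L
  for (i in seq_len(n)[-1]) {
    gap <- as.numeric(events$timestamp[i] - events$timestamp[i - 1],
                      units = "mins")
    new_session <- gap > timeout_min ||
      events$event_type[i] == "login" ||
      events$event_type[i - 1] == "logout"
    sid[i] <- sid[i - 1] + if (new_session) 1L else 0L
  }
  sid
}

session_summary_from_ids <- function(events, sid) {
  do.call(rbind, lapply(split(seq_along(sid), sid), function(ix) {
    data.frame(start = min(events$timestamp[ix]),
               end = max(events$timestamp[ix]),
               n_events = length(ix))
  }))
}

# profile stub for classifier tests
stub_profile <- function(frequency, activity, user = "u1") {
  list(user_id = user, frequency = frequency, activity = activity)
}

small_cohort <- function(n = 20, seed = 101, ...) {
  sample_cohort(cohort_config(n_users = n, seed = seed, ...))
}
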