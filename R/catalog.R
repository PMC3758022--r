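#' Intervention ingredient catalogs
#'
#' An ingredient catalog describes every discrete content unit of a stepwise
#' 16-week web intervention: information scripts, assignment tasks,
#' assessment tests and video clusters. Each ingredient is planned for one
#' week (1-16) and therefore one 4-week phase (1-4); content unlocks at the
#' start of its planned week and stays accessible afterwards. A subset of
#' assignments and assessments carries an optional usefulness prompt shown
#' after use.
#'
#' @name catalog
NULL

INGREDIENT_KINDS <- c("information", "assignment", "assessment", "video")

phase_of_week <- function(week) as.integer(ceiling(week / 4))

#' Validate an ingredient catalog
#'
#' Checks the structural invariants every catalog must satisfy: unique
#' ingredient ids, known kinds, planned weeks in 1-16, and
#' \code{planned_phase == ceiling(planned_week / 4)}.
#'
#' @param catalog data frame with columns \code{ingredient_id}, \code{kind},
#'   \code{planned_week}, \code{planned_phase}, \code{has_usefulness_prompt}.
#' @return the validated catalog, invisibly coerced to canonical column types.
#' @export
validate_catalog <- function(catalog) {
  required <- c("ingredient_id", "kind", "planned_week", "planned_phase",
                "has_usefulness_prompt")
  missing <- setdiff(required, names(catalog))
  if (length(missing))
    stop("catalog is missing column(s): ", paste(missing, collapse = ", "))
  catalog$ingredient_id <- as.character(catalog$ingredient_id)
  catalog$kind <- as.character(catalog$kind)
  catalog$planned_week <- as.integer(catalog$planned_week)
  catalog$planned_phase <- as.integer(catalog$planned_phase)
  catalog$has_usefulness_prompt <- parse_logical(catalog$has_usefulness_prompt)

  dup <- duplicated(catalog$ingredient_id)
  if (any(dup))
    stop("duplicate ingredient_id in catalog row(s) ",
         paste(which(dup), collapse = ", "), ": ",
         paste(unique(catalog$ingredient_id[dup]), collapse = ", "))
  bad <- which(!catalog$kind %in% INGREDIENT_KINDS)
  if (length(bad))
    stop("unknown ingredient kind in catalog row(s) ",
         paste(bad, collapse = ", "), ": ",
         paste(unique(catalog$kind[bad]), collapse = ", "))
  bad <- which(is.na(catalog$planned_week) | catalog$planned_week < 1L |
                 catalog$planned_week > 16L)
  if (length(bad))
    stop("planned_week outside 1-16 in catalog row(s) ",
         paste(bad, collapse = ", "))
  bad <- which(catalog$planned_phase != phase_of_week(catalog$planned_week))
  if (length(bad))
    stop("planned_phase does not equal ceiling(planned_week/4) in row(s) ",
         paste(bad, collapse = ", "))
  if (any(is.na(catalog$has_usefulness_prompt)))
    stop("has_usefulness_prompt must be TRUE/FALSE in every row")
  catalog
}

parse_logical <- function(x) {
  if (is.logical(x)) return(x)
  out <- rep(NA, length(x))
  lx <- tolower(trimws(as.character(x)))
  out[lx %in% c("true", "t", "1", "yes")] <- TRUE
  out[lx %in% c("false", "f", "0", "no")] <- FALSE
  out
}

#' Read an ingredient catalog from CSV
#'
#' Expected columns: \code{ingredient_id, kind, planned_week, planned_phase,
#' has_usefulness_prompt}. All \code{\link{validate_catalog}} invariants are
#' enforced; errors name the offending row.
#'
#' @param path path to a catalog CSV file.
#' @return validated catalog data frame.
#' @export
load_catalog <- function(path) {
  if (!file.exists(path)) stop("catalog file does not exist: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (nrow(raw) == 0) {
    validate_catalog(data.frame(ingredient_id = character(),
                                kind = character(),
                                planned_week = integer(),
                                planned_phase = integer(),
                                has_usefulness_prompt = logical()))
  } else {
    validate_catalog(raw)
  }
}

#' Write an ingredient catalog to CSV
#'
#' @param catalog validated catalog data frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  catalog <- validate_catalog(catalog)
  out <- catalog[c("ingredient_id", "kind", "planned_week", "planned_phase",
                   "has_usefulness_prompt")]
  out$has_usefulness_prompt <- tolower(as.character(out$has_usefulness_prompt))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Canonical 104-ingredient default catalog
#'
#' The intervention studied by this package contains 104 ingredients:
#' 26 information scripts, 48 assignment tasks, 10 assessment tests and
#' 20 video clusters, spread over 16 weeks in four 4-week phases, with all
#' assessments planned in the first two phases and 45 assignments/assessments
#' carrying a usefulness prompt. The exact per-week placement of ingredients
#' was never published, so this constructor fixes one documented,
#' deterministic layout satisfying every published constraint: each kind is
#' spread as evenly as possible over its eligible weeks (assessments over
#' weeks 1-8 only), and the 45 prompt-bearing ingredients are the 10
#' assessments plus the first 35 assignments in id order. All downstream
#' code reads placement only from the catalog, so a different layout can be
#' substituted from file at any time.
#'
#' @return a validated catalog data frame with 104 rows.
#' @export
#' @examples
#' cat104 <- default_catalog()
#' table(cat104$kind)
default_catalog <- function() {
  info_weeks <- rep(1:16, length.out = 26)
  assign_weeks <- rep(1:16, each = 3)
  assess_weeks <- rep(1:8, length.out = 10)
  video_weeks <- rep(1:16, length.out = 20)
  catalog <- data.frame(
    ingredient_id = c(sprintf("I%02d", 1:26), sprintf("A%02d", 1:48),
                      sprintf("T%02d", 1:10), sprintf("V%02d", 1:20)),
    kind = rep(INGREDIENT_KINDS, times = c(26, 48, 10, 20)),
    planned_week = as.integer(c(sort(info_weeks), assign_weeks,
                                sort(assess_weeks), sort(video_weeks))),
    stringsAsFactors = FALSE
  )
  catalog$planned_phase <- phase_of_week(catalog$planned_week)
  catalog$has_usefulness_prompt <-
    catalog$kind == "assessment" |
    (catalog$kind == "assignment" & catalog$ingredient_id <= "A35")
  validate_catalog(catalog)
}
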