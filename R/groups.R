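#' Intended-vs-observed user-group classification
#'
#' Developers of an intervention state, before evaluation, the minimal
#' usage they intend: here at least 10 logins over the course of the
#' intervention and opening at least 50% of the 104 ingredients. Observed
#' frequency and activity are cross-tabulated against four nested tiers of
#' minimal intended usage; a user's tier is the highest tier whose
#' frequency AND activity minima are both met (conjunctive rule: the
#' minimum of the two band indices). The intended tier is collapsed into
#' high when it turns out nonsubstantial (at most 2 members by default),
#' mirroring published practice.
#'
#' @name user-groups
NULL

#' Specification of the intended-usage tiers
#'
#' @param tiers data frame with columns \code{label},
#'   \code{min_frequency} (logins), \code{min_activity_fraction} (fraction
#'   of the catalog opened), ordered and strictly increasing in both
#'   thresholds. Defaults: nonuser (0, 0), low (1, 1%), intended (10, 50%),
#'   high (17, 75%).
#' @param collapse_intended_into_high collapse the intended tier into high
#'   when nonsubstantial; default TRUE.
#' @param collapse_threshold collapse only when the intended tier has at
#'   most this many members (cohort-level classification); default 2.
#' @param activity_rounding \code{"ceiling"} (default) converts fraction
#'   thresholds to ingredient counts with \code{ceiling(fraction * catalog
#'   size)}; \code{"exact"} compares fractions directly.
#' @return object of class \code{intended_usage_spec}.
#' @export
intended_usage_spec <- function(
    tiers = data.frame(
      label = c("nonuser", "low", "intended", "high"),
      min_frequency = c(0L, 1L, 10L, 17L),
      min_activity_fraction = c(0, 0.01, 0.50, 0.75),
      stringsAsFactors = FALSE),
    collapse_intended_into_high = TRUE,
    collapse_threshold = 2L,
    activity_rounding = c("ceiling", "exact")) {
  activity_rounding <- match.arg(activity_rounding)
  if (is.unsorted(tiers$min_frequency, strictly = TRUE) ||
      is.unsorted(tiers$min_activity_fraction, strictly = TRUE))
    stop("tier thresholds must be strictly increasing")
  structure(list(tiers = tiers,
                 collapse_intended_into_high = collapse_intended_into_high,
                 collapse_threshold = as.integer(collapse_threshold),
                 activity_rounding = activity_rounding),
            class = "intended_usage_spec")
}

activity_band <- function(activity, spec, catalog_size) {
  if (spec$activity_rounding == "ceiling") {
    minima <- ceiling(spec$tiers$min_activity_fraction * catalog_size)
    v <- activity
  } else {
    minima <- spec$tiers$min_activity_fraction
    v <- activity / catalog_size
  }
  max(which(v >= minima)) - 1L
}

frequency_band <- function(frequency, spec) {
  max(which(frequency >= spec$tiers$min_frequency)) - 1L
}

#' Classify one user against the intended-usage tiers
#'
#' @param profile a \code{user_usage_profile}, or a list with
#'   \code{frequency} and \code{activity} fields.
#' @param spec an \code{\link{intended_usage_spec}}.
#' @param catalog_size number of ingredients in the catalog, default 104.
#' @return list with \code{user_id}, \code{frequency_band} and
#'   \code{activity_band} (0-3), \code{tier} (label of min band), and
#'   \code{final_group} (intended collapsed into high when the spec says
#'   so; cohort-conditional collapse is applied by
#'   \code{\link{classify_cohort}}).
#' @export
#' @examples
#' spec <- intended_usage_spec()
#' classify_user(list(frequency = 21, activity = 95), spec)$final_group
classify_user <- function(profile, spec = intended_usage_spec(),
                          catalog_size = 104) {
  fb <- frequency_band(profile$frequency, spec)
  ab <- activity_band(profile$activity, spec, catalog_size)
  tier <- spec$tiers$label[min(fb, ab) + 1L]
  final <- if (tier == "intended" && spec$collapse_intended_into_high)
    "high" else tier
  list(user_id = profile$user_id, frequency_band = fb, activity_band = ab,
       tier = tier, final_group = final)
}

#' Classify a cohort and cross-tabulate observed against intended usage
#'
#' Produces the per-user assignments and the 4x4 cross-tabulation of
#' frequency band (rows) by activity band (columns). The intended tier is
#' collapsed into high only when its member count does not exceed
#' \code{spec$collapse_threshold}; a substantial intended group is kept as
#' its own final group.
#'
#' @param profiles list of \code{user_usage_profile} objects.
#' @inheritParams classify_user
#' @return object of class \code{user_group_classification}: list with
#'   \code{assignments} (data frame), \code{crosstab} (4x4 matrix),
#'   \code{group_sizes}, \code{collapsed} (logical).
#' @export
classify_cohort <- function(profiles, spec = intended_usage_spec(),
                            catalog_size = 104) {
  if (!length(profiles)) stop("no profiles supplied")
  rows <- lapply(profiles, classify_user, spec = spec,
                 catalog_size = catalog_size)
  assignments <- data.frame(
    user_id = vapply(rows, `[[`, character(1), "user_id"),
    frequency_band = vapply(rows, `[[`, integer(1), "frequency_band"),
    activity_band = vapply(rows, `[[`, integer(1), "activity_band"),
    tier = vapply(rows, `[[`, character(1), "tier"),
    stringsAsFactors = FALSE)
  labels <- spec$tiers$label
  n_intended <- sum(assignments$tier == "intended")
  collapsed <- spec$collapse_intended_into_high &&
    n_intended <= spec$collapse_threshold
  assignments$final_group <- if (collapsed)
    ifelse(assignments$tier == "intended", "high", assignments$tier)
  else assignments$tier
  crosstab <- table(
    frequency_band = factor(assignments$frequency_band, levels = 0:3),
    activity_band = factor(assignments$activity_band, levels = 0:3))
  final_levels <- if (collapsed) setdiff(labels, "intended") else labels
  structure(list(
    assignments = assignments,
    crosstab = unclass(crosstab),
    group_sizes = table(factor(assignments$final_group,
                               levels = final_levels)),
    collapsed = collapsed, spec = spec
  ), class = "user_group_classification")
}

#' @export
print.user_group_classification <- function(x, ...) {
  cat("User groups (intended tier ",
      if (x$collapsed) "collapsed into high" else "kept separate", "):\n",
      sep = "")
  print(x$group_sizes)
  cat("Cross-tabulation (frequency band x activity band):\n")
  print(x$crosstab)
  invisible(x)
}

#' Compare classified groups with generator ground truth
#'
#' For validating the classifier against the synthetic generator's
#' archetype labels: builds the 3x3 confusion matrix over
#' {nonuser, low, high} (classified "intended" users count as high) and the
#' overall agreement fraction.
#'
#' @param truth named character vector or data frame (\code{user_id},
#'   \code{archetype}) of generator labels.
#' @param assignments assignments data frame from
#'   \code{\link{classify_cohort}} (or any data frame with \code{user_id}
#'   and \code{final_group}).
#' @return list with \code{confusion} (truth rows x classified columns) and
#'   \code{recovery} (agreement fraction).
#' @export
truth_report <- function(truth, assignments) {
  if (is.data.frame(truth))
    truth <- stats::setNames(truth$archetype, truth$user_id)
  if (!length(truth)) stop("empty cohort: no truth labels")
  got <- stats::setNames(assignments$final_group, assignments$user_id)
  if (!setequal(names(truth), names(got)))
    stop("truth and classified user sets differ")
  got <- got[names(truth)]
  got[got == "intended"] <- "high"
  levs <- c("nonuser", "low", "high")
  confusion <- table(truth = factor(truth, levels = levs),
                     classified = factor(got, levels = levs))
  list(confusion = unclass(confusion),
       recovery = mean(truth == got))
}
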