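#' Full usage evaluation of an intervention cohort
#'
#' Runs the complete pipeline on a validated event log: session
#' reconstruction with the inactivity timeout, per-user usage profiles,
#' phase-coverage adherence with Wilson intervals, intended-vs-observed
#' user-group classification, weekday login profile with a uniformity
#' test, correlations among the singular usage statistics, and (when the
#' roster carries covariates) a group-characteristics comparison table.
#' The result is a classed object with print, summary and plot methods.
#'
#' @param events validated event log (see \code{\link{load_events}}).
#' @param roster validated roster defining the user set and start dates.
#' @param catalog ingredient catalog, default \code{\link{default_catalog}}.
#' @param timeout_min inactivity timeout in minutes, default 30.
#' @param confidence confidence level for all Wilson intervals.
#' @param spec an \code{\link{intended_usage_spec}}.
#' @param weeks observation window in weeks, default 16.
#' @param out_of_window policy for events outside the window (see
#'   \code{\link{compute_profile}}).
#' @return object of class \code{usage_evaluation}: list with
#'   \code{sessions}, \code{profiles}, \code{profile_table},
#'   \code{adherence}, \code{weekly_persistence}, \code{groups},
#'   \code{usage_table}, \code{weekday}, \code{weekday_test},
#'   \code{correlations}, \code{engagement} (contract/avatar/thermometer
#'   proportions with Wilson CIs), \code{group_table} (or NULL), and the
#'   configuration used.
#' @export
#' @examples
#' coh <- sample_cohort(cohort_config(n_users = 20, seed = 7))
#' ev <- usage_evaluation(coh$events, coh$roster)
#' print(ev)
usage_evaluation <- function(events, roster, catalog = default_catalog(),
                             timeout_min = 30, confidence = 0.95,
                             spec = intended_usage_spec(), weeks = 16,
                             out_of_window = "reject") {
  events <- validate_events(events, catalog, roster)
  sessions <- sessionize_cohort(events, timeout_min)
  profiles <- compute_profiles(events, sessions, catalog, roster,
                               weeks = weeks,
                               out_of_window = out_of_window)
  coverages <- lapply(profiles, phase_coverage)
  adher <- adherence_summary(coverages, confidence)
  groups <- classify_cohort(profiles, spec, nrow(catalog))
  glab <- stats::setNames(groups$assignments$final_group,
                          groups$assignments$user_id)
  usage_tab <- cohort_usage_table(profiles, glab)
  wk <- weekday_histogram(sessions)
  wk_test <- if (wk$total > 0) weekday_uniformity_test(wk$counts) else NULL

  tab <- profiles_table(profiles)
  corr <- list()
  for (pair in list(c("frequency", "total_duration"),
                    c("frequency", "activity"),
                    c("total_duration", "activity"))) {
    nm <- paste(pair, collapse = "_vs_")
    corr[[nm]] <- tryCatch(
      pearson_correlation(tab[[pair[1]]], tab[[pair[2]]]),
      error = function(e) NULL)
  }
  n <- nrow(roster)
  engagement <- list(
    contract_opened = wilson_ci(sum(tab$contract_opened), n, confidence),
    contract_signed = wilson_ci(sum(tab$contract_signed), n, confidence),
    avatar_used = wilson_ci(sum(tab$avatar_used), n, confidence),
    any_thermometer = wilson_ci(sum(tab$n_thermometers > 0), n, confidence))

  group_tab <- if (any(c("age", "education", "hads_t") %in% names(roster)))
    tryCatch(group_characteristics_table(roster, glab),
             error = function(e) NULL)
  else NULL

  structure(list(
    sessions = sessions, profiles = profiles, profile_table = tab,
    adherence = adher,
    weekly_persistence = weekly_persistence(coverages, weeks),
    groups = groups, usage_table = usage_tab,
    weekday = wk, weekday_test = wk_test, correlations = corr,
    engagement = engagement, group_table = group_tab,
    config = list(timeout_min = timeout_min, confidence = confidence,
                  weeks = weeks, n_users = n,
                  catalog_size = nrow(catalog))
  ), class = "usage_evaluation")
}

#' @export
print.usage_evaluation <- function(x, ...) {
  cat("Usage evaluation:", x$config$n_users, "users,", x$config$weeks,
      "weeks,", x$config$catalog_size, "ingredients\n\n")
  print(x$adherence)
  cat("\n")
  print(x$groups)
  if (!is.null(x$weekday_test))
    cat(sprintf("\nModal login day: %d (share %.1f%%), uniformity p = %.3g\n",
                x$weekday$modal_day, 100 * x$weekday$modal_share,
                x$weekday_test$p_value))
  invisible(x)
}

#' @export
summary.usage_evaluation <- function(object, ...) {
  print(object)
  cat("\nUsage statistics by group:\n")
  print(object$usage_table, digits = 3)
  if (length(object$correlations)) {
    cat("\nCorrelations among usage statistics:\n")
    for (nm in names(object$correlations)) {
      co <- object$correlations[[nm]]
      if (!is.null(co))
        cat(sprintf("  %s: r = %.2f (p = %.3g)\n", nm, co$r, co$p_value))
    }
  }
  if (!is.null(object$group_table)) {
    cat("\nGroup characteristics (low vs high):\n")
    print(object$group_table, digits = 3)
  }
  invisible(object)
}

#' Stacked adherence bar (phase-coverage breakdown)
#'
#' @param x a \code{usage_evaluation}.
#' @param ... passed to \code{barplot}.
#' @export
plot.usage_evaluation <- function(x, ...) {
  counts <- x$adherence$counts
  counts <- counts[counts > 0 | names(counts) %in%
                     c("never", "all_four")]
  graphics::barplot(as.matrix(counts), horiz = TRUE, beside = FALSE,
                    legend.text = names(counts),
                    main = "Phase coverage (continuous vs intermittent usage)",
                    xlab = "participants", ...)
  invisible(x)
}

#' Group-characteristics comparison table
#'
#' Compares baseline covariates between the low and high user groups, one
#' row per characteristic: continuous covariates with a two-sample t test
#' (pooled by default, the classical reporting convention), binary
#' covariates with Pearson chi-square or, when any expected cell is below
#' 5, the Fisher exact test. Rows are labelled with the test used. Groups
#' with fewer than 2 members yield NA rows rather than an error.
#'
#' @param roster roster with covariate columns (any of \code{age},
#'   \code{education}, \code{hads_t} continuous; \code{married},
#'   \code{children}, \code{hormonal_therapy} logical; \code{employment},
#'   \code{adjuvant_treatment} categorical).
#' @param groups named character vector user_id -> final group.
#' @param compare which two groups to compare, default c("low", "high").
#' @param pooled use pooled-variance t tests, default TRUE.
#' @param test_override optional named character vector mapping a row name
#'   to "fisher" or "chisq" to force the test used for that binary row.
#' @return data frame with columns characteristic, test, and per-group
#'   summaries, plus the two-sided p value.
#' @export
group_characteristics_table <- function(roster, groups,
                                        compare = c("low", "high"),
                                        pooled = TRUE,
                                        test_override = NULL) {
  g <- groups[roster$user_id]
  a <- roster[!is.na(g) & g == compare[1], , drop = FALSE]
  b <- roster[!is.na(g) & g == compare[2], , drop = FALSE]
  rows <- list()

  cont_row <- function(name, col) {
    x <- a[[col]]; y <- b[[col]]
    if (is.null(x) || is.null(y)) return(NULL)
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    p <- if (length(x) >= 2 && length(y) >= 2)
      two_sample_t(x, y, pooled = pooled)$p_value else NA_real_
    data.frame(characteristic = name, test = "t",
               group1 = sprintf("%.2f (%.2f)", mean(x), stats::sd(x)),
               group2 = sprintf("%.2f (%.2f)", mean(y), stats::sd(y)),
               p_value = p, stringsAsFactors = FALSE)
  }
  bin_row <- function(name, flag_a, flag_b) {
    flag_a <- flag_a[!is.na(flag_a)]; flag_b <- flag_b[!is.na(flag_b)]
    if (!length(flag_a) || !length(flag_b))
      return(data.frame(characteristic = name, test = NA, group1 = NA,
                        group2 = NA, p_value = NA_real_))
    tab <- rbind(c(sum(flag_a), sum(!flag_a)),
                 c(sum(flag_b), sum(!flag_b)))
    choice <- if (!is.null(test_override) && name %in% names(test_override))
      test_override[[name]]
    else if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) "fisher"
    else if (any(suppressWarnings(
      stats::chisq.test(tab, correct = FALSE))$expected < 5))
      "fisher" else "chisq"
    p <- if (choice == "fisher") fisher_exact_2x2(tab)$p_value
    else pearson_chi_square(tab)$p_value
    data.frame(characteristic = name, test = choice,
               group1 = sprintf("%d (%.1f%%)", sum(flag_a),
                                100 * mean(flag_a)),
               group2 = sprintf("%d (%.1f%%)", sum(flag_b),
                                100 * mean(flag_b)),
               p_value = p, stringsAsFactors = FALSE)
  }

  for (col in intersect(c("age", "education", "hads_t",
                          "overall_satisfaction", "user_friendliness"),
                        names(roster)))
    rows[[col]] <- cont_row(col, col)
  for (col in intersect(c("married", "children", "hormonal_therapy"),
                        names(roster)))
    rows[[col]] <- bin_row(col, a[[col]], b[[col]])
  if ("employment" %in% names(roster)) {
    rows$employment_paid <- bin_row("employment_paid",
                                    a$employment == "paid",
                                    b$employment == "paid")
    rows$employment_disablement <- bin_row("employment_disablement",
                                           a$employment == "disablement",
                                           b$employment == "disablement")
  }
  if ("adjuvant_treatment" %in% names(roster))
    rows$adjuvant_both <- bin_row("adjuvant_both",
                                  a$adjuvant_treatment == "both",
                                  b$adjuvant_treatment == "both")
  if ("hads_t" %in% names(roster))
    rows$elevated_distress <- bin_row("elevated_distress",
                                      a$hads_t >= 11, b$hads_t >= 11)
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  rownames(out) <- NULL
  names(out)[names(out) == "group1"] <- compare[1]
  names(out)[names(out) == "group2"] <- compare[2]
  out
}

#' File-based pipeline run with a reproducibility manifest
#'
#' Reads the event log, catalog and roster from file, runs
#' \code{\link{usage_evaluation}}, and writes the report bundle to
#' \code{out_dir}: \code{sessions.csv}, \code{profiles.csv},
#' \code{groups.csv}, \code{crosstab.csv}, \code{adherence.json},
#' \code{summary.json} and \code{manifest.json} (input MD5 checksums plus
#' the configuration, so identical inputs and configuration yield an
#' identical manifest). Deterministic given its inputs.
#'
#' @param events_path,catalog_path,roster_path input file paths.
#' @param out_dir output directory (created if absent).
#' @inheritParams usage_evaluation
#' @return the \code{usage_evaluation} object, invisibly.
#' @export
run_usage_pipeline <- function(events_path, catalog_path = NULL,
                               roster_path, out_dir,
                               timeout_min = 30, confidence = 0.95,
                               spec = intended_usage_spec(), weeks = 16,
                               out_of_window = "reject") {
  catalog <- if (is.null(catalog_path)) default_catalog()
  else load_catalog(catalog_path)
  roster <- load_roster(roster_path)
  events <- load_events(events_path, catalog, roster)
  res <- usage_evaluation(events, roster, catalog, timeout_min, confidence,
                          spec, weeks, out_of_window)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)

  sess <- res$sessions
  sess$start <- format_minute(sess$start)
  sess$end <- format_minute(sess$end)
  utils::write.csv(sess, p("sessions.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(res$profile_table, p("profiles.csv"), row.names = FALSE)
  utils::write.csv(res$groups$assignments, p("groups.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(as.data.frame.matrix(res$groups$crosstab),
                   p("crosstab.csv"))
  ci <- function(x) list(successes = x$successes, n = x$n,
                         percent = 100 * x$point,
                         lower = 100 * x$lower, upper = 100 * x$upper)
  jsonlite::write_json(list(
    n = res$adherence$n,
    counts = as.list(res$adherence$counts),
    continuous = ci(res$adherence$continuous),
    intermittent_as_printed = ci(res$adherence$intermittent_as_printed),
    intermittent_strict = ci(res$adherence$intermittent_strict),
    weekly_persistence = res$weekly_persistence
  ), p("adherence.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(
    group_sizes = as.list(res$groups$group_sizes),
    collapsed = res$groups$collapsed,
    monday_share = unname(res$weekday$shares[2]),
    weekday_p = if (is.null(res$weekday_test)) NULL
    else res$weekday_test$p_value,
    engagement = lapply(res$engagement, ci)
  ), p("summary.json"), auto_unbox = TRUE, digits = NA)

  inputs <- c(events = events_path, roster = roster_path,
              catalog = if (!is.null(catalog_path)) catalog_path)
  jsonlite::write_json(list(
    inputs = as.list(tools::md5sum(inputs)),
    config = list(timeout_min = timeout_min, confidence = confidence,
                  weeks = weeks,
                  tiers = res$groups$spec$tiers,
                  collapse_threshold = res$groups$spec$collapse_threshold)
  ), p("manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(res)
}
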