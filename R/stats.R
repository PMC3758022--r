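#' Wilson score confidence interval for a binomial proportion
#'
#' The Wilson interval is obtained by inverting the normal-approximation
#' score test. With \eqn{\hat p = k/n} and \eqn{z} the two-sided standard
#' normal quantile for the confidence level, the interval is centred at
#' \deqn{(\hat p + z^2/2n) / (1 + z^2/n)} with half-width
#' \deqn{z \sqrt{\hat p (1-\hat p)/n + z^2/4n^2} / (1 + z^2/n),}
#' clipped to [0, 1]. Unlike the Wald interval it never escapes [0, 1],
#' collapses to 0 at \eqn{k = 0} and to 1 at \eqn{k = n}, and has close to
#' nominal coverage at moderate n; it is the reporting standard used for
#' every proportion in this package. The exact normal quantile is used
#' (1.959964 at 95%), not the rounded 1.96.
#'
#' @param successes number of successes (0..n).
#' @param n number of trials (positive).
#' @param confidence confidence level, default 0.95.
#' @return object of class \code{proportion_ci}: a list with
#'   \code{successes}, \code{n}, \code{point} (= successes/n),
#'   \code{center} (Wilson center), \code{lower}, \code{upper},
#'   \code{confidence}.
#' @export
#' @examples
#' wilson_ci(31, 70)   # 44.3% (33.2, 55.9)
wilson_ci <- function(successes, n, confidence = 0.95) {
  if (length(n) != 1L || is.na(n) || n < 1) stop("n must be a positive integer")
  if (length(successes) != 1L || is.na(successes) || successes < 0 ||
      successes > n)
    stop("successes must lie in 0..n")
  if (confidence <= 0 || confidence >= 1) stop("confidence must be in (0, 1)")
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  p <- successes / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  structure(list(successes = as.integer(successes), n = as.integer(n),
                 point = p, center = center,
                 lower = max(0, center - half), upper = min(1, center + half),
                 confidence = confidence),
            class = "proportion_ci")
}

#' @export
print.proportion_ci <- function(x, digits = 1, ...) {
  cat(sprintf("%d/%d = %.*f%% (%d%% CI %.*f-%.*f)\n", x$successes, x$n,
              digits, 100 * x$point, round(100 * x$confidence),
              digits, 100 * x$lower, digits, 100 * x$upper))
  invisible(x)
}

#' @export
format.proportion_ci <- function(x, digits = 1, ...) {
  sprintf("%.*f%% (%.*f-%.*f)", digits, 100 * x$point, digits, 100 * x$lower,
          digits, 100 * x$upper)
}

#' Two-sample t test from raw samples or summary statistics
#'
#' Accepts either raw numeric vectors or (mean, sd, n) summaries per group,
#' the form in which published group characteristics are usually available.
#' Both the pooled-variance (Student) and unpooled (Welch) variants are
#' provided; Welch is the default for new analyses, while the pooled variant
#' reproduces classically reported p values. When both groups have zero
#' variance and equal means the statistic is 0 and p = 1 by convention.
#'
#' @param x,y raw samples (ignored when summaries are given).
#' @param mean_x,sd_x,n_x,mean_y,sd_y,n_y group summaries.
#' @param pooled use the pooled-variance (Student) statistic; default FALSE
#'   (Welch).
#' @return list with \code{statistic}, \code{df}, \code{p_value},
#'   \code{pooled}, and the group summaries used.
#' @export
#' @examples
#' two_sample_t(mean_x = 51.83, sd_x = 8.73, n_x = 30,
#'              mean_y = 49.70, sd_y = 8.30, n_y = 31, pooled = TRUE)
two_sample_t <- function(x = NULL, y = NULL,
                         mean_x = NULL, sd_x = NULL, n_x = NULL,
                         mean_y = NULL, sd_y = NULL, n_y = NULL,
                         pooled = FALSE) {
  if (!is.null(x)) {
    x <- x[!is.na(x)]
    mean_x <- mean(x); sd_x <- stats::sd(x); n_x <- length(x)
  }
  if (!is.null(y)) {
    y <- y[!is.na(y)]
    mean_y <- mean(y); sd_y <- stats::sd(y); n_y <- length(y)
  }
  if (is.null(mean_x) || is.null(sd_x) || is.null(n_x) ||
      is.null(mean_y) || is.null(sd_y) || is.null(n_y))
    stop("supply raw samples or complete (mean, sd, n) summaries")
  if (n_x < 2 || n_y < 2) stop("each group needs n >= 2")
  if (sd_x < 0 || sd_y < 0) stop("standard deviations must be nonnegative")
  if (sd_x == 0 && sd_y == 0) {
    if (isTRUE(all.equal(mean_x, mean_y)))
      return(list(statistic = 0, df = n_x + n_y - 2, p_value = 1,
                  pooled = pooled, mean_x = mean_x, mean_y = mean_y,
                  n_x = n_x, n_y = n_y))
    stop("zero variance in both groups with unequal means")
  }
  if (pooled) {
    sp2 <- ((n_x - 1) * sd_x^2 + (n_y - 1) * sd_y^2) / (n_x + n_y - 2)
    se <- sqrt(sp2 * (1 / n_x + 1 / n_y))
    df <- n_x + n_y - 2
  } else {
    vx <- sd_x^2 / n_x; vy <- sd_y^2 / n_y
    se <- sqrt(vx + vy)
    df <- (vx + vy)^2 / (vx^2 / (n_x - 1) + vy^2 / (n_y - 1))
  }
  tstat <- (mean_x - mean_y) / se
  list(statistic = tstat, df = df,
       p_value = 2 * stats::pt(-abs(tstat), df), pooled = pooled,
       mean_x = mean_x, mean_y = mean_y, n_x = n_x, n_y = n_y)
}

#' Pearson chi-square test of independence
#'
#' Standard Pearson statistic on an r x c table of counts with
#' df = (r-1)(c-1) and no continuity correction (matching common reporting
#' practice for group comparisons).
#'
#' @param table matrix of nonnegative counts, at least 2 x 2.
#' @return list with \code{statistic}, \code{df}, \code{p_value},
#'   \code{expected}.
#' @export
pearson_chi_square <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2)
    stop("table must be at least 2 x 2")
  if (any(table < 0) || any(table != round(table)))
    stop("table must hold nonnegative integer counts")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero row or column marginal: test undefined")
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value, expected = res$expected)
}

#' Fisher exact test for a 2 x 2 table
#'
#' Two-sided p value by the point-probability convention: the sum of
#' hypergeometric probabilities of all tables with the observed margins
#' that are no more probable than the observed table. Two-sided Fisher
#' definitions differ between software packages; this is the most common
#' one. A table with an all-zero row or column admits only one table with
#' those margins, so p = 1 by convention.
#'
#' @param table 2 x 2 matrix of nonnegative integer counts.
#' @return list with \code{p_value}.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("table must be 2 x 2")
  if (any(table < 0) || any(table != round(table)))
    stop("table must hold nonnegative integer counts")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    return(list(p_value = 1))
  list(p_value = stats::fisher.test(table)$p.value)
}

#' Pearson product-moment correlation with two-sided p value
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance;
#'   the p value comes from the t transform with n - 2 degrees of freedom.
#' @return list with \code{r}, \code{df}, \code{p_value}, \code{n}.
#' @export
pearson_correlation <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  res <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(res$estimate), df = unname(res$parameter),
       p_value = res$p.value, n = length(x))
}

#' Goodness-of-fit test of login days against a uniform week
#'
#' Chi-square goodness-of-fit of the 7 observed weekday counts against the
#' uniform distribution (df = 6); used to test whether logins cluster on
#' particular days, e.g. the day the weekly reminder email is sent.
#'
#' @param counts integer vector of 7 weekday counts (Sunday = 1 ...
#'   Saturday = 7), total >= 1.
#' @return list with \code{statistic}, \code{df}, \code{p_value}.
#' @export
weekday_uniformity_test <- function(counts) {
  if (length(counts) != 7) stop("counts must have length 7 (Sunday-Saturday)")
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (sum(counts) < 1) stop("at least one login is required")
  res <- suppressWarnings(stats::chisq.test(counts, p = rep(1 / 7, 7)))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value)
}
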