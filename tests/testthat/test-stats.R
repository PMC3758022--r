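test_that("wilson_ci agrees with the score-interval oracle (prop.test)", {
  set.seed(3)
  for (i in 1:100) {
    n <- sample(1:500, 1)
    k <- sample(0:n, 1)
    conf <- sample(c(0.9, 0.95, 0.99), 1)
    got <- wilson_ci(k, n, conf)
    ref <- suppressWarnings(stats::prop.test(k, n, conf.level = conf,
                                             correct = FALSE))$conf.int
    expect_equal(got$lower, ref[1], tolerance = 1e-10)
    expect_equal(got$upper, ref[2], tolerance = 1e-10)
    # interval contains both the raw and adjusted point estimates
    expect_true(got$lower <= k / n + 1e-12 && k / n <= got$upper + 1e-12)
    expect_true(got$lower <= got$center && got$center <= got$upper)
  }
})

test_that("wilson_ci boundary identities and symmetry", {
  expect_equal(wilson_ci(0, 10)$lower, 0)
  expect_equal(wilson_ci(10, 10)$upper, 1)
  # success/failure exchange reflects the interval
  for (k in c(0, 3, 35, 70)) {
    a <- wilson_ci(k, 70)
    b <- wilson_ci(70 - k, 70)
    expect_equal(a$lower, 1 - b$upper, tolerance = 1e-12)
    expect_equal(a$upper, 1 - b$lower, tolerance = 1e-12)
  }
  expect_error(wilson_ci(5, 0), "positive")
  expect_error(wilson_ci(8, 7), "0..n")
})

test_that("wilson coverage is near nominal for n = 70", {
  # moderate-size version of the coverage simulation (full run in the
  # acceptance suite)
  set.seed(11)
  for (p in c(0.1, 0.44, 0.9)) {
    k <- stats::rbinom(2000, 70, p)
    bounds <- vapply(0:70, function(x) {
      ci <- wilson_ci(x, 70)
      c(ci$lower, ci$upper)
    }, numeric(2))
    covered <- bounds[1, k + 1] <= p & p <= bounds[2, k + 1]
    expect_gt(mean(covered), 0.91)
    expect_lt(mean(covered), 0.99)
  }
})

test_that("two_sample_t matches t.test on raw samples", {
  set.seed(5)
  for (i in 1:25) {
    x <- rnorm(sample(3:30, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(3:30, 1), mean = runif(1, -1, 1))
    for (pooled in c(TRUE, FALSE)) {
      got <- two_sample_t(x, y, pooled = pooled)
      ref <- stats::t.test(x, y, var.equal = pooled)
      expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-10)
      expect_equal(got$df, unname(ref$parameter), tolerance = 1e-8)
      expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
    }
  }
})

test_that("two_sample_t handles degenerate and summary input", {
  expect_equal(two_sample_t(c(1, 2, 3), c(1, 2, 3), pooled = TRUE)$p_value, 1)
  expect_equal(two_sample_t(c(2, 2, 2), c(2, 2, 2))$p_value, 1)
  expect_error(two_sample_t(c(1), c(1, 2)), "n >= 2")
  # doubling both group sizes at fixed means/SDs strictly decreases p
  p1 <- two_sample_t(mean_x = 10, sd_x = 2, n_x = 20,
                     mean_y = 11, sd_y = 2, n_y = 20, pooled = TRUE)$p_value
  p2 <- two_sample_t(mean_x = 10, sd_x = 2, n_x = 40,
                     mean_y = 11, sd_y = 2, n_y = 40, pooled = TRUE)$p_value
  expect_lt(p2, p1)
})

test_that("pearson_chi_square reproduces the classical statistic", {
  # perfectly proportional table: statistic 0, p 1
  res <- pearson_chi_square(matrix(c(10, 20, 30, 60), 2))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$df, 1)
  res <- pearson_chi_square(matrix(c(10, 18, 20, 13), 2))
  expect_equal(round(res$p_value, 3), 0.053)
  expect_error(pearson_chi_square(matrix(c(0, 0, 5, 3), 2, byrow = TRUE)),
               "marginal")
  expect_error(pearson_chi_square(matrix(1:3, 1)), "2 x 2")
})

test_that("fisher_exact_2x2 equals hypergeometric enumeration", {
  # independent oracle: sum point probabilities <= observed over all tables
  # with the observed margins
  oracle <- function(tab) {
    m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1])
    x_obs <- tab[1, 1]
    xs <- max(0, k - n2):min(k, m)
    probs <- stats::dhyper(xs, m, n2, k)
    sum(probs[probs <= stats::dhyper(x_obs, m, n2, k) * (1 + 1e-7)])
  }
  set.seed(13)
  for (i in 1:200) {
    tab <- matrix(stats::rpois(4, sample(1:8, 1)), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      expect_equal(fisher_exact_2x2(tab)$p_value, 1)
    } else {
      expect_equal(fisher_exact_2x2(tab)$p_value, oracle(tab),
                   tolerance = 1e-7)
    }
  }
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 3, 5), 2, byrow = TRUE))$p_value, 1)
  expect_error(fisher_exact_2x2(matrix(1:6, 2)), "2 x 2")
})

test_that("pearson_correlation matches the closed-form oracle", {
  expect_equal(pearson_correlation(1:10, 2 * (1:10) + 1)$r, 1)
  expect_equal(pearson_correlation(1:10, -(1:10))$r, -1)
  x <- c(1, 2, 3, 4); y <- c(1, 3, 2, 4)
  r_formula <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  got <- pearson_correlation(x, y)
  expect_equal(got$r, r_formula, tolerance = 1e-12)
  t_stat <- r_formula * sqrt(2 / (1 - r_formula^2))
  expect_equal(got$p_value, 2 * stats::pt(-abs(t_stat), 2), tolerance = 1e-10)
  expect_error(pearson_correlation(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_correlation(1:2, 2:3), "at least 3")
})

test_that("weekday uniformity test behaves at the extremes", {
  expect_equal(weekday_uniformity_test(rep(10, 7))$p_value, 1)
  expect_equal(weekday_uniformity_test(rep(10, 7))$df, 6)
  expect_lt(weekday_uniformity_test(c(35, 0, 0, 0, 0, 0, 0))$p_value, 0.001)
  expect_error(weekday_uniformity_test(rep(0, 7)), "at least one")
  expect_error(weekday_uniformity_test(rep(1, 6)), "length 7")
})
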