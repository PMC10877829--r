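test_that("empirical inverse survival follows the clamped-floor convention", {
  expect_equal(empirical_inverse_survival(1:10, 0.3), 7)
  expect_equal(empirical_inverse_survival(1:10, 0), 10)
  expect_equal(empirical_inverse_survival(1:10, 1), 1)
  expect_equal(empirical_inverse_survival(5, 0.7), 5)
  expect_error(empirical_inverse_survival(numeric(0), 0.5), "empty")

  # strict reading drops one rank at integer arguments, and only there
  expect_equal(empirical_inverse_survival(1:10, 0.3, strict = TRUE), 6)
  expect_equal(empirical_inverse_survival(1:10, 0.25, strict = TRUE), 7)
  expect_equal(empirical_inverse_survival(1:10, 1, strict = TRUE), 1)
})

test_that("Mann-Whitney U-statistics match the literal double sums", {
  expect_equal(auc_mw(hand_set()), 0.75)
  expect_equal(auc_mw(score_set(c(5, 6), c(1, 2))), 1)
  expect_equal(auc_mw(score_set(0, 0)), 0)  # strict inequality, tie scores 0

  set.seed(21)
  for (i in 1:15) {
    x <- c(rnorm(12, 1), sample(0:4, 8, TRUE))
    y <- c(rnorm(15), sample(0:4, 8, TRUE))
    s <- score_set(x, y)
    expect_equal(auc_mw(s), auc_mw_loop(x, y), tolerance = 1e-14)
    b <- runif(2, 0.1, 0.9)
    expect_equal(tpauc_trimmed_mw(s, tpauc_bounds(b[1], b[2])),
                 tpauc_trimmed_loop(x, y, b[1], b[2]), tolerance = 1e-14)
  }
})

test_that("trimmed partial U-statistics behave per the trimming rules", {
  s <- hand_set()
  expect_equal(pauc_trimmed_mw(s, "se", 0.5, 1), 0.25)
  set.seed(22)
  for (i in 1:10) {
    s2 <- random_score_set(sample(5:40, 1), sample(5:40, 1))
    expect_equal(pauc_trimmed_mw(s2, "fpr", 0, 1), auc_mw(s2))
    expect_equal(pauc_trimmed_mw(s2, "se", 0, 1), auc_mw(s2))
  }
  expect_error(pauc_trimmed_mw(s, "fpr", 0.9, 0.1), "lo < hi")
})

test_that("trimmed one-way partial areas approach the trapezoid areas at large n", {
  set.seed(23)
  s <- random_score_set(2500, 2500, shift = 1.2)
  r <- build_empirical_roc(s)
  expect_lt(abs(pauc_trimmed_mw(s, "se", 0.4, 0.9) -
                  pauc_sensitivity(r, 0.4, 0.9)), 2e-3)
  expect_lt(abs(pauc_trimmed_mw(s, "fpr", 0.1, 0.6) -
                  pauc_specificity(r, 0.4, 0.9)), 2e-3)
})

test_that("two-way trimmed U-statistic matches hand geometry and reduces to AUC", {
  s <- hand_set()
  expect_equal(tpauc_trimmed_mw(s, tpauc_bounds(0.5, 0.5)), 0.25)
  set.seed(24)
  for (i in 1:10) {
    s2 <- random_score_set(sample(5:40, 1), sample(5:40, 1))
    expect_equal(tpauc_trimmed_mw(s2, tpauc_bounds(0, 0)), auc_mw(s2))
  }
})

test_that("fast estimator reproduces hand geometry, zero condition included", {
  r <- hand_roc()
  est <- tpauc_proposed(r, tpauc_bounds(0.5, 0.4))
  expect_equal(est$value, 0.05)
  expect_false(est$is_zero_by_condition)
  expect_equal(est$components$auc, 0.75)
  expect_equal(est$components$pauc_sp, 0.35)
  expect_equal(est$components$pauc_se, 0.25)

  touch <- tpauc_proposed(r, tpauc_bounds(0.5, 0.5))
  expect_equal(touch$value, 0)

  # curve strictly misses the rectangle: flagged zero
  inv <- build_empirical_roc(score_set(c(-3, -2), c(2, 3)))
  z <- tpauc_proposed(inv, tpauc_bounds(0.6, 0.6))
  expect_true(z$is_zero_by_condition)
  expect_equal(z$value, 0)

  # with both bounds 0 the estimator reduces to the plain AUC
  set.seed(25)
  for (i in 1:10) {
    r2 <- build_empirical_roc(random_score_set(15, 25))
    expect_equal(tpauc_proposed(r2, tpauc_bounds(0, 0))$value,
                 auc_trapezoid(r2), tolerance = 1e-12)
  }
})

test_that("proposed and alternative estimators are numerically identical", {
  r <- hand_roc()
  expect_equal(tpauc_alternative(r, tpauc_bounds(0.5, 0.5))$value, 0)
  perfect <- build_empirical_roc(score_set(c(2, 3), c(0, 1)))
  expect_equal(tpauc_alternative(perfect, tpauc_bounds(0.6, 0.6))$value, 0.16)

  set.seed(26)
  for (i in 1:200) {
    s <- score_set(c(rnorm(sample(3:50, 1), runif(1, 0, 2))),
                   rnorm(sample(3:50, 1)))
    roc <- build_empirical_roc(s)
    b <- tpauc_bounds(runif(1, 0, 0.95), runif(1, 0, 0.95))
    expect_equal(tpauc_proposed(roc, b)$value,
                 tpauc_alternative(roc, b)$value, tolerance = 1e-10)
  }
})

test_that("estimates stay inside the rectangle and grow as bounds relax", {
  set.seed(27)
  for (i in 1:20) {
    roc <- build_empirical_roc(random_score_set(20, 20))
    b_se <- runif(1, 0.1, 0.8)
    b_sp <- runif(1, 0.1, 0.8)
    v <- tpauc_proposed(roc, tpauc_bounds(b_se, b_sp))$value
    expect_gte(v, 0)
    expect_lte(v, (1 - b_se) * (1 - b_sp))
    # relaxing either bound never decreases the estimate
    expect_gte(tpauc_proposed(roc, tpauc_bounds(b_se / 2, b_sp))$value, v)
    expect_gte(tpauc_proposed(roc, tpauc_bounds(b_se, b_sp / 2))$value, v)
  }
  perfect <- build_empirical_roc(score_set(c(2, 3, 4), c(-1, 0, 1)))
  expect_equal(tpauc_proposed(perfect, tpauc_bounds(0.6, 0.6))$value, 0.16)
  expect_equal(tpauc_trimmed_mw(score_set(c(2, 3, 4), c(-1, 0, 1)),
                                tpauc_bounds(0, 0)), 1)
})

test_that("fast and trimmed estimators converge to each other with n", {
  p <- binormal_params(2, 1.5, 0, 1)
  b <- tpauc_bounds(0.6, 0.6)
  gap <- function(n, seed) {
    s <- sample_binormal(p, n / 2, n / 2, seed = seed)
    abs(tpauc_proposed(build_empirical_roc(s), b)$value -
          tpauc_trimmed_mw(s, b))
  }
  gaps_small <- vapply(1:8, function(i) gap(100, 100 + i), numeric(1))
  gaps_large <- vapply(1:8, function(i) gap(5000, 200 + i), numeric(1))
  expect_lt(mean(gaps_large), mean(gaps_small))
  expect_lt(mean(gaps_large), 0.01)
})
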