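test_that("empirical ROC vertices match hand enumeration", {
  r <- hand_roc()
  expect_equal(cbind(r$fpr, r$tpr),
               cbind(c(0, 0, 0.5, 0.5, 1), c(0, 0.5, 0.5, 1, 1)))

  perfect <- build_empirical_roc(score_set(1, 0))
  expect_equal(cbind(perfect$fpr, perfect$tpr),
               cbind(c(0, 0, 1), c(0, 1, 1)))

  # complete cross-class tie: no interior vertex, curve is the chance diagonal
  tie <- build_empirical_roc(score_set(0, 0))
  expect_equal(cbind(tie$fpr, tie$tpr), cbind(c(0, 1), c(0, 1)))
  expect_equal(auc_trapezoid(tie), 0.5)
})

test_that("single-class or non-finite input is rejected", {
  expect_error(score_set(numeric(0), 1), "degenerate")
  expect_error(score_set(c(1, NA), 0), "finite")
  expect_error(split_scores(c(1, 2), c(1, 1)), "degenerate")
  expect_error(split_scores(c(1, 2), c(1, 2)), "labels")
})

test_that("trapezoidal AUC matches hand values and pROC on random data", {
  expect_equal(auc_trapezoid(hand_roc()), 0.75)
  expect_equal(auc_trapezoid(build_empirical_roc(score_set(1, 0))), 1)

  skip_if_not_installed("pROC")
  set.seed(11)
  for (i in 1:10) {
    x <- rnorm(40, 0.8)
    y <- rnorm(60)
    r <- build_empirical_roc(score_set(x, y))
    pr <- pROC::roc(controls = y, cases = x, direction = "<", quiet = TRUE)
    expect_equal(auc_trapezoid(r), as.numeric(pROC::auc(pr)),
                 tolerance = 1e-12)
  }
})

test_that("partial areas match hand geometry and full-range recovers the AUC", {
  r <- hand_roc()
  expect_equal(pauc_specificity(r, 0.75, 1), 0.125)
  expect_equal(pauc_sensitivity(r, 0.5, 1), 0.25)
  expect_equal(pauc_specificity(r, 0, 1), auc_trapezoid(r))
  expect_equal(pauc_sensitivity(r, 0, 1), auc_trapezoid(r))

  perfect <- build_empirical_roc(score_set(1, 0))
  expect_equal(pauc_specificity(perfect, 0.6, 1), 0.4)
  expect_equal(pauc_sensitivity(perfect, 0.6, 1), 0.4)

  expect_error(pauc_specificity(r, 0.8, 0.2), "sp_lo < sp_hi")
  expect_error(pauc_sensitivity(r, 1, 0), "se_lo < se_hi")
})

test_that("partial areas match pROC with interpolated boundaries", {
  skip_if_not_installed("pROC")
  set.seed(12)
  for (i in 1:10) {
    x <- c(rnorm(25, 1), sample(0:3, 10, TRUE))  # include ties
    y <- c(rnorm(35), sample(0:3, 10, TRUE))
    r <- build_empirical_roc(score_set(x, y))
    pr <- pROC::roc(controls = y, cases = x, direction = "<", quiet = TRUE)
    sp <- sort(runif(2, 0.05, 0.95))
    p_sp <- as.numeric(pROC::auc(pr, partial.auc = c(1, sp[1]),
                                 partial.auc.focus = "specificity",
                                 partial.auc.correct = FALSE)) -
      as.numeric(pROC::auc(pr, partial.auc = c(1, sp[2]),
                           partial.auc.focus = "specificity",
                           partial.auc.correct = FALSE))
    expect_equal(pauc_specificity(r, sp[1], sp[2]), p_sp, tolerance = 1e-10)
    se <- sort(runif(2, 0.05, 0.95))
    p_se <- as.numeric(pROC::auc(pr, partial.auc = c(1, se[1]),
                                 partial.auc.focus = "sensitivity",
                                 partial.auc.correct = FALSE)) -
      as.numeric(pROC::auc(pr, partial.auc = c(1, se[2]),
                           partial.auc.focus = "sensitivity",
                           partial.auc.correct = FALSE))
    expect_equal(pauc_sensitivity(r, se[1], se[2]), p_se, tolerance = 1e-10)
  }
})

test_that("partial areas are additive and monotone in the range", {
  set.seed(13)
  for (i in 1:20) {
    r <- build_empirical_roc(random_score_set(sample(5:60, 1),
                                              sample(5:60, 1)))
    cuts <- sort(runif(3))
    expect_equal(pauc_specificity(r, cuts[1], cuts[2]) +
                   pauc_specificity(r, cuts[2], cuts[3]),
                 pauc_specificity(r, cuts[1], cuts[3]), tolerance = 1e-12)
    expect_equal(pauc_sensitivity(r, cuts[1], cuts[2]) +
                   pauc_sensitivity(r, cuts[2], cuts[3]),
                 pauc_sensitivity(r, cuts[1], cuts[3]), tolerance = 1e-12)
    expect_gte(pauc_specificity(r, cuts[1], cuts[3]),
               pauc_specificity(r, cuts[2], cuts[3]))
    expect_gte(pauc_sensitivity(r, cuts[1], cuts[3]),
               pauc_sensitivity(r, cuts[2], cuts[3]))
  }
})

test_that("specificity at a sensitivity bound interpolates and steps correctly", {
  r <- hand_roc()
  expect_equal(specificity_at_sensitivity(r, 0.75), 0.5)
  expect_equal(specificity_at_sensitivity(build_empirical_roc(score_set(1, 0)),
                                          0.75), 1)
  diag_roc <- build_empirical_roc(score_set(0, 0))
  expect_equal(specificity_at_sensitivity(diag_roc, 0.3), 0.7)

  # non-increasing in the sensitivity bound
  set.seed(14)
  for (i in 1:10) {
    r <- build_empirical_roc(random_score_set(20, 30))
    b <- sort(runif(5))
    specs <- vapply(b, function(bi) specificity_at_sensitivity(r, bi),
                    numeric(1))
    expect_true(all(diff(specs) <= 1e-12))
  }
})

test_that("trapezoidal AUC equals the Mann-Whitney statistic on tie-free data", {
  set.seed(15)
  for (i in 1:25) {
    s <- random_score_set(sample(3:50, 1), sample(3:50, 1))
    expect_equal(auc_trapezoid(build_empirical_roc(s)),
                 auc_mw_loop(s$x_scores, s$y_scores), tolerance = 1e-12)
  }
})
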