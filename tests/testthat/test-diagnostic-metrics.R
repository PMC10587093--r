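# ROC/AUC, partial AUC, Wilson intervals, bootstrap CI, cutoff selection.

test_that("roc_curve AUC equals pairwise concordance on known examples", {
  r <- roc_curve(c(.9, .8, .4, .7, .3, .2),
                 rep(c("case", "control"), each = 3))
  expect_equal(r$auc, 8 / 9)

  sep <- roc_curve(c(5, 6, 1, 2), c("case", "case", "control", "control"))
  expect_equal(sep$auc, 1)

  ties <- roc_curve(rep(1, 6), rep(c("case", "control"), 3))
  expect_equal(ties$auc, 0.5)

  expect_error(roc_curve(1:3, rep("case", 3)), "both classes")
})

test_that("roc_curve is monotone with endpoints and matches pROC", {
  set.seed(31)
  sc <- c(rnorm(20, 1), rnorm(30))
  lb <- rep(c("case", "control"), c(20, 30))
  r <- roc_curve(sc, lb)
  expect_true(all(diff(r$points$sensitivity) <= 0))
  expect_true(all(diff(r$points$specificity) >= 0))
  expect_equal(r$points$sensitivity[1], 1)
  expect_equal(r$points$specificity[1], 0)
  expect_equal(tail(r$points$sensitivity, 1), 0)
  expect_equal(tail(r$points$specificity, 1), 1)
  ref <- pROC::roc(lb, sc, levels = c("control", "case"),
                   direction = "<", quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(ref)))
})

test_that("partial_auc integrates the high-specificity band correctly", {
  perfect <- roc_curve(c(5, 6, 1, 2), c("case", "case", "control", "control"))
  expect_equal(partial_auc(perfect, 0.9), 0.1)

  chance <- roc_curve(rep(1, 10), rep(c("case", "control"), 5))
  expect_equal(partial_auc(chance, 0.9), 0.005)

  r <- roc_curve(c(.9, .8, .4, .7, .3, .2),
                 rep(c("case", "control"), each = 3))
  expect_equal(partial_auc(r, 0.9), 0.1 * 2 / 3)

  expect_error(partial_auc(r, 1), "spec_min")
})

test_that("partial_auc at spec_min 0 equals the AUC (property)", {
  set.seed(37)
  for (i in 1:25) {
    n1 <- sample(2:25, 1); n0 <- sample(2:25, 1)
    sc <- round(c(rnorm(n1, 0.5), rnorm(n0)), sample(0:2, 1))  # force ties
    lb <- rep(c("case", "control"), c(n1, n0))
    r <- roc_curve(sc, lb)
    expect_equal(partial_auc(r, 0), r$auc, tolerance = 1e-12)
  }
})

test_that("wilson_interval matches the score-test inversion and reflects", {
  ci <- wilson_interval(27, 30)
  ref <- prop.test(27, 30, correct = FALSE)$conf.int
  expect_equal(ci$lower, ref[1], tolerance = 1e-9)
  expect_equal(ci$upper, ref[2], tolerance = 1e-9)

  expect_equal(wilson_interval(0, 10)$lower, 0)
  expect_equal(wilson_interval(10, 10)$upper, 1)

  # reflection equivariance: CI(n-s) = 1 - rev(CI(s))
  for (s in c(0, 3, 9, 14)) {
    a <- wilson_interval(s, 14)
    b <- wilson_interval(14 - s, 14)
    expect_equal(a$lower, 1 - b$upper, tolerance = 1e-12)
    expect_equal(a$upper, 1 - b$lower, tolerance = 1e-12)
  }
  expect_error(wilson_interval(2, 0), "trials")
  expect_error(wilson_interval(5, 3), "successes")
})

test_that("bootstrap_auc_ci is stratified, deterministic and consistent", {
  sc <- c(5, 6, 7, 1, 2, 3)
  lb <- rep(c("case", "control"), each = 3)
  ci <- bootstrap_auc_ci(sc, lb, n_reps = 100, seed = 1)
  expect_equal(ci$lower, 1)
  expect_equal(ci$upper, 1)

  set.seed(41)
  sc2 <- c(rnorm(40, 1.2), rnorm(60))
  lb2 <- rep(c("case", "control"), c(40, 60))
  a <- bootstrap_auc_ci(sc2, lb2, n_reps = 300, seed = 9)
  b <- bootstrap_auc_ci(sc2, lb2, n_reps = 300, seed = 9)
  expect_identical(a, b)
  expect_lte(a$lower, a$auc)
  expect_gte(a$upper, a$auc)
})

test_that("threshold_for_specificity finds the smallest qualifying cutoff", {
  ctrl <- seq(0, 0.99, by = 0.01)
  cut <- threshold_for_specificity(ctrl, 0.91)
  expect_equal(sum(ctrl >= cut), 9)          # exactly 9 false positives
  expect_equal(mean(ctrl < cut), 0.91)

  # brute-force oracle: no smaller cutoff among the scores qualifies
  smaller <- ctrl[ctrl < cut]
  expect_true(all(vapply(smaller, function(c0)
    mean(ctrl < c0) < 0.91, logical(1))))

  cut1 <- threshold_for_specificity(ctrl, 1)
  expect_gt(cut1, max(ctrl))
  expect_equal(sum(ctrl >= cut1), 0)

  same <- rep(0.4, 20)
  cs <- threshold_for_specificity(same, 0.5)
  expect_true(mean(same < cs) %in% c(0, 1))

  expect_error(threshold_for_specificity(numeric(0), 0.9), "non-empty")
  expect_error(threshold_for_specificity(ctrl, 0), "target_spec")
})

test_that("achieved specificity meets the target on the fitting data", {
  set.seed(43)
  for (i in 1:20) {
    ctrl <- runif(sample(10:200, 1))
    target <- runif(1, 0.5, 1)
    cut <- threshold_for_specificity(ctrl, target)
    expect_gte(mean(ctrl < cut), target)
  }
})

test_that("confusion_summary reproduces counts, strata and Wilson CIs", {
  labels <- rep(c("case", "control"), c(30, 83))
  stages <- c(rep("I", 10), rep("II", 20), rep("none", 83))
  calls <- c(rep(TRUE, 10),                 # all stage I called
             rep(TRUE, 17), rep(FALSE, 3), # 17/20 stage II
             rep(FALSE, 77), rep(TRUE, 6)) # 77/83 controls negative
  out <- confusion_summary(calls, labels, stages)
  get <- function(m) out[out$metric == m, ]
  expect_equal(get("sensitivity")$estimate, 27 / 30)
  expect_equal(round(100 * get("sensitivity")$lower, 1), 74.4)
  expect_equal(round(100 * get("sensitivity")$upper, 1), 96.5)
  expect_equal(get("sensitivity_stage_I")$estimate, 1)
  expect_equal(get("specificity")$estimate, 77 / 83)

  allpos <- confusion_summary(rep(TRUE, 113), labels, stages)
  expect_equal(allpos[allpos$metric == "sensitivity", "estimate"], 1)
  expect_equal(allpos[allpos$metric == "specificity", "estimate"], 0)

  expect_warning(
    confusion_summary(calls, labels, rep(c("II", "none"), c(30, 83))),
    "stratum")
})
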