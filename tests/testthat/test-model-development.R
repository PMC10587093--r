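# CV planning, candidate evaluation, permutation importance, RFE, the
# locked classifier and its application.

test_that("cv plans are stratified, exhaustive and deterministic", {
  lb <- rep(c("case", "control"), each = 10)
  plan <- make_cv_plan(lb, n_reps = 3, n_folds = 5, seed = 1)
  for (f in plan$folds) {
    expect_setequal(unique(f), 1:5)
    for (k in 1:5) {
      expect_equal(sum(f == k & lb == "case"), 2)
      expect_equal(sum(f == k & lb == "control"), 2)
    }
  }

  lb2 <- rep(c("case", "control"), c(105, 545))
  plan2 <- make_cv_plan(lb2, n_reps = 2, n_folds = 5, seed = 4)
  for (f in plan2$folds) for (k in 1:5) {
    expect_equal(sum(f == k & lb2 == "case"), 21)
    expect_equal(sum(f == k & lb2 == "control"), 109)
  }

  expect_identical(make_cv_plan(lb, 3, 5, seed = 1)$folds, plan$folds)
  expect_false(identical(make_cv_plan(lb, 3, 5, seed = 2)$folds, plan$folds))
  expect_error(make_cv_plan(rep(c("case", "control"), c(3, 50)), 1, 5),
               "fewer patients than folds")
})

test_that("uneven class sizes stay within one patient of balance", {
  lb <- rep(c("case", "control"), c(23, 101))
  plan <- make_cv_plan(lb, n_reps = 5, n_folds = 5, seed = 3)
  for (f in plan$folds) {
    cases <- table(f[lb == "case"])
    expect_lte(diff(range(cases)), 1)
    ctrls <- table(f[lb == "control"])
    expect_lte(diff(range(ctrls)), 1)
  }
})

test_that("evaluate_candidate recovers strong synthetic signal leak-free", {
  cfg <- synthetic_config(n_cases_stage1 = 20, n_cases_stage2 = 20,
                          n_controls = 160, n_biomarkers = 12,
                          informative = setNames(rep(2.5, 4), 1:4),
                          correlated_blocks = list(), censor_fraction = 0.05,
                          seed = 17)
  coh <- generate_cohort(cfg)
  plan <- make_cv_plan(coh$patients$label, n_reps = 2, n_folds = 5, seed = 6)
  res <- evaluate_candidate(candidate_spec(), coh, plan, seed = 5)
  expect_equal(nrow(res$per_fold), 10)
  expect_gt(res$summary$mean[res$summary$metric == "auc"], 0.95)

  # determinism: same plan and seed, identical result
  res2 <- evaluate_candidate(candidate_spec(), coh, plan, seed = 5)
  expect_identical(res$per_fold, res2$per_fold)
})

test_that("held-out pAUC on permuted labels stays at chance", {
  coh <- generate_cohort(synthetic_config(seed = 13))
  pf <- permuted_pauc_folds(coh, perm_seeds = 6:8, n_folds = 5)
  se <- sd(pf) / sqrt(length(pf))
  expect_lt(abs(mean(pf) - 0.005), 3 * se)
})

test_that("permutation importance is zero for ignored features", {
  set.seed(51)
  X <- matrix(rnorm(200), 50, 4,
              dimnames = list(NULL, paste0("BM0", 1:4)))
  y <- rep(c("case", "control"), 25)
  model <- list(score = function(Xn) plogis(2 * Xn[, "BM01"]))
  imp <- permutation_importance(model, X, y, cutoff = 0.5,
                                n_shuffles = 5, seed = 2)
  ignored <- imp[imp$feature != "BM01", ]
  expect_true(all(ignored$loss_auc == 0))
  expect_true(all(ignored$loss_pauc == 0))
  expect_true(all(ignored$loss_sensitivity == 0))
})

test_that("shuffling the only informative feature loses all its AUC", {
  set.seed(53)
  n <- 200
  y <- rep(c("case", "control"), each = n / 2)
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("BM01", "BM02")))
  X[y == "case", "BM01"] <- X[y == "case", "BM01"] + 2.5
  model <- list(score = function(Xn) plogis(Xn[, "BM01"]))
  base_auc <- roc_curve(model$score(X), y)$auc
  imp <- permutation_importance(model, X, y, cutoff = 0.5,
                                n_shuffles = 10, seed = 7)
  loss <- imp$loss_auc[imp$feature == "BM01"]
  expect_lt(abs(loss - (base_auc - 0.5)), 0.08)

  imp2 <- permutation_importance(model, X, y, cutoff = 0.5,
                                 n_shuffles = 10, seed = 7)
  expect_identical(imp, imp2)
})

test_that("RFE is the identity at n_target = n and picks one of a dup pair", {
  cfg <- synthetic_config(n_cases_stage1 = 25, n_cases_stage2 = 25,
                          n_controls = 150, n_biomarkers = 7,
                          informative = setNames(rep(2, 3), 1:3),
                          correlated_blocks = list(), censor_fraction = 0,
                          seed = 19)
  coh <- generate_cohort(cfg)
  all7 <- coh$schema$biomarkers
  expect_identical(recursive_feature_elimination(coh, all7, 7), all7)
  expect_error(recursive_feature_elimination(coh, all7, 0), "n_target")
  expect_error(recursive_feature_elimination(coh, all7[1:3], 5),
               "at least n_target")

  # duplicate an informative column: exactly one of the pair survives
  vals <- coh$values
  vals[, "BM07"] <- vals[, "BM01"]
  dup <- tiny_cohort(vals, coh$patients$label,
                     stages = coh$patients$stage)
  # at n_target 3 the collinear pair cannot both survive: each carries
  # half the standardized weight, so one must be eliminated
  sel <- suppressMessages(
    recursive_feature_elimination(dup, dup$schema$biomarkers, 3))
  expect_equal(sum(c("BM01", "BM07") %in% sel), 1)
})

test_that("locked classifier honours cutoff contract and score algebra", {
  cfg <- synthetic_config(n_cases_stage1 = 20, n_cases_stage2 = 25,
                          n_controls = 180, n_biomarkers = 10,
                          informative = setNames(c(2, 1.5, 1.2), 1:3),
                          correlated_blocks = list(), censor_fraction = 0.05,
                          seed = 23)
  coh <- generate_cohort(cfg)
  m <- suppressMessages(
    fit_locked_classifier(coh, c("BM01", "BM02", "BM03")))
  pred <- apply_classifier(m, coh)

  expect_true(all(pred$score > 0 & pred$score < 1))
  is_ctrl <- coh$patients$label == "control"
  expect_gte(mean(pred$score[is_ctrl] < m$cutoff), 0.91)

  # applying to the training set reproduces the stored confusion summary
  redo <- confusion_summary(pred$call == "positive", coh$patients$label,
                            coh$patients$stage)
  expect_equal(redo, m$training)

  # repeated application is bit-identical (no hidden state)
  expect_identical(pred, apply_classifier(m, coh))

  # doubling a concentration moves the linear predictor by exactly coef
  i <- 4
  lp <- function(d) {
    x <- log2(d$values[i, m$features, drop = FALSE])
    m$intercept + sum(x * m$coefficients)
  }
  coh2 <- coh
  coh2$values[i, "BM01"] <- 2 * coh2$values[i, "BM01"]
  expect_equal(lp(coh2) - lp(coh), unname(m$coefficients["BM01"]),
               tolerance = 1e-12)

  # score is monotone in each feature, in the direction of its coefficient
  for (ft in m$features) {
    up <- coh
    up$values[, ft] <- up$values[, ft] * 2
    dscore <- apply_classifier(m, up)$score - pred$score
    if (m$coefficients[ft] > 0) expect_true(all(dscore >= 0))
    else expect_true(all(dscore <= 0))
  }

  expect_error(fit_locked_classifier(coh, c("BM01", "NOPE")), "NOPE")
  bad <- coh; bad$schema <- panel_schema(coh$schema$llod[1:2])
  expect_error(apply_classifier(m, bad), "lacks selected features")
})

test_that("separable training data trigger the ridge path at full sensitivity", {
  n <- 40
  labels <- rep(c("case", "control"), each = n / 2)
  vals <- cbind(c(runif(n / 2, 100, 200), runif(n / 2, 1, 10)),
                rexp(n) + 1)
  coh <- tiny_cohort(vals, labels)
  expect_message(m <- fit_locked_classifier(coh, c("BM01", "BM02")),
                 "ridge")
  expect_true(m$ridge)
  pred <- apply_classifier(m, coh)
  expect_equal(mean(pred$call[labels == "case"] == "positive"), 1)
})

test_that("classifier JSON serialization round-trips", {
  coh <- generate_cohort(synthetic_config(
    n_cases_stage1 = 10, n_cases_stage2 = 10, n_controls = 60,
    n_biomarkers = 5, informative = c("1" = 2),
    correlated_blocks = list(), censor_fraction = 0, seed = 29))
  m <- suppressMessages(fit_locked_classifier(coh, c("BM01", "BM02")))
  path <- withr::local_tempfile(fileext = ".json")
  write_classifier(m, path)
  back <- read_classifier(path)
  expect_equal(back$coefficients, m$coefficients)
  expect_equal(back$intercept, m$intercept)
  expect_equal(back$cutoff, m$cutoff)
  pa <- apply_classifier(back, coh); pb <- apply_classifier(m, coh)
  expect_equal(pa$score, pb$score, tolerance = 1e-12)
  expect_identical(pa$call, pb$call)
})

test_that("alternative algorithm candidates run through the same harness", {
  skip_if_not_installed("ranger")
  cfg <- synthetic_config(n_cases_stage1 = 15, n_cases_stage2 = 15,
                          n_controls = 60, n_biomarkers = 6,
                          informative = setNames(c(2.5, 2), 1:2),
                          correlated_blocks = list(), censor_fraction = 0,
                          seed = 31)
  coh <- generate_cohort(cfg)
  plan <- make_cv_plan(coh$patients$label, n_reps = 1, n_folds = 3, seed = 2)
  rf <- candidate_spec("random_forest", "none",
                       hyperparameters = list(num_trees = 100))
  res <- evaluate_candidate(rf, coh, plan, seed = 3)
  expect_equal(nrow(res$per_fold), 3)
  expect_gt(res$summary$mean[res$summary$metric == "auc"], 0.7)

  expect_error(evaluate_candidate(candidate_spec("neural_net"), coh, plan),
               "stub")
})
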