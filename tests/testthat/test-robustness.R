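# Within-patient CV estimation and the 68/32 perturbation noise model.

test_that("within_patient_cv computes sd/mean per patient, averaged", {
  reps <- array(0, dim = c(2, 1, 2), dimnames = list(NULL, "BM01", NULL))
  reps[1, 1, ] <- c(8, 12)       # sd 2.828, mean 10 -> CV 0.2828
  reps[2, 1, ] <- c(10, 10)      # CV 0
  prof <- within_patient_cv(reps)
  expect_equal(prof$mean_cv, (sd(c(8, 12)) / 10) / 2)
  expect_equal(prof$mean_cv, 0.1414214, tolerance = 1e-6)

  # two patients with CVs 0.1 and 0.3 average to 0.2
  mk <- function(cv, mean0) mean0 * c(1 - cv / sqrt(2), 1 + cv / sqrt(2))
  reps2 <- array(0, dim = c(2, 1, 2), dimnames = list(NULL, "BM01", NULL))
  reps2[1, 1, ] <- mk(0.1, 50)
  reps2[2, 1, ] <- mk(0.3, 5)
  expect_equal(within_patient_cv(reps2)$mean_cv, 0.2, tolerance = 1e-10)

  reps3 <- reps; reps3[2, 1, 2] <- NA
  expect_warning(p3 <- within_patient_cv(reps3), "skipped")
  expect_equal(p3$n_patients, 1)

  expect_error(within_patient_cv(array(1, c(2, 1, 1))), "2 replicates")
  expect_error(within_patient_cv(array(-1, c(2, 1, 2))), "positive")
})

test_that("perturbation with zero CV is a strict no-op", {
  coh <- generate_cohort(synthetic_config(
    n_cases_stage1 = 5, n_cases_stage2 = 5, n_controls = 20,
    n_biomarkers = 4, correlated_blocks = list(),
    informative = c("1" = 2), censor_fraction = 0.1, seed = 37))
  prof <- cv_profile(setNames(rep(0, 4), colnames(coh$values)))
  pert <- perturb_dataset(coh, prof, seed = 5)
  expect_identical(pert$values, coh$values)
  expect_identical(pert$imputed, coh$imputed)
  expect_identical(pert$patients, coh$patients)
})

test_that("perturbation respects the 68/32 band structure", {
  coh <- generate_cohort(synthetic_config(
    n_cases_stage1 = 100, n_cases_stage2 = 100, n_controls = 800,
    n_biomarkers = 100, correlated_blocks = list(),
    informative = setNames(numeric(0), character(0)),
    censor_fraction = 0, seed = 41))
  cv <- 0.1
  prof <- cv_profile(setNames(rep(cv, 100), colnames(coh$values)))
  pert <- perturb_dataset(coh, prof, seed = 8)

  free <- !coh$imputed                     # censored cells stay at LLoD
  ratio <- pert$values[free] / coh$values[free]
  n <- length(ratio)
  expect_gte(n, 1e5)
  # every perturbed value within +/- 2 CV of its original
  expect_true(all(abs(ratio - 1) <= 2 * cv + 1e-12))
  # inner-band fraction ~ Bernoulli(0.68)
  inner <- mean(abs(ratio - 1) <= cv)
  se <- sqrt(0.68 * 0.32 / n)
  expect_lt(abs(inner - 0.68), 3 * se)
  # noise is mean-preserving: mean factor within 3 SEs of 1
  expect_lt(abs(mean(ratio) - 1), 3 * sd(ratio) / sqrt(n))

  # determinism and metadata preservation
  expect_identical(pert$values,
                   perturb_dataset(coh, prof, seed = 8)$values)
  expect_identical(pert$patients, coh$patients)
  expect_identical(pert$imputed, coh$imputed)
  expect_identical(dim(pert$values), dim(coh$values))

  # exact partition mode hits 68% of cells up to rounding
  px <- perturb_dataset(coh, prof, seed = 9, exact_partition = TRUE)
  rx <- px$values[free] / coh$values[free]
  expect_lt(abs(mean(abs(rx - 1) <= cv) - 0.68), 0.005)
})

test_that("perturbation_study summarises and brackets per-set metrics", {
  cfg <- synthetic_config(n_cases_stage1 = 15, n_cases_stage2 = 15,
                          n_controls = 120, n_biomarkers = 8,
                          informative = setNames(c(2, 1.5), 1:2),
                          correlated_blocks = list(), censor_fraction = 0.05,
                          seed = 43)
  coh <- generate_cohort(cfg)
  m <- suppressMessages(fit_locked_classifier(coh, c("BM01", "BM02")))

  zero <- cv_profile(setNames(rep(0, 8), colnames(coh$values)))
  s0 <- perturbation_study(m, coh, zero, n_sets = 3, seed = 1)
  base <- apply_classifier(m, coh)
  base_auc <- roc_curve(base$score, coh$patients$label)$auc
  for (i in 1:3) expect_equal(s0$per_set$auc[i], base_auc)
  expect_true(all(s0$summary$mean == s0$summary$min &
                  s0$summary$min == s0$summary$max))

  prof <- cv_profile(setNames(rep(0.15, 8), colnames(coh$values)))
  s <- perturbation_study(m, coh, prof, n_sets = 10, seed = 2)
  expect_true(all(s$summary$min <= s$summary$mean + 1e-12))
  expect_true(all(s$summary$mean <= s$summary$max + 1e-12))
  for (mt in s$summary$metric) {
    v <- s$per_set[[mt]]
    row <- s$summary[s$summary$metric == mt, ]
    expect_equal(row$min, min(v))
    expect_equal(row$max, max(v))
    expect_equal(row$mean, mean(v))
  }
  expect_identical(s$summary,
                   perturbation_study(m, coh, prof, n_sets = 10,
                                      seed = 2)$summary)
  expect_error(perturbation_study(m, coh, prof, n_sets = 0), "n_sets")
})

test_that("heavier measurement noise degrades mean AUC (paired seeds)", {
  cfg <- synthetic_config(n_cases_stage1 = 20, n_cases_stage2 = 20,
                          n_controls = 160, n_biomarkers = 6,
                          informative = setNames(c(1.5, 1.2), 1:2),
                          correlated_blocks = list(), censor_fraction = 0.05,
                          seed = 47)
  coh <- generate_cohort(cfg)
  m <- suppressMessages(fit_locked_classifier(coh, c("BM01", "BM02")))
  bm <- colnames(coh$values)
  lo <- cv_profile(setNames(rep(0.05, 6), bm))
  hi <- cv_profile(setNames(rep(0.30, 6), bm))
  worse <- vapply(1:20, function(s) {
    a_lo <- perturbation_study(m, coh, lo, n_sets = 1, seed = s)$summary
    a_hi <- perturbation_study(m, coh, hi, n_sets = 1, seed = s)$summary
    a_hi$mean[a_hi$metric == "auc"] - a_lo$mean[a_lo$metric == "auc"]
  }, numeric(1))
  expect_lt(mean(worse), 0)
})
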