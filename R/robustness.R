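# Perturbation robustness: within-patient CV estimation from replicate
# measurements and the 68%/32% measurement-noise perturbation study.

#' Mean within-patient coefficient of variation per biomarker
#'
#' For each patient and biomarker, the CV is the sample standard deviation
#' of that patient's replicate measurements divided by their mean (n-1
#' denominator); the profile value is the unweighted mean of these CVs
#' across patients (the median is reported alongside). Patients with fewer
#' than two replicates are skipped with a warning. Replicate values are
#' expected to have had below-LLoD readings already set to the LLoD.
#'
#' @param replicates a `replicate_measurements` array
#'   (patients x biomarkers x replicates), e.g. from [generate_replicates].
#' @return object of class `cv_profile`: data.frame `biomarker`,
#'   `mean_cv`, `median_cv`, `n_patients`.
#' @export
within_patient_cv <- function(replicates) {
  if (length(dim(replicates)) != 3)
    stop_input("replicates must be a patients x biomarkers x replicates array")
  if (dim(replicates)[3] < 2)
    stop_input("at least 2 replicates per patient are required")
  if (any(replicates <= 0, na.rm = TRUE))
    stop_input("replicate concentrations must be strictly positive")
  p <- dim(replicates)[2]
  bm <- dimnames(replicates)[[2]] %||% sprintf("BM%02d", seq_len(p))
  rows <- lapply(seq_len(p), function(j) {
    cvs <- apply(replicates[, j, , drop = TRUE], 1, function(v) {
      v <- v[!is.na(v)]
      if (length(v) < 2) return(NA_real_)
      sd(v) / mean(v)
    })
    if (anyNA(cvs))
      warning(sprintf("%d patients skipped for %s (<2 replicates)",
                      sum(is.na(cvs)), bm[j]))
    data.frame(biomarker = bm[j],
               mean_cv = mean(cvs, na.rm = TRUE),
               median_cv = median(cvs, na.rm = TRUE),
               n_patients = sum(!is.na(cvs)))
  })
  structure(do.call(rbind, rows), class = c("cv_profile", "data.frame"))
}

#' Build a CV profile directly from known values
#'
#' Convenience constructor for simulation studies where the per-biomarker
#' CVs are specified rather than estimated from replicates.
#'
#' @param cv named numeric vector (biomarker -> CV fraction, >= 0).
#' @return a `cv_profile`.
#' @export
cv_profile <- function(cv) {
  if (is.null(names(cv))) stop_input("cv must be a named vector")
  if (any(cv < 0)) stop_input("CVs must be >= 0")
  structure(data.frame(biomarker = names(cv), mean_cv = as.numeric(cv),
                       median_cv = as.numeric(cv),
                       n_patients = NA_integer_),
            class = c("cv_profile", "data.frame"))
}

#' Perturb a cohort with within-patient measurement noise
#'
#' Emulates re-measuring every sample: each concentration is independently
#' multiplied by a random factor. With probability 0.68 (one standard
#' deviation of a bell curve) the relative change is uniform within
#' +/- CV; with probability 0.32 its magnitude is uniform in [CV, 2 CV]
#' with random sign (the one-to-two standard deviation scenario). The
#' factor has expectation 1, so the noise is mean-preserving. Labels,
#' stages and the imputation mask are untouched. A perturbed value can
#' only become non-positive when CV > 0.5 in the outer band; such values
#' are clamped to the biomarker's LLoD with a warning.
#'
#' @param dataset a [cohort_dataset].
#' @param profile a `cv_profile` covering every biomarker in the dataset
#'   (`mean_cv` column is used).
#' @param seed integer seed; deterministic given it.
#' @param exact_partition if `TRUE`, exactly 68% of cells (rounded) get
#'   inner-band noise instead of an independent Bernoulli(0.68) draw per
#'   cell.
#' @return a perturbed [cohort_dataset].
#' @export
perturb_dataset <- function(dataset, profile, seed = 1,
                            exact_partition = FALSE) {
  stopifnot(inherits(dataset, "cohort_dataset"),
            inherits(profile, "cv_profile"))
  bm <- dataset$schema$biomarkers
  missing_bm <- setdiff(bm, profile$biomarker)
  if (length(missing_bm))
    stop_input("profile lacks biomarkers: %s",
               paste(missing_bm, collapse = ", "))
  cv <- profile$mean_cv[match(bm, profile$biomarker)]

  n <- nrow(dataset$values); p <- ncol(dataset$values)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, "perturb"))

  cvm <- matrix(cv, n, p, byrow = TRUE)
  inner <- if (exact_partition) {
    ncells <- n * p
    k <- round(0.68 * ncells)
    m <- matrix(FALSE, n, p)
    m[sample.int(ncells, k)] <- TRUE
    m
  } else matrix(runif(n * p) < 0.68, n, p)
  u_in <- matrix(runif(n * p, -1, 1), n, p) * cvm
  mag_out <- matrix(runif(n * p, 1, 2), n, p) * cvm
  sgn <- matrix(sample(c(-1, 1), n * p, replace = TRUE), n, p)
  factor <- ifelse(inner, 1 + u_in, 1 + sgn * mag_out)
  vals <- dataset$values * factor

  llod <- matrix(dataset$schema$llod, n, p, byrow = TRUE)
  bad <- vals <= 0
  if (any(bad)) {
    warning(sprintf("%d perturbed values were non-positive; clamped to LLoD",
                    sum(bad)))
    vals[bad] <- llod[bad]
  }
  # keep mask semantics: cells flagged imputed stay exactly at the LLoD
  vals[dataset$imputed] <- llod[dataset$imputed]
  out <- dataset
  out$values[] <- vals
  out
}

#' Perturbation robustness study of a locked classifier
#'
#' Generates `n_sets` independently perturbed copies of the dataset (see
#' [perturb_dataset]), applies the locked classifier with its locked
#' cutoff to each, and summarises AUC, specificity, and overall / stage I
#' / stage II sensitivity as mean, minimum and maximum across the
#' perturbed sets. Per-set metrics are retained for audit.
#'
#' @param model a `trained_classifier`.
#' @param dataset a [cohort_dataset] the model applies to.
#' @param profile a `cv_profile`.
#' @param n_sets number of perturbed in-silico datasets (100 for a full
#'   robustness run).
#' @param seed integer master seed; set `i` uses the derived stream
#'   `"perturb_set/i"`.
#' @return object of class `perturbation_summary`: data.frame `summary`
#'   (metric x mean/min/max) and data.frame `per_set`.
#' @export
perturbation_study <- function(model, dataset, profile, n_sets = 100,
                               seed = 1) {
  if (n_sets < 1) stop_input("n_sets must be >= 1")
  labels <- cohort_labels(dataset)
  stages <- dataset$patients$stage
  is_case <- labels == "case"

  per_set <- lapply(seq_len(n_sets), function(i) {
    pert <- perturb_dataset(dataset, profile,
                            seed = derive_seed(seed,
                              sprintf("perturb_set/%d", i)))
    pred <- apply_classifier(model, pert)
    pos <- pred$call == "positive"
    data.frame(
      set = i,
      auc = auc_fast(pred$score, is_case),
      specificity = mean(!pos[!is_case]),
      sensitivity = mean(pos[is_case]),
      sensitivity_stage_I = mean(pos[is_case & stages == "I"]),
      sensitivity_stage_II = mean(pos[is_case & stages == "II"]))
  })
  per_set <- do.call(rbind, per_set)

  metrics <- c("auc", "specificity", "sensitivity",
               "sensitivity_stage_I", "sensitivity_stage_II")
  summ <- do.call(rbind, lapply(metrics, function(m) {
    v <- per_set[[m]]
    data.frame(metric = m, mean = mean(v), min = min(v), max = max(v))
  }))
  structure(list(summary = summ, per_set = per_set, n_sets = n_sets,
                 seed = seed),
            class = "perturbation_summary")
}

#' @export
print.perturbation_summary <- function(x, ...) {
  cat(sprintf("Perturbation study over %d in-silico datasets:\n", x$n_sets))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
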