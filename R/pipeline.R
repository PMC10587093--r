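# End-to-end pipeline and reporting: filter -> CV candidate selection ->
# RFE -> lock -> validate -> perturb, with reproducible artifacts, plus
# the control-normalised log2 fold-change matrix.

#' Pipeline configuration
#'
#' Bundles everything one development run needs. Exactly one of
#' `synthetic` (a [synthetic_config], the cohort is generated) or
#' `patients_path`/`measurements_path`/`schema` (a real cohort is read)
#' must be supplied.
#'
#' @param synthetic optional [synthetic_config].
#' @param patients_path,measurements_path,schema optional real-data inputs
#'   for [read_cohort].
#' @param validation optional second cohort source: a [synthetic_config]
#'   (an independent cohort is generated from it) or a list
#'   `list(patients_path =, measurements_path =)` read with the training
#'   schema.
#' @param filter a [filter_config] (screening filter).
#' @param lock_filter a [filter_config] used when locking the final model
#'   (conventionally tighter: 0.3 / 0.5).
#' @param candidates named list of [candidate_spec]s to compare by CV.
#' @param n_reps,n_folds cross-validation plan parameters.
#' @param n_target_features signature size retained by RFE.
#' @param target_specificity cutoff anchor.
#' @param n_perturbation_sets perturbed in-silico datasets for the
#'   robustness stage.
#' @param seed master seed; every stage derives a named stream from it.
#' @param out_dir output directory for run artifacts.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(synthetic = NULL,
                            patients_path = NULL, measurements_path = NULL,
                            schema = NULL,
                            validation = NULL,
                            filter = filter_config(0.5, 0.9),
                            lock_filter = filter_config(0.3, 0.5),
                            candidates = list(
                              logistic = candidate_spec("logistic_regression",
                                                        "log2")),
                            n_reps = 100, n_folds = 5,
                            n_target_features = 7,
                            target_specificity = 0.91,
                            n_perturbation_sets = 100,
                            seed = 1,
                            out_dir = tempfile("evpanel_run_")) {
  real <- !is.null(patients_path)
  if (real == !is.null(synthetic))
    stop_input("supply exactly one of 'synthetic' or real cohort paths")
  if (real && (is.null(measurements_path) || is.null(schema)))
    stop_input("real cohort input needs patients_path, measurements_path and schema")
  structure(list(synthetic = synthetic, patients_path = patients_path,
                 measurements_path = measurements_path, schema = schema,
                 validation = validation,
                 filter = filter, lock_filter = lock_filter,
                 candidates = candidates,
                 n_reps = n_reps, n_folds = n_folds,
                 n_target_features = n_target_features,
                 target_specificity = target_specificity,
                 n_perturbation_sets = n_perturbation_sets,
                 seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full classifier-development pipeline
#'
#' Stages, in order: load or generate the cohort; screening filters;
#' repeated stratified CV over the candidate registry ranked by mean
#' held-out partial AUC (with permutation importance for the winner);
#' tighter lock-stage filters and recursive feature elimination to the
#' target signature size; locked logistic fit with specificity-anchored
#' cutoff; optional independent validation; within-patient-CV perturbation
#' robustness study. Every artifact is stamped with the config hash and
#' master seed, and a rerun with the same config is bit-identical.
#'
#' Artifacts written to `config$out_dir`: `manifest.json`,
#' `filter_report.csv`, `cv_report.csv`, `importance.csv`,
#' `locked_model.json`, `cutoff_table.csv`, `fold_change.csv`,
#' `perturbation_summary.csv`, and `validation_report.csv` /
#' `training_report.csv` (confusion summaries with Wilson CIs).
#'
#' @param config a [pipeline_config].
#' @param quiet suppress stage progress messages.
#' @return invisibly, a list with the run's in-memory objects (`cohort`,
#'   `filters`, `cv_results`, `selected_features`, `model`, `validation`,
#'   `perturbation`, `out_dir`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_input("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  # -- cohort ------------------------------------------------------------
  cohort <- stage("load", {
    if (!is.null(config$synthetic)) generate_cohort(config$synthetic)
    else read_cohort(config$patients_path, config$measurements_path,
                     config$schema)
  })
  say("cohort: %d patients x %d biomarkers",
      nrow(cohort$values), ncol(cohort$values))

  # -- screening filters ---------------------------------------------------
  filt <- stage("filter", filter_features(cohort, config$filter))
  say("filter: %d -> %d biomarkers", ncol(cohort$values), length(filt$kept))
  write.csv(filt$report, file.path(config$out_dir, "filter_report.csv"),
            row.names = FALSE)

  # -- candidate CV selection ---------------------------------------------
  labels <- cohort_labels(cohort)
  plan <- make_cv_plan(labels, config$n_reps, config$n_folds,
                       seed = derive_seed(config$seed, "plan"))
  cv_results <- stage("cv_selection", {
    lapply(config$candidates, function(sp)
      evaluate_candidate(sp, cohort, plan,
                         target_specificity = config$target_specificity,
                         seed = derive_seed(config$seed, "candidate")))
  })
  mean_pauc <- vapply(cv_results, function(r)
    r$summary$mean[r$summary$metric == "pauc"], numeric(1))
  best <- names(which.max(mean_pauc))
  say("cv: best candidate '%s' (mean pAUC %.4f)", best, max(mean_pauc))

  cv_report <- do.call(rbind, lapply(names(cv_results), function(nm) {
    s <- cv_results[[nm]]$summary
    data.frame(candidate = nm, metric = s$metric, mean = s$mean, sd = s$sd)
  }))
  write.csv(cv_report, file.path(config$out_dir, "cv_report.csv"),
            row.names = FALSE)

  # permutation importance for the winning candidate
  imp <- stage("importance", {
    r <- evaluate_candidate(config$candidates[[best]], cohort,
                            make_cv_plan(labels, 1, config$n_folds,
                                         seed = derive_seed(config$seed,
                                                            "plan")),
                            target_specificity = config$target_specificity,
                            importance = TRUE,
                            seed = derive_seed(config$seed, "candidate"))
    r$importance
  })
  write.csv(imp, file.path(config$out_dir, "importance.csv"),
            row.names = FALSE)

  # -- lock: tighter filters + RFE + final fit -----------------------------
  model <- stage("lock", {
    lock_kept <- filter_features(cohort, config$lock_filter)$kept
    n_target <- min(config$n_target_features, length(lock_kept))
    feats <- recursive_feature_elimination(cohort, lock_kept, n_target,
                                           seed = derive_seed(config$seed,
                                                              "rfe"))
    fit_locked_classifier(cohort, feats, config$target_specificity)
  })
  say("lock: %d-feature logistic model, cutoff %.4f",
      length(model$features), model$cutoff)
  write_classifier(model, file.path(config$out_dir, "locked_model.json"))
  write.csv(model$training, file.path(config$out_dir, "training_report.csv"),
            row.names = FALSE)

  # -- validation ----------------------------------------------------------
  validation <- NULL
  if (!is.null(config$validation)) {
    validation <- stage("validate", {
      vset <- if (inherits(config$validation, "synthetic_config"))
        generate_cohort(config$validation)
      else read_cohort(config$validation$patients_path,
                       config$validation$measurements_path, cohort$schema)
      pred <- apply_classifier(model, vset)
      summ <- confusion_summary(pred$call == "positive",
                                cohort_labels(vset), vset$patients$stage)
      list(cohort = vset, predictions = pred, summary = summ)
    })
    write.csv(validation$summary,
              file.path(config$out_dir, "validation_report.csv"),
              row.names = FALSE)
  }

  # -- cutoff table (every distinct training score as candidate cutoff) ----
  cutoffs <- stage("cutoff_table", {
    tr_pred <- apply_classifier(model, cohort)
    tab <- cutoff_table(tr_pred$score, labels)
    if (!is.null(validation)) {
      vtab <- cutoff_table(validation$predictions$score,
                           cohort_labels(validation$cohort),
                           cutoffs = tab$cutoff)
      names(vtab) <- c("cutoff", "validation_sensitivity",
                       "validation_specificity")
      tab <- cbind(tab, vtab[, -1, drop = FALSE])
    }
    tab
  })
  write.csv(cutoffs, file.path(config$out_dir, "cutoff_table.csv"),
            row.names = FALSE)

  # -- fold-change matrix ---------------------------------------------------
  fc <- fold_change_matrix(cohort, grouping = "stage")
  write.csv(as.data.frame(fc), file.path(config$out_dir, "fold_change.csv"),
            row.names = TRUE)

  # -- perturbation robustness ---------------------------------------------
  perturbation <- stage("perturb", {
    profile <- if (!is.null(config$synthetic)) {
      reps <- generate_replicates(cohort, config$synthetic)
      within_patient_cv(reps)
    } else {
      # without replicate data, assume a flat conventional 10% assay CV
      cv_profile(setNames(rep(0.10, ncol(cohort$values)),
                          colnames(cohort$values)))
    }
    perturbation_study(model, cohort, profile,
                       n_sets = config$n_perturbation_sets,
                       seed = derive_seed(config$seed, "perturbation"))
  })
  write.csv(perturbation$summary,
            file.path(config$out_dir, "perturbation_summary.csv"),
            row.names = FALSE)

  manifest <- list(config_hash = config_hash(unclass(config)),
                   master_seed = config$seed,
                   streams = list(plan = derive_seed(config$seed, "plan"),
                                  candidate = derive_seed(config$seed,
                                                          "candidate"),
                                  rfe = derive_seed(config$seed, "rfe"),
                                  perturbation = derive_seed(config$seed,
                                                             "perturbation")),
                   n_patients = nrow(cohort$values),
                   n_biomarkers = ncol(cohort$values),
                   n_kept_screening = length(filt$kept),
                   best_candidate = best,
                   selected_features = model$features)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  say("run complete: %s", config$out_dir)

  invisible(list(cohort = cohort, filters = filt, cv_results = cv_results,
                 importance = imp, selected_features = model$features,
                 model = model, validation = validation,
                 cutoff_table = cutoffs, fold_change = fc,
                 perturbation = perturbation, out_dir = config$out_dir))
}

# sens/spec at every candidate cutoff (default: each distinct score)
cutoff_table <- function(scores, labels, cutoffs = NULL) {
  cutoffs <- cutoffs %||% sort(unique(scores))
  is_case <- labels == "case"
  data.frame(cutoff = cutoffs,
             sensitivity = vapply(cutoffs, function(c0)
               mean(scores[is_case] >= c0), numeric(1)),
             specificity = vapply(cutoffs, function(c0)
               mean(scores[!is_case] < c0), numeric(1)))
}

#' Control-normalised log2 fold-change matrix
#'
#' For each group (case/control, or control/stage I/stage II) and
#' biomarker, computes `log2(group mean concentration / control mean
#' concentration)` — the heatmap-ready summary of how each marker shifts
#' relative to controls. The control row is identically zero by
#' construction.
#'
#' @param dataset a [cohort_dataset].
#' @param grouping `"label"` (case vs control) or `"stage"` (control,
#'   stage I, stage II).
#' @return numeric matrix groups x biomarkers, class `fold_change_matrix`.
#' @export
fold_change_matrix <- function(dataset, grouping = c("label", "stage")) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  grouping <- match.arg(grouping)
  g <- if (grouping == "label") cohort_labels(dataset)
       else ifelse(dataset$patients$stage == "none", "control",
                   paste("stage", dataset$patients$stage))
  if (!any(g == "control")) stop_input("control group is empty")
  groups <- c("control", setdiff(sort(unique(g)), "control"))
  ctrl_mean <- colMeans(dataset$values[g == "control", , drop = FALSE])
  out <- do.call(rbind, lapply(groups, function(gr)
    log2(colMeans(dataset$values[g == gr, , drop = FALSE]) / ctrl_mean)))
  dimnames(out) <- list(groups, colnames(dataset$values))
  structure(out, class = c("fold_change_matrix", class(out)))
}
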