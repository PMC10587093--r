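# Classifier development engine: repeated stratified cross-validation over
# candidate pipelines scored by partial AUC, permutation feature
# importance, recursive feature elimination, and the locked logistic
# classifier with a specificity-anchored score cutoff.

#' Candidate pipeline specification
#'
#' A candidate couples a learning algorithm with a feature transform, a
#' hyperparameter map, and the filter configuration applied inside each
#' cross-validation fold. The logistic-regression path is the fully
#' supported one; random forest, gradient boosted trees and SVM candidates
#' dispatch to ranger, xgboost and e1071 when installed. A neural-network
#' entry exists in the registry but is a stub (not implemented).
#'
#' @param algorithm one of `"logistic_regression"`, `"random_forest"`,
#'   `"gradient_boosted_trees"`, `"svm"`, `"neural_net"`.
#' @param transform one of `"log2"`, `"standardize"`, `"log2_standardize"`,
#'   `"none"`.
#' @param hyperparameters named list, algorithm-specific.
#' @param filter_config a [filter_config] applied within folds.
#' @return a `candidate_spec` list.
#' @export
candidate_spec <- function(algorithm = "logistic_regression",
                           transform = "log2",
                           hyperparameters = list(),
                           filter_config = evpanel::filter_config()) {
  algorithm <- match.arg(algorithm,
    c("logistic_regression", "random_forest", "gradient_boosted_trees",
      "svm", "neural_net"))
  transform <- match.arg(transform,
    c("log2", "standardize", "log2_standardize", "none"))
  structure(list(algorithm = algorithm, transform = transform,
                 hyperparameters = hyperparameters,
                 filter_config = filter_config),
            class = "candidate_spec")
}

#' Repeated stratified cross-validation plan
#'
#' Builds fold assignments for `n_reps` repetitions of `n_folds`-fold
#' cross-validation, stratified by the binary case/control label: within
#' each repetition every patient appears in exactly one validation fold
#' and every fold's case count is within one patient of perfect balance.
#'
#' @param labels `"case"`/`"control"` vector.
#' @param n_reps repetitions (100 for a full development run).
#' @param n_folds folds per repetition.
#' @param seed integer seed; the plan is deterministic given it.
#' @return object of class `cv_plan`: list with `folds` (list of integer
#'   vectors, one per repetition, fold id per patient), `n_reps`,
#'   `n_folds`, `seed`.
#' @export
make_cv_plan <- function(labels, n_reps = 100, n_folds = 5, seed = 1) {
  if (!all(labels %in% c("case", "control")))
    stop_input("labels must be 'case' or 'control'")
  n <- length(labels)
  for (cl in c("case", "control"))
    if (sum(labels == cl) < n_folds)
      stop_input("class '%s' has fewer patients than folds", cl)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, "cv_plan"))
  folds <- lapply(seq_len(n_reps), function(r) {
    f <- integer(n)
    for (cl in c("case", "control")) {
      idx <- which(labels == cl)
      f[sample(idx)] <- rep_len(seq_len(n_folds), length(idx))
    }
    f
  })
  structure(list(folds = folds, n_reps = n_reps, n_folds = n_folds,
                 seed = seed),
            class = "cv_plan")
}

# ---- internal: transforms and algorithm registry ------------------------

fit_transform <- function(transform, X_train) {
  st <- list(transform = transform)
  if (transform %in% c("log2", "log2_standardize")) X_train <- log2(X_train)
  if (transform %in% c("standardize", "log2_standardize")) {
    st$center <- colMeans(X_train)
    st$scale <- apply(X_train, 2, sd)
    st$scale[st$scale == 0] <- 1
  }
  st
}

apply_transform <- function(st, X) {
  if (st$transform %in% c("log2", "log2_standardize")) X <- log2(X)
  if (st$transform %in% c("standardize", "log2_standardize"))
    X <- sweep(sweep(X, 2, st$center), 2, st$scale, "/")
  X
}

# Fit one algorithm on transformed features; returns an object with a
# score() closure mapping a transformed matrix to scores in (0, 1).
fit_algorithm <- function(spec, X, y, seed = 1) {
  hp <- spec$hyperparameters
  switch(spec$algorithm,
    logistic_regression = fit_logistic(X, y, lambda = hp$lambda),
    random_forest = {
      need_pkg("ranger")
      df <- data.frame(X, .y = factor(y, levels = c("control", "case")))
      fit <- ranger::ranger(.y ~ ., data = df, probability = TRUE,
                            num.trees = hp$num_trees %||% 500,
                            seed = seed)
      list(type = "random_forest",
           score = function(Xn) predict(
             fit, data.frame(Xn))$predictions[, "case"])
    },
    gradient_boosted_trees = {
      need_pkg("xgboost")
      yv <- as.numeric(y == "case")
      fit <- xgboost::xgboost(data = as.matrix(X), label = yv,
                              nrounds = hp$nrounds %||% 50,
                              max_depth = hp$max_depth %||% 3,
                              eta = hp$eta %||% 0.3,
                              objective = "binary:logistic",
                              verbose = 0, nthread = 1)
      list(type = "gradient_boosted_trees",
           score = function(Xn) predict(fit, as.matrix(Xn)))
    },
    svm = {
      need_pkg("e1071")
      yf <- factor(y, levels = c("control", "case"))
      fit <- e1071::svm(as.matrix(X), yf, probability = TRUE,
                        kernel = hp$kernel %||% "radial",
                        cost = hp$cost %||% 1)
      list(type = "svm",
           score = function(Xn) attr(
             predict(fit, as.matrix(Xn), probability = TRUE),
             "probabilities")[, "case"])
    },
    neural_net = stop_input(
      "neural_net is a registry stub and not implemented"))
}

need_pkg <- function(pkg) {
  if (!requireNamespace(pkg, quietly = TRUE))
    stop_input("package '%s' is required for this candidate", pkg)
}

# Logistic fit with ridge (glmnet, alpha = 0) fallback when glm reports
# (quasi-)separation, i.e. fitted probabilities numerically 0 or 1.
fit_logistic <- function(X, y, lambda = NULL) {
  yv <- as.numeric(y == "case")
  df <- data.frame(X)
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(yv ~ ., data = df, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (sep || !is.null(lambda) || anyNA(coef(fit))) {
    lam <- lambda %||% 1e-3
    gfit <- glmnet::glmnet(as.matrix(X), yv, family = "binomial",
                           alpha = 0, lambda = lam,
                           standardize = TRUE)
    b <- as.numeric(coef(gfit))
    coefs <- setNames(b[-1], colnames(X))
    intercept <- b[1]
    ridge <- TRUE
  } else {
    b <- coef(fit)
    intercept <- unname(b[1])
    coefs <- setNames(unname(b[-1]), colnames(X))
    ridge <- FALSE
  }
  list(type = "logistic_regression", intercept = intercept,
       coefficients = coefs, ridge = ridge,
       score = function(Xn)
         as.numeric(plogis(intercept + as.matrix(Xn) %*% coefs)))
}

# ---- cross-validated candidate evaluation -------------------------------

#' Evaluate a candidate pipeline by repeated stratified cross-validation
#'
#' For every fold of every repetition, the candidate's filters
#' (imputation-rate, then correlation/KS) and transform are fitted on the
#' training portion only and applied unchanged to the held-out fold — no
#' information flows from a validation fold into the model that scores it.
#' Held-out predictions yield partial AUC (specificity 90-100% band), AUC,
#' and sensitivity at the fold-level cutoff achieving the target
#' specificity on the training portion's controls. Metrics are averaged
#' over all folds of all repetitions.
#'
#' @param spec a [candidate_spec].
#' @param dataset a [cohort_dataset].
#' @param plan a [cv_plan] for the dataset's patients.
#' @param target_specificity specificity anchor for the fold-level
#'   sensitivity metric.
#' @param importance if `TRUE`, also accumulate permutation feature
#'   importance (10 shuffles per feature per fold) across folds.
#' @param seed seed for model fitting and permutation shuffles.
#' @return object of class `cv_result`: `summary` (mean/sd per metric),
#'   `per_fold` data.frame, `failed_folds` count, and optionally
#'   `importance` (data.frame feature x mean metric loss).
#' @export
evaluate_candidate <- function(spec, dataset, plan,
                               target_specificity = 0.91,
                               importance = FALSE, seed = 1) {
  stopifnot(inherits(spec, "candidate_spec"),
            inherits(dataset, "cohort_dataset"),
            inherits(plan, "cv_plan"))
  labels <- cohort_labels(dataset)
  if (length(labels) != length(plan$folds[[1]]))
    stop_input("plan does not match dataset size")

  rows <- list()
  imp_acc <- list()
  failed <- 0L
  fit_seed <- derive_seed(seed, "fit")

  for (r in seq_len(plan$n_reps)) {
    f <- plan$folds[[r]]
    for (k in seq_len(plan$n_folds)) {
      hold <- f == k
      sub <- subset_cohort(dataset, !hold)
      feats <- tryCatch({
        kept1 <- imputation_rate_filter(sub, spec$filter_config)
        if (length(kept1) >= 2)
          correlation_ks_filter(sub, kept1,
                                config = spec$filter_config)$kept
        else kept1
      }, error = function(e) character())
      if (!length(feats)) { failed <- failed + 1L; next }

      Xtr <- dataset$values[!hold, feats, drop = FALSE]
      Xva <- dataset$values[hold, feats, drop = FALSE]
      st <- fit_transform(spec$transform, Xtr)
      Xtr_t <- apply_transform(st, Xtr)
      Xva_t <- apply_transform(st, Xva)
      ytr <- labels[!hold]; yva <- labels[hold]
      if (length(unique(yva)) < 2 || length(unique(ytr)) < 2) {
        failed <- failed + 1L; next
      }

      model <- fit_algorithm(spec, Xtr_t, ytr, seed = fit_seed)
      cut_k <- threshold_for_specificity(model$score(Xtr_t)[ytr == "control"],
                                         target_specificity)
      sc <- model$score(Xva_t)
      m <- fold_metrics(sc, yva, cut_k)
      rows[[length(rows) + 1L]] <-
        data.frame(rep = r, fold = k, n_features = length(feats),
                   pauc = m$pauc, auc = m$auc, sensitivity = m$sens)

      if (importance) {
        imp <- permutation_importance(model, Xva_t, yva,
                                      cutoff = cut_k, n_shuffles = 10,
                                      seed = derive_seed(seed,
                                        sprintf("shuffle/%d/%d", r, k)))
        imp_acc[[length(imp_acc) + 1L]] <- imp
      }
    }
  }
  if (!length(rows)) stop_input("all folds failed for this candidate")
  per_fold <- do.call(rbind, rows)
  summ <- data.frame(
    metric = c("pauc", "auc", "sensitivity"),
    mean = c(mean(per_fold$pauc), mean(per_fold$auc),
             mean(per_fold$sensitivity)),
    sd = c(sd(per_fold$pauc), sd(per_fold$auc), sd(per_fold$sensitivity)))
  out <- list(spec = spec, summary = summ, per_fold = per_fold,
              failed_folds = failed)
  if (importance && length(imp_acc))
    out$importance <- aggregate_importance(imp_acc)
  structure(out, class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("CV result (%s, %s): %d folds%s\n", x$spec$algorithm,
              x$spec$transform, nrow(x$per_fold),
              if (x$failed_folds) sprintf(" (%d failed)", x$failed_folds)
              else ""))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

fold_metrics <- function(scores, labels, cutoff) {
  roc <- roc_curve(scores, labels)
  list(pauc = partial_auc(roc, 0.90), auc = roc$auc,
       sens = mean(scores[labels == "case"] >= cutoff))
}

subset_cohort <- function(dataset, keep) {
  cohort_dataset(dataset$schema,
                 dataset$patients[keep, , drop = FALSE],
                 dataset$values[keep, , drop = FALSE],
                 dataset$imputed[keep, , drop = FALSE])
}

#' Permutation feature importance on a validation fold
#'
#' With the model fixed, each feature's column in the validation matrix is
#' shuffled `n_shuffles` times across observations and the mean loss from
#' the baseline value of each metric (partial AUC, AUC, sensitivity at the
#' supplied cutoff) is recorded. Larger losses mean the model leans on the
#' feature more heavily; a feature the model ignores has zero expected
#' loss.
#'
#' @param model object returned by the internal algorithm registry (has a
#'   `score` function), e.g. from [fit_locked_classifier]'s `fit` element.
#' @param X_val transformed validation feature matrix.
#' @param y_val labels for the validation fold.
#' @param cutoff score cutoff used for the sensitivity metric.
#' @param n_shuffles shuffles per feature.
#' @param seed integer seed.
#' @return data.frame: `feature`, `loss_pauc`, `loss_auc`,
#'   `loss_sensitivity`, `n_shuffles`.
#' @export
permutation_importance <- function(model, X_val, y_val, cutoff,
                                   n_shuffles = 10, seed = 1) {
  X_val <- as.matrix(X_val)
  if (nrow(X_val) < 2) stop_input("validation fold too small")
  base_sc <- model$score(X_val)
  base <- fold_metrics(base_sc, y_val, cutoff)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  res <- lapply(colnames(X_val), function(ft) {
    losses <- matrix(0, n_shuffles, 3)
    for (s in seq_len(n_shuffles)) {
      Xp <- X_val
      Xp[, ft] <- sample(Xp[, ft])
      m <- fold_metrics(model$score(Xp), y_val, cutoff)
      losses[s, ] <- c(base$pauc - m$pauc, base$auc - m$auc,
                       base$sens - m$sens)
    }
    data.frame(feature = ft,
               loss_pauc = mean(losses[, 1]),
               loss_auc = mean(losses[, 2]),
               loss_sensitivity = mean(losses[, 3]),
               n_shuffles = n_shuffles)
  })
  do.call(rbind, res)
}

aggregate_importance <- function(tables) {
  all_tab <- do.call(rbind, tables)
  agg <- aggregate(all_tab[c("loss_pauc", "loss_auc", "loss_sensitivity")],
                   by = list(feature = all_tab$feature), FUN = mean)
  agg$n_folds <- as.vector(table(all_tab$feature)[agg$feature])
  agg[order(-agg$loss_pauc), ]
}

#' Recursive feature elimination for the logistic signature
#'
#' Repeatedly fits a logistic model on log2-transformed, internally
#' standardized features and drops the feature with the smallest absolute
#' standardized coefficient, until `n_target` features remain.
#' Standardization is used for ranking only; it makes coefficient
#' magnitudes comparable across markers with different dynamic ranges.
#'
#' @param dataset a [cohort_dataset].
#' @param candidates character vector of candidate features
#'   (length >= `n_target`).
#' @param n_target number of features to retain (7 for a compact panel).
#' @param seed seed for the ridge fallback path.
#' @return character vector of selected features (schema order).
#' @export
recursive_feature_elimination <- function(dataset, candidates, n_target = 7,
                                          seed = 1) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  if (n_target < 1) stop_input("n_target must be >= 1")
  if (length(candidates) < n_target)
    stop_input("need at least n_target candidate features")
  labels <- cohort_labels(dataset)
  current <- candidates
  while (length(current) > n_target) {
    X <- log2(dataset$values[, current, drop = FALSE])
    X <- scale(X)
    X[, attr(X, "scaled:scale") == 0] <- 0
    fit <- fit_logistic(as.data.frame(X), labels)
    drop_ft <- names(which.min(abs(fit$coefficients)))
    current <- setdiff(current, drop_ft)
  }
  dataset$schema$biomarkers[dataset$schema$biomarkers %in% current]
}

#' Fit and lock the final logistic classifier
#'
#' Fits logistic regression on the log2-transformed concentrations of the
#' selected features (post-imputation values are >= LLoD > 0, so log2 is
#' always defined), then locks the score cutoff at the smallest value
#' achieving the target specificity on the training controls. The sigmoid
#' output in (0, 1) is the diagnostic score; a sample is called positive
#' when its score is at or above the locked cutoff. If the training data
#' are (quasi-)separated the fit falls back to a lightly ridge-penalised
#' logistic model and records that in the object.
#'
#' @param dataset the training [cohort_dataset].
#' @param features character vector of selected biomarkers.
#' @param target_specificity specificity anchor for the cutoff (default
#'   0.91, the conventional choice for a high-risk surveillance test).
#' @return object of class `trained_classifier` with elements `features`,
#'   `transform` (`"log2"`), `coefficients`, `intercept`, `cutoff`,
#'   `target_specificity`, `ridge`, `training` (achieved training
#'   confusion summary).
#' @export
fit_locked_classifier <- function(dataset, features,
                                  target_specificity = 0.91) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  missing_ft <- setdiff(features, dataset$schema$biomarkers)
  if (length(missing_ft))
    stop_input("features not in dataset: %s", paste(missing_ft, collapse = ", "))
  labels <- cohort_labels(dataset)
  if (length(unique(labels)) < 2) stop_input("both classes required")

  X <- log2(dataset$values[, features, drop = FALSE])
  fit <- fit_logistic(as.data.frame(X), labels)
  if (fit$ridge)
    message("quasi-separation detected; ridge-penalised logistic fit used")
  scores <- fit$score(X)
  cutoff <- threshold_for_specificity(scores[labels == "control"],
                                      target_specificity)
  model <- structure(list(features = features, transform = "log2",
                          coefficients = fit$coefficients,
                          intercept = fit$intercept,
                          cutoff = cutoff,
                          target_specificity = target_specificity,
                          ridge = fit$ridge),
                     class = "trained_classifier")
  model$training <- confusion_summary(scores >= cutoff, labels,
                                      dataset$patients$stage)
  model
}

#' @export
print.trained_classifier <- function(x, ...) {
  cat(sprintf("Locked logistic classifier: %d log2 features, cutoff %.4f (target specificity %.0f%%)%s\n",
              length(x$features), x$cutoff, 100 * x$target_specificity,
              if (x$ridge) " [ridge]" else ""))
  print(data.frame(feature = c("(intercept)", x$features),
                   coefficient = c(x$intercept, unname(x$coefficients))),
        row.names = FALSE)
  invisible(x)
}

#' Apply a locked classifier to a cohort
#'
#' Pure prediction: `score = sigmoid(intercept + sum coef * log2(conc))`,
#' positive call iff `score >= cutoff`. Nothing is refit on the new data.
#'
#' @param model a `trained_classifier`.
#' @param dataset a [cohort_dataset] containing all selected features.
#' @return data.frame: `patient_id`, `score`, `call`
#'   (`"positive"`/`"negative"`).
#' @export
apply_classifier <- function(model, dataset) {
  stopifnot(inherits(model, "trained_classifier"),
            inherits(dataset, "cohort_dataset"))
  missing_ft <- setdiff(model$features, dataset$schema$biomarkers)
  if (length(missing_ft))
    stop_input("dataset lacks selected features: %s",
               paste(missing_ft, collapse = ", "))
  X <- log2(dataset$values[, model$features, drop = FALSE])
  score <- as.numeric(plogis(model$intercept + X %*% model$coefficients))
  data.frame(patient_id = dataset$patients$patient_id,
             score = score,
             call = ifelse(score >= model$cutoff, "positive", "negative"),
             stringsAsFactors = FALSE)
}

#' Serialize / deserialize a locked classifier as JSON
#'
#' @param model a `trained_classifier`.
#' @param path file path.
#' @return `read_classifier` returns the model; `write_classifier` the
#'   path, invisibly.
#' @export
write_classifier <- function(model, path) {
  stopifnot(inherits(model, "trained_classifier"))
  obj <- list(features = model$features, transform = model$transform,
              coefficients = as.list(model$coefficients),
              intercept = model$intercept, cutoff = model$cutoff,
              target_specificity = model$target_specificity,
              ridge = model$ridge)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(features = obj$features, transform = obj$transform,
                 coefficients = unlist(obj$coefficients),
                 intercept = obj$intercept, cutoff = obj$cutoff,
                 target_specificity = obj$target_specificity,
                 ridge = obj$ridge),
            class = "trained_classifier")
}
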