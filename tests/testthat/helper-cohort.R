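# Fixture builders shared across tests. Everything is generated in code;
# no data files.

# Minimal cohort from an explicit value matrix (columns BM01..).
tiny_cohort <- function(values, labels, imputed = NULL, llod = NULL,
                        stages = NULL) {
  p <- ncol(values)
  colnames(values) <- sprintf("BM%02d", seq_len(p))
  llod <- llod %||% apply(values, 2, function(v) min(v) / 2)
  names(llod) <- colnames(values)
  sch <- panel_schema(llod)
  if (is.null(stages)) {  # alternate stages I/II over the cases
    stages <- rep("none", length(labels))
    ci <- which(labels == "case")
    stages[ci] <- rep(c("I", "II"), length.out = length(ci))
  }
  pats <- data.frame(patient_id = sprintf("P%03d", seq_len(nrow(values))),
                     label = labels, stage = stages,
                     noted_condition = "none", stringsAsFactors = FALSE)
  cohort_dataset(sch, pats, values, imputed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Balanced null cohort with no informative markers.
null_config <- function(n_per_class = 300, p = 52, seed = 1) {
  synthetic_config(n_cases_stage1 = ceiling(n_per_class / 2),
                   n_cases_stage2 = floor(n_per_class / 2),
                   n_controls = n_per_class,
                   n_biomarkers = p,
                   informative = setNames(numeric(0), character(0)),
                   correlated_blocks = list(),
                   censor_fraction = 0,
                   seed = seed)
}

# Permute case/control labels of a cohort, keeping metadata consistent
# (stage must remain tied to the case label).
permute_labels <- function(cohort, seed = 1) {
  set.seed(seed)
  perm <- sample(cohort$patients$label)
  cohort$patients$label <- perm
  cohort$patients$stage <- ifelse(perm == "case", "I", "none")
  cohort
}

# Held-out fold pAUCs of the full selection pipeline under the label-
# permutation null. Each permutation gets its own 1 x n_folds CV pass;
# averaging over several independent permutations removes the chance
# label-marker association any single permutation retains.
permuted_pauc_folds <- function(coh, perm_seeds, n_folds = 5) {
  unlist(lapply(perm_seeds, function(ps) {
    perm <- permute_labels(coh, seed = ps)
    plan <- make_cv_plan(perm$patients$label, n_reps = 1,
                         n_folds = n_folds, seed = ps + 1000)
    evaluate_candidate(candidate_spec(), perm, plan,
                       seed = ps)$per_fold$pauc
  }))
}

# Brute-force concordance AUC: loop over all case-control pairs,
# ties count one half. Independent oracle for the rank-based estimator.
brute_force_auc <- function(scores, labels) {
  cs <- scores[labels == "case"]
  ct <- scores[labels == "control"]
  tot <- 0
  for (a in cs) for (b in ct)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(cs) * length(ct))
}

# Brute-force two-sample KS statistic over the pooled points.
brute_force_ks_d <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(vapply(pts, function(t)
    abs(mean(x <= t) - mean(y <= t)), numeric(1)))
}
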