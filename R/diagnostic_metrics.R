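# ROC analysis, partial AUC over the high-specificity band, bootstrap AUC
# confidence intervals, Wilson score intervals, and specificity-anchored
# threshold selection.

#' Empirical ROC curve
#'
#' Operating points are generated by the rule "score >= cutoff is a
#' positive call", sweeping the cutoff over every distinct score (tied
#' scores collapse to a single operating point, the standard staircase).
#' The AUC is the concordance probability (probability a random case
#' outscores a random control, ties counting one half), computed by the
#' rank / Mann-Whitney identity.
#'
#' @param scores numeric score per patient (higher = more case-like).
#' @param labels `"case"`/`"control"` per patient.
#' @return object of class `roc_curve`: data.frame `points` with columns
#'   `threshold`, `sensitivity`, `specificity` (sorted by threshold), plus
#'   `auc`, `n_cases`, `n_controls`.
#' @export
#' @examples
#' roc_curve(c(.9, .8, .4, .7, .3, .2),
#'           c("case", "case", "case", "control", "control", "control"))
roc_curve <- function(scores, labels) {
  check_scores_labels(scores, labels)
  is_case <- labels == "case"
  n1 <- sum(is_case); n0 <- sum(!is_case)

  thr <- sort(unique(scores))
  # counts of scores >= each threshold, per class
  sens <- vapply(thr, function(t) sum(scores[is_case] >= t), numeric(1)) / n1
  spec <- vapply(thr, function(t) sum(scores[!is_case] < t), numeric(1)) / n0
  pts <- data.frame(threshold = c(thr, Inf),
                    sensitivity = c(sens, 0),
                    specificity = c(spec, 1))

  ranks <- rank(scores)  # average ranks -> ties count 1/2
  auc <- (sum(ranks[is_case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  structure(list(points = pts, auc = auc, n_cases = n1, n_controls = n0),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d cases vs %d controls, AUC = %.3f (pAUC[spec>=0.9] = %.4f)\n",
              x$n_cases, x$n_controls, x$auc, partial_auc(x)))
  invisible(x)
}

#' Partial AUC over the high-specificity band
#'
#' Unnormalised trapezoidal area under the ROC curve restricted to false
#' positive rates in `[0, 1 - spec_min]`, with linear interpolation at the
#' band edge. With the default `spec_min = 0.90` the maximum attainable
#' value is 0.10 (perfect classifier) and the chance level is 0.005. With
#' `spec_min = 0` it equals the full AUC.
#'
#' @param roc a [roc_curve].
#' @param spec_min lower edge of the specificity band, in `[0, 1)`.
#' @return partial AUC in `[0, 1 - spec_min]`.
#' @export
partial_auc <- function(roc, spec_min = 0.90) {
  stopifnot(inherits(roc, "roc_curve"))
  if (spec_min < 0 || spec_min >= 1)
    stop_input("spec_min must lie in [0, 1)")
  fpr <- 1 - roc$points$specificity
  tpr <- roc$points$sensitivity
  ord <- order(fpr, tpr)
  fpr <- c(fpr[ord], 1); tpr <- c(tpr[ord], 1)
  # ensure the curve starts at (0, tpr at highest threshold) -> prepend (0,0)
  fpr <- c(0, fpr); tpr <- c(0, tpr)
  band <- 1 - spec_min
  trapezoid_area(fpr, tpr, band)
}

# Area under the piecewise-linear curve through ordered points (x, y) over
# [0, xmax]; a segment straddling xmax contributes its linearly
# interpolated part. Vertical segments (dx = 0) contribute nothing, so a
# jump sitting exactly at xmax is handled correctly.
trapezoid_area <- function(x, y, xmax) {
  area <- 0
  for (k in seq_len(length(x) - 1)) {
    x1 <- x[k]; x2 <- x[k + 1]; y1 <- y[k]; y2 <- y[k + 1]
    if (x2 <= xmax) {
      area <- area + (x2 - x1) * (y1 + y2) / 2
    } else if (x1 < xmax) {
      yi <- y1 + (y2 - y1) * (xmax - x1) / (x2 - x1)
      area <- area + (xmax - x1) * (y1 + yi) / 2
    }
  }
  area
}

#' Wilson score confidence interval for a binomial proportion
#'
#' The interval obtained by inverting the normal-approximation score test;
#' it is the standard choice for reporting diagnostic sensitivity and
#' specificity because it behaves sensibly at proportions near 0 or 1
#' (0 successes gives a lower bound of exactly 0; n of n gives an upper
#' bound of exactly 1). Uses the exact normal quantile (1.959964... at 95%).
#'
#' @param successes,trials counts, `0 <= successes <= trials`, `trials >= 1`.
#' @param level two-sided confidence level.
#' @return object of class `binomial_ci` with `estimate`, `lower`, `upper`,
#'   `successes`, `trials`, `level`.
#' @export
#' @examples
#' wilson_interval(27, 30)   # 90.0% (74.4-96.5)
wilson_interval <- function(successes, trials, level = 0.95) {
  if (trials < 1) stop_input("trials must be >= 1")
  if (successes < 0 || successes > trials)
    stop_input("successes must lie in [0, trials]")
  z <- qnorm(1 - (1 - level) / 2)
  p <- successes / trials
  z2n <- z^2 / trials
  centre <- (p + z2n / 2) / (1 + z2n)
  half <- z * sqrt(p * (1 - p) / trials + z2n / (4 * trials)) / (1 + z2n)
  structure(list(estimate = p,
                 lower = max(0, centre - half),
                 upper = min(1, centre + half),
                 successes = successes, trials = trials, level = level),
            class = "binomial_ci")
}

#' @export
print.binomial_ci <- function(x, ...) {
  cat(sprintf("%d/%d = %.1f%% (%.0f%% Wilson CI %.1f-%.1f%%)\n",
              x$successes, x$trials, 100 * x$estimate, 100 * x$level,
              100 * x$lower, 100 * x$upper))
  invisible(x)
}

#' Bootstrap percentile confidence interval for the AUC
#'
#' Cases and controls are resampled separately (stratified bootstrap,
#' preserving the class sizes, so no resample can lose a class), the AUC
#' recomputed per resample, and the percentile interval reported.
#'
#' @param scores,labels as in [roc_curve].
#' @param n_reps bootstrap repetitions (2000 is the conventional choice
#'   for stable 95% percentile bounds).
#' @param level confidence level.
#' @param seed integer seed; results are deterministic given it.
#' @return object of class `auc_ci` with `auc`, `lower`, `upper`, `n_reps`,
#'   `seed`.
#' @export
bootstrap_auc_ci <- function(scores, labels, n_reps = 2000, level = 0.95,
                             seed = 1) {
  check_scores_labels(scores, labels)
  is_case <- labels == "case"
  cs <- scores[is_case]; ctl <- scores[!is_case]
  n1 <- length(cs); n0 <- length(ctl)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, "bootstrap_auc"))
  aucs <- vapply(seq_len(n_reps), function(i) {
    auc_fast(c(sample(cs, n1, replace = TRUE),
               sample(ctl, n0, replace = TRUE)),
             c(rep(TRUE, n1), rep(FALSE, n0)))
  }, numeric(1))
  qs <- quantile(aucs, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  structure(list(auc = auc_fast(scores, is_case),
                 lower = qs[1], upper = qs[2],
                 n_reps = n_reps, level = level, seed = seed),
            class = "auc_ci")
}

#' @export
print.auc_ci <- function(x, ...) {
  cat(sprintf("AUC %.3f (%.0f%% bootstrap CI %.3f-%.3f, %d reps)\n",
              x$auc, 100 * x$level, x$lower, x$upper, x$n_reps))
  invisible(x)
}

# rank-based AUC, ties counting 1/2
auc_fast <- function(scores, is_case) {
  n1 <- sum(is_case); n0 <- sum(!is_case)
  r <- rank(scores)
  (sum(r[is_case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Score cutoff achieving a target specificity
#'
#' Returns the smallest cutoff such that the fraction of control scores
#' strictly below it is at least `target_spec`, under the classification
#' rule "score >= cutoff is a positive call". If no observed score
#' qualifies (e.g. `target_spec = 1`), the cutoff is placed just above the
#' maximum control score.
#'
#' @param control_scores numeric scores of the control group.
#' @param target_spec desired specificity in `(0, 1]`.
#' @return the cutoff value.
#' @export
threshold_for_specificity <- function(control_scores, target_spec = 0.91) {
  if (!length(control_scores)) stop_input("control scores must be non-empty")
  if (target_spec <= 0 || target_spec > 1)
    stop_input("target_spec must lie in (0, 1]")
  u <- sort(unique(control_scores))
  n <- length(control_scores)
  for (c0 in u) {
    if (sum(control_scores < c0) / n >= target_spec) return(c0)
  }
  mx <- max(u)
  mx + max(abs(mx), 1) * 1e-9
}

#' Confusion summary with Wilson intervals (overall and per stage)
#'
#' Tabulates sensitivity (overall and within stage I / stage II case
#' subsets) and specificity for a vector of positive/negative calls, each
#' with its two-sided Wilson confidence interval. Strata with no patients
#' are reported as `NA` with a warning.
#'
#' @param calls logical (or `"positive"`/`"negative"`) vector of calls.
#' @param labels `"case"`/`"control"` vector aligned with `calls`.
#' @param stages stage vector (`"I"`, `"II"`, `"none"`) aligned with
#'   `calls`; optional — stage rows are omitted when absent.
#' @param level confidence level for the Wilson intervals.
#' @return data.frame with columns `metric`, `successes`, `trials`,
#'   `estimate`, `lower`, `upper`.
#' @export
confusion_summary <- function(calls, labels, stages = NULL, level = 0.95) {
  if (is.character(calls)) calls <- calls == "positive"
  if (length(calls) != length(labels))
    stop_input("calls must align with labels")
  is_case <- labels == "case"

  row_for <- function(metric, succ, n) {
    if (n == 0) {
      warning(sprintf("no patients in stratum '%s'; CI omitted", metric))
      return(data.frame(metric = metric, successes = NA_integer_,
                        trials = 0L, estimate = NA_real_,
                        lower = NA_real_, upper = NA_real_))
    }
    ci <- wilson_interval(succ, n, level)
    data.frame(metric = metric, successes = succ, trials = n,
               estimate = ci$estimate, lower = ci$lower, upper = ci$upper)
  }

  out <- rbind(
    row_for("sensitivity", sum(calls & is_case), sum(is_case)),
    if (!is.null(stages))
      rbind(row_for("sensitivity_stage_I",
                    sum(calls & is_case & stages == "I"),
                    sum(is_case & stages == "I")),
            row_for("sensitivity_stage_II",
                    sum(calls & is_case & stages == "II"),
                    sum(is_case & stages == "II"))),
    row_for("specificity", sum(!calls & !is_case), sum(!is_case)))
  rownames(out) <- NULL
  out
}

check_scores_labels <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop_input("scores and labels must have equal length")
  if (!all(labels %in% c("case", "control")))
    stop_input("labels must be 'case' or 'control'")
  if (!any(labels == "case") || !any(labels == "control"))
    stop_input("both classes must be present")
  if (any(!is.finite(scores)))
    stop_input("scores must be finite")
  invisible(TRUE)
}
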