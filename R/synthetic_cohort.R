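# Synthetic case/control cohort generator emulating a multiplex EV-protein
# immunoassay panel: log-normal concentrations, left-censoring at
# biomarker-specific LLoDs, correlated biomarker blocks, a small informative
# subset shifted in cases, and replicate measurements per patient.

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the structure of an early-detection pancreatic-cancer
#' training cohort: 105 cases (39 stage I, 66 stage II) versus 545
#' controls over a 52-biomarker panel, with 7 informative markers shifted
#' in cases on the log2 scale, one highly correlated noise block, mild
#' left-censoring for most markers plus two heavily censored (unreliable)
#' markers, and ~10% within-patient assay variation.
#'
#' @param n_cases_stage1,n_cases_stage2,n_controls cohort sizes.
#' @param n_biomarkers panel width.
#' @param informative named numeric vector: names are biomarker indices
#'   (coerced) or names, values are the case shift in log2 units.
#' @param correlated_blocks list of `list(indices =, r =)` giving marker
#'   index groups sharing an equicorrelated latent structure with target
#'   Pearson r on the log2 (generation) scale.
#' @param censor_fraction target below-LLoD fraction among controls; either
#'   a single value recycled to all markers or a vector of length
#'   `n_biomarkers`.
#' @param within_patient_cv true within-patient coefficient of variation of
#'   replicate measurements; scalar or per-marker vector.
#' @param n_replicates replicate measurements per patient (>= 2 for CV
#'   estimation).
#' @param sd_log2 residual biological spread of each marker, log2 units.
#' @param seed master seed; all sampling randomness derives from it.
#' @param population_seed seed for the population-level marker baselines
#'   (mean log2 concentrations). Defaults to `seed`; give two configs the
#'   same `population_seed` but different `seed`s to draw independent
#'   cohorts (e.g. training and blinded validation) from one population.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_cases_stage1 = 39,
                             n_cases_stage2 = 66,
                             n_controls = 545,
                             n_biomarkers = 52,
                             informative = c("1" = 3, "2" = 2.5, "3" = 2.5,
                                             "4" = 2, "5" = 2, "6" = 1.5,
                                             "7" = 1.5),
                             correlated_blocks = if (n_biomarkers >= 12)
                               list(list(indices = 10:12, r = 0.95))
                             else list(),
                             censor_fraction = {
                               cf <- rep(0.05, n_biomarkers)
                               if (n_biomarkers >= 31) cf[30:31] <- 0.65
                               cf
                             },
                             within_patient_cv = 0.10,
                             n_replicates = 3,
                             sd_log2 = 1,
                             seed = 1,
                             population_seed = seed) {
  stopifnot(n_cases_stage1 >= 0, n_cases_stage2 >= 0, n_controls >= 0,
            n_biomarkers >= 1, n_replicates >= 2, sd_log2 >= 0)
  censor_fraction <- rep_len(censor_fraction, n_biomarkers)
  within_patient_cv <- rep_len(within_patient_cv, n_biomarkers)
  if (any(censor_fraction < 0 | censor_fraction > 1))
    stop_input("censor_fraction must lie in [0, 1]")
  if (any(within_patient_cv < 0))
    stop_input("within_patient_cv must be >= 0")
  inf_idx <- as.integer(names(informative) %||% character())
  if (length(informative) && (any(is.na(inf_idx)) ||
                              any(inf_idx < 1 | inf_idx > n_biomarkers)))
    stop_input("informative names must be marker indices in 1..n_biomarkers")
  for (blk in correlated_blocks) {
    if (!all(c("indices", "r") %in% names(blk)))
      stop_input("each correlated block needs 'indices' and 'r'")
    if (any(blk$indices < 1 | blk$indices > n_biomarkers))
      stop_input("correlated block indices must lie in 1..n_biomarkers")
    if (blk$r <= -1 || blk$r >= 1)
      stop_input("block correlation target must lie in (-1, 1)")
    m <- length(blk$indices)
    if (blk$r < 0 && m > 2 && blk$r < -1 / (m - 1))
      stop_input("correlation target %g infeasible for a block of %d markers",
                 blk$r, m)
  }
  structure(list(n_cases_stage1 = as.integer(n_cases_stage1),
                 n_cases_stage2 = as.integer(n_cases_stage2),
                 n_controls = as.integer(n_controls),
                 n_biomarkers = as.integer(n_biomarkers),
                 informative = informative,
                 correlated_blocks = correlated_blocks,
                 censor_fraction = censor_fraction,
                 within_patient_cv = within_patient_cv,
                 n_replicates = as.integer(n_replicates),
                 sd_log2 = sd_log2,
                 seed = seed,
                 population_seed = population_seed),
            class = "synthetic_config")
}

#' Generate a synthetic case/control cohort
#'
#' Concentrations are drawn log-normally: each marker has a random baseline
#' level (log2 concentrations centred between ~4 and ~1000 pg/mL),
#' equicorrelated residuals within configured blocks (via the Cholesky
#' factor of the block correlation matrix), and the configured log2 case
#' shift for informative markers. The LLoD of each marker is then placed at
#' the `censor_fraction` quantile of its control distribution and
#' below-LLoD cells are imputed to the LLoD via [impute_llod], so the mask
#' semantics are identical to real panel data.
#'
#' @param config a [synthetic_config].
#' @return a [cohort_dataset]; the true case shifts are attached as
#'   attribute `"true_shift"` for parameter-recovery studies.
#' @export
#' @examples
#' coh <- generate_cohort(synthetic_config(seed = 42))
#' coh
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n_case <- config$n_cases_stage1 + config$n_cases_stage2
  n <- n_case + config$n_controls
  p <- config$n_biomarkers
  if (n < 2) stop_input("cohort must contain at least 2 patients")
  bm <- sprintf("BM%02d", seq_len(p))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))

  # Baseline log2 levels per marker: 2..10 log2 pg/mL (~4 to ~1000 pg/mL).
  # Drawn from the population stream so independent cohorts can share them.
  set.seed(derive_seed(config$population_seed, "population"))
  mu <- runif(p, 2, 10)

  set.seed(derive_seed(config$seed, "cohort"))

  # Residuals: standard-normal with equicorrelation inside blocks, then
  # scaled by sd_log2.
  z <- matrix(rnorm(n * p), n, p)
  for (blk in config$correlated_blocks) {
    idx <- blk$indices
    m <- length(idx)
    if (m < 2) next
    cmat <- matrix(blk$r, m, m); diag(cmat) <- 1
    ch <- tryCatch(chol(cmat), error = function(e)
      stop_input("correlation block %s is not positive definite",
                 paste(idx, collapse = ",")))
    z[, idx] <- matrix(rnorm(n * m), n, m) %*% ch
  }
  log2x <- sweep(z * config$sd_log2, 2, mu, "+")

  # Patient metadata; informative markers shifted in cases.
  label <- c(rep("case", n_case), rep("control", config$n_controls))
  stage <- c(rep("I", config$n_cases_stage1),
             rep("II", config$n_cases_stage2),
             rep("none", config$n_controls))
  shift <- numeric(p)
  if (length(config$informative))
    shift[as.integer(names(config$informative))] <- config$informative
  log2x[label == "case", ] <-
    sweep(log2x[label == "case", , drop = FALSE], 2, shift, "+")

  values <- 2^log2x
  colnames(values) <- bm

  # LLoD at the configured control quantile; markers with 0 target get a
  # token LLoD below the observed minimum so nothing is censored.
  ctrl <- values[label == "control", , drop = FALSE]
  if (nrow(ctrl) == 0) ctrl <- values
  llod <- vapply(seq_len(p), function(j) {
    f <- config$censor_fraction[j]
    if (f <= 0) min(ctrl[, j]) / 2 else quantile(ctrl[, j], f, names = FALSE)
  }, numeric(1))
  schema <- panel_schema(setNames(llod, bm))

  raw <- values
  raw[raw < matrix(llod, n, p, byrow = TRUE)] <- NA_real_
  imp <- impute_llod(raw, schema)

  patients <- data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    label = label, stage = stage,
    noted_condition = "none",
    stringsAsFactors = FALSE)

  out <- cohort_dataset(schema, patients, imp$values, imp$imputed)
  attr(out, "true_shift") <- setNames(shift, bm)
  out
}

#' Generate replicate measurements for within-patient CV estimation
#'
#' Each patient/biomarker cell of the cohort is re-measured `n_replicates`
#' times with multiplicative Gaussian noise of the configured true CV
#' (replicate = base value x (1 + N(0, CV))). Replicates falling below the
#' biomarker's LLoD are set to the LLoD, mirroring how real repeat
#' measurements are preprocessed before CV estimation.
#'
#' @param cohort a [cohort_dataset].
#' @param config the [synthetic_config] used to generate it (supplies
#'   `within_patient_cv`, `n_replicates`, and the replicate seed stream).
#' @return a `replicate_measurements` object: a 3-d array
#'   patients x biomarkers x replicates.
#' @export
generate_replicates <- function(cohort, config) {
  stopifnot(inherits(cohort, "cohort_dataset"),
            inherits(config, "synthetic_config"))
  if (config$n_replicates < 2)
    stop_input("n_replicates must be >= 2 (CV undefined otherwise)")
  n <- nrow(cohort$values); p <- ncol(cohort$values)
  r <- config$n_replicates
  cv <- rep_len(config$within_patient_cv, p)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(config$seed, "replicates"))

  reps <- array(NA_real_, dim = c(n, p, r),
                dimnames = list(rownames(cohort$values),
                                colnames(cohort$values), NULL))
  llod <- matrix(cohort$schema$llod, n, p, byrow = TRUE)
  for (k in seq_len(r)) {
    noise <- matrix(rnorm(n * p), n, p) *
      matrix(cv, n, p, byrow = TRUE)
    v <- cohort$values * (1 + noise)
    v <- pmax(v, llod)
    reps[, , k] <- v
  }
  structure(reps, class = c("replicate_measurements", class(reps)))
}

# Save/restore the global RNG state so generator calls are deterministic
# without disturbing the caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
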