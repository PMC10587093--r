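---
title: "Developing a blood EV-protein biomarker classifier with evpanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Developing a blood EV-protein biomarker classifier with evpanel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(evpanel)
```

## The problem

Early-stage pancreatic ductal adenocarcinoma (PDAC) is usually asymptomatic,
and no blood test is in routine use for surveillance of high-risk
individuals. One promising route is to isolate extracellular vesicles (EVs)
from plasma and quantify a panel of EV-associated proteins by multiplex
immunoassay; a handful of markers measured in pg/mL, combined by a simple
model, can separate early-stage cases from controls. `evpanel` implements
the complete statistical development pipeline for such a test: from raw
panel concentrations with left-censoring, through filter-based feature
selection and cross-validated model comparison, to a locked logistic
classifier with a specificity-anchored cutoff, and finally a
measurement-noise robustness study. A synthetic cohort generator with the
same statistical structure makes every stage testable without patient-level
data.

## Data model and LLoD imputation

Multiplex immunoassays have a biomarker-specific lower limit of detection
(LLoD). Readings that are missing or fall below the LLoD are
*left-censored*: the true concentration lies in (0, LLoD). Both kinds of
cell are imputed to the LLoD itself and flagged in a boolean mask
(`impute_llod()`); the mask travels with the data so every later stage
knows which cells are censored. Two invariants are enforced throughout: all
stored concentrations are strictly positive, and a masked cell equals its
biomarker's LLoD exactly. Because post-imputation values are never below
the LLoD (> 0), the classifier's `log2` transform needs no pseudo-count.

## Filter-based feature selection

Two filters reduce the panel to a candidate set:

1. **Reliability filter.** A biomarker imputed in more than
   `max_imputed_fraction` of patients cannot be reliably measured and is
   dropped. The bound is inclusive (a marker imputed in exactly half the
   patients survives a 0.5 cutoff). The screening default is 0.5; the
   lock-stage default is 0.3.
2. **Correlation/KS filter.** Pairs with absolute Pearson correlation above
   `max_abs_correlation` (screening 0.9, lock stage 0.5) are redundant; the
   member that separates cases from controls *less* well — the larger
   two-sample Kolmogorov–Smirnov p-value against the binary response — is
   removed. Cliques of mutually correlated markers are resolved greedily in
   descending |r|, which terminates deterministically; exact p ties fall to
   the marker later in panel order, so results are reproducible.

Numerical choices worth knowing:

* Pearson r is computed on the raw (post-imputation) concentrations, and
  imputed values participate at their LLoD in both r and the KS statistic;
  no exclusion rule is applied. Whether a log-scale r would change a
  borderline pair is a sensitivity question users can probe by
  pre-transforming.
* The threshold applies to |r|: redundancy is symmetric in sign.
* The KS statistic is the exact sup of the ECDF difference over the pooled
  points, which is well defined under the heavy ties censoring creates; the
  p-value uses the two-sided asymptotic Kolmogorov series
  `2 * sum((-1)^(k-1) exp(-2 k^2 lambda^2))`. At the cohort sizes involved
  (dozens to hundreds per class) the asymptotic form is adequate, and the
  p-value is only used ordinally — to rank the two members of a pair.
* A constant-valued marker has undefined r; it is flagged, logged, and
  treated as uncorrelated rather than silently dropped.

## Cross-validated candidate selection

Model selection runs repeated stratified cross-validation
(`make_cv_plan()`: default 100 repetitions of 5 folds, stratified by the
case/control label so every fold's case count is within one patient of
balance). The objective is the **partial AUC (pAUC)** over the
high-specificity band — the unnormalised trapezoidal area under the ROC
curve for specificities 90–100%, maximum 0.10, chance level 0.005. For a
rule-out-poor screening context, performance below 90% specificity is
irrelevant, and pAUC focuses selection there. The pAUC is left
unnormalised (no McClish scaling): ranking of candidates is unaffected and
the raw area is directly interpretable against its 0.10 ceiling.

The critical property of `evaluate_candidate()` is **leakage freedom**:
both filters and any transform parameters are fitted on each fold's
training portion only and applied unchanged to the held-out fold. The test
suite verifies this with a label-permutation null: over 25 held-out folds
spread across five independent label permutations, mean held-out pAUC must
stay within three standard errors of 0.005. (Five independent permutations
are used rather than one because any single permutation retains a chance
label–marker association of order $1/\sqrt{n}$ that all folds detect
consistently; averaging permutations isolates genuine leakage. The
empirical pAUC estimator also has a small positive finite-sample bias —
about 0.0054 rather than 0.0050 at a 21-case/109-control fold — which the
band absorbs.)

ROC conventions: a sample is called positive when its score is **at or
above** the cutoff (the "≥" direction is a documented choice; the
alternative ">" differs only on tied scores), tied scores collapse to a
single operating point, and the AUC is the rank-based concordance
probability with ties counting one half. Sensitivity inside CV is measured
at the fold-level cutoff achieving the target specificity on the fold's
training controls.

**Permutation feature importance** is computed per fold: each feature's
validation column is shuffled ten times and the mean loss in pAUC, AUC and
sensitivity from baseline is recorded, then averaged across folds. A
feature the model ignores has zero expected loss.

## Locking the classifier

After candidate selection, the lock-stage filters (0.3 / 0.5) are applied
and **recursive feature elimination** reduces the survivors to a compact
signature (default 7 markers): a logistic model is fitted repeatedly on
log2-transformed, internally standardized features, dropping the smallest
absolute standardized coefficient each round. Standardization here is for
ranking only — it makes coefficient magnitudes comparable across markers
with different dynamic ranges — and the locked model itself is fitted on
unstandardized log2 concentrations, so its coefficients are
per-doubling log-odds increments.

The locked classifier maps concentrations to a score in (0, 1) via the
sigmoid of a linear combination of log2 concentrations. The cutoff is the
smallest value achieving the target specificity (default 91%, the
conventional operating point for a high-risk surveillance test) on the
training controls, then frozen; application to any new cohort is pure
prediction with no refitting. If the training data are quasi-separated —
common in strongly separable synthetic cohorts — plain maximum likelihood
diverges, and the fit falls back to a lightly ridge-penalised logistic
model (glmnet, alpha = 0, lambda = 1e-3), recorded in the model object.
RFE is run once on the full training set after candidate selection (not
inside CV): the signature is part of the locked object, and the CV stage
has already done its job of comparing pipeline families.

## Perturbation robustness

Assay reproducibility is summarised by the **within-patient coefficient of
variation**: per patient and biomarker, the sample standard deviation of
replicate measurements divided by their mean, averaged (unweighted) across
patients. Note the plain sd/mean estimator has the usual small-sample bias
(its expectation is $c_4(n)\,\sigma$, about 0.89σ for duplicates-plus-one,
0.97σ at ten replicates), so CV profiles estimated from few replicates are
mildly conservative.

`perturb_dataset()` then emulates re-measurement: independently per cell,
with probability 0.68 the value is multiplied by $1+u$, $u \sim
U(-CV, CV)$ (one standard deviation of a bell curve); otherwise by
$1 \pm v$, $v \sim U(CV, 2\,CV)$ with random sign (the one-to-two standard
deviation scenario). The factor has expectation 1, so the noise is
mean-preserving. The 68/32 split is an independent Bernoulli draw per cell
("68% of the data" read as an expected fraction); an exact-partition mode
is available behind a flag. Two boundary choices: LLoD-imputed cells are
held fixed at the LLoD (a censored cell has no measured value to perturb,
and re-measurement of a below-detection sample is again reported at the
LLoD), and a perturbed value that would become non-positive — possible
only when CV > 0.5 in the outer band — is clamped to the LLoD with a
warning. `perturbation_study()` applies the locked classifier to 100 such
perturbed datasets and reports mean/min/max of AUC, specificity and
overall/stage-wise sensitivity, retaining per-set values for audit.

## Reporting

`confusion_summary()` reports sensitivity (overall and per stage) and
specificity with two-sided **Wilson score intervals**, the standard
interval for diagnostic proportions because of its behaviour at the
boundaries (0/n gives a lower bound of exactly 0, n/n an upper bound of
exactly 1). The normal quantile is used at full precision (1.959964 at
95%), not rounded to 1.96. AUC confidence intervals use a stratified
percentile bootstrap (cases and controls resampled separately with sizes
preserved, 2000 repetitions): stratification preserves the cohort's class
balance and makes a class-free resample impossible, and the percentile
interval is the simplest method consistent with plain "bootstrapping".
`fold_change_matrix()` produces the heatmap-ready summary
`log2(group mean / control mean)` per biomarker; the control row is
identically zero by construction.

## The synthetic cohort generator

`synthetic_config()` defaults encode the study conditions the pipeline is
designed for: 105 cases (39 stage I, 66 stage II) versus 545 controls over
a 52-marker panel, with

* log-normal concentrations (positive, right-skewed, as immunoassay panels
  are), baseline log2 levels uniform between about 4 and 1000 pg/mL;
* residual biological spread `sd_log2 = 1` (a 2-fold coefficient of
  variation on the natural scale, typical of circulating protein markers);
* seven informative markers with case shifts of 3, 2.5, 2.5, 2, 2, 1.5,
  1.5 log2 units — deliberately large effects, chosen so that
  parameter-recovery properties (RFE finding the planted markers) are
  sharp tests rather than coin flips;
* one three-marker block with r = 0.95 to exercise the correlation filter,
  correlation being imposed on the log2 (generation) scale via the
  Cholesky factor of an equicorrelation matrix (raw-scale Pearson r is
  slightly attenuated under log-normality);
* mild censoring (5% of controls below LLoD) for most markers plus two
  markers censored at 65% to exercise the reliability filter — the LLoD is
  placed at the configured quantile of the control distribution and
  `impute_llod()` applied, so mask semantics are identical to real data;
* within-patient CV 0.10 and triplicate re-measurement for the robustness
  stage.

Case shifts induce between-marker correlation in the pooled cohort (two
markers both elevated in cases co-vary even with independent residuals);
at the lock-stage 0.5 threshold the correlation filter may therefore
legitimately remove some informative markers as mutually redundant — the
same behaviour the filter exists to produce on real panels.

Seeding is hierarchical: a single seed fans out to named streams (cohort
sampling, replicates, CV plan, shuffles, bootstrap, perturbation) via a
hash, so any stage can be regenerated independently and whole runs
replayed bit-exactly. Marker baselines are drawn from a separate
`population_seed` stream (defaulting to `seed`), so a blinded validation
cohort can be drawn from the *same* population as training by sharing
`population_seed` while varying `seed`.

What the generator does **not** emulate: the identities, effect sizes or
covariance of any real marker panel, assay plate/batch
effects, age/sex/comorbidity structure in controls, or distributional
quirks beyond log-normality. Passing tests therefore demonstrate that the
*pipeline machinery* is correct (leakage-free CV, contract-honouring
cutoffs, parameter recovery under known truth), not that any particular
real-data performance level will be attained.

## Worked example

A reduced-scale end-to-end run (sizes chosen to keep the example quick;
a full development run uses the defaults of 100 CV repetitions and 100
perturbation sets):

```{r example, eval = FALSE}
synth <- synthetic_config(seed = 7)
cfg <- pipeline_config(synthetic = synth,
                       n_reps = 5, n_perturbation_sets = 20,
                       seed = 7, out_dir = tempfile("run_"))
res <- run_pipeline(cfg)
res$model              # locked 7-marker logistic classifier
res$model$training     # training confusion summary with Wilson CIs
res$perturbation       # robustness summary (mean/min/max per metric)
```

## Test-suite problem sizes

The shipped tests exercise the same code paths at reduced scale: the
leakage guard uses 25 held-out folds (five permutations of a 650-patient
cohort), RFE recovery uses 20 generator seeds at 650 x 34, the
perturbation band check uses 10^5 cells, and the pipeline determinism
check runs 2 repetitions of 5-fold CV on a 375-patient, 16-marker cohort.
These sizes give the property tests adequate power while keeping the
default test run fast; all constants scale up through the public
configuration objects.

## Known limitations

* The KS p-value is asymptotic; for very small strata (< ~10 per class) an
  exact permutation p would differ, though only the within-pair ordering
  matters here.
* The ridge fallback's penalty (lambda = 1e-3) is fixed, not tuned;
  separable training data therefore yield finite but penalty-dependent
  coefficients.
* `within_patient_cv` assumes replicates are exchangeable re-measurements;
  drift between replicate runs inflates the estimated CV.
* The perturbation model treats cells independently; correlated assay
  noise (plate effects) would stress a classifier differently.
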