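# Filter-based feature selection: imputation-rate reliability filter and
# the Pearson-correlation pair filter resolved by two-sample
# Kolmogorov-Smirnov tests against the binary case/control response.

#' Filter configuration
#'
#' `max_imputed_fraction` drops biomarkers that cannot be reliably measured
#' (too many patients imputed at the LLoD); `max_abs_correlation` caps
#' pairwise redundancy among the survivors. The defaults (0.5 / 0.9) are
#' the screening values used when assembling a candidate feature set; the
#' tighter 0.3 / 0.5 pair is typical for locking a final parsimonious
#' model.
#'
#' @param max_imputed_fraction inclusive upper bound on the per-marker
#'   imputation fraction.
#' @param max_abs_correlation inclusive upper bound on pairwise `|r|`.
#' @return a `filter_config` list.
#' @export
filter_config <- function(max_imputed_fraction = 0.5,
                          max_abs_correlation = 0.9) {
  if (max_imputed_fraction < 0 || max_imputed_fraction > 1 ||
      max_abs_correlation < 0 || max_abs_correlation > 1)
    stop_input("filter cutoffs must lie in [0, 1]")
  structure(list(max_imputed_fraction = max_imputed_fraction,
                 max_abs_correlation = max_abs_correlation),
            class = "filter_config")
}

#' Reliability filter on the LLoD-imputation rate
#'
#' Keeps exactly the biomarkers whose imputation fraction is less than or
#' equal to `max_imputed_fraction` (the bound is inclusive: a marker
#' imputed in exactly half the patients survives a 0.5 cutoff). Order is
#' preserved from the schema.
#'
#' @param dataset a [cohort_dataset].
#' @param config a [filter_config].
#' @param candidates optional subset of biomarkers to consider (defaults to
#'   the full schema); used for in-fold filtering.
#' @return character vector of kept biomarker names.
#' @export
imputation_rate_filter <- function(dataset, config = filter_config(),
                                   candidates = NULL) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  if (nrow(dataset$values) == 0) stop_input("empty dataset")
  candidates <- candidates %||% dataset$schema$biomarkers
  frac <- colMeans(dataset$imputed[, candidates, drop = FALSE])
  candidates[frac <= config$max_imputed_fraction]
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Computes `D`, the supremum over the pooled sample points of the absolute
#' difference of the two empirical CDFs, and the two-sided asymptotic
#' p-value from the Kolmogorov distribution,
#' `p = 2 * sum_{k>=1} (-1)^(k-1) exp(-2 k^2 lambda^2)` with
#' `lambda = D * sqrt(n1 n2 / (n1 + n2))`. The statistic is exact in the
#' presence of ties (common here because censored values sit at the LLoD);
#' the p-value is asymptotic and used ordinally, to rank markers within a
#' redundant pair.
#'
#' @param x,y numeric samples (non-empty).
#' @return list with `statistic` (D) and `p_value`, class `ks_result`.
#' @export
#' @examples
#' ks_two_sample(c(1, 2, 3, 4), c(3, 4, 5, 6))
ks_two_sample <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (!length(x) || !length(y)) stop_input("both samples must be non-empty")
  pooled <- sort(unique(c(x, y)))
  d <- max(abs(ecdf(x)(pooled) - ecdf(y)(pooled)))
  n1 <- length(x); n2 <- length(y)
  lambda <- d * sqrt(n1 * n2 / (n1 + n2))
  p <- if (d == 0) 1 else kolmogorov_sf(lambda)
  structure(list(statistic = d, p_value = p), class = "ks_result")
}

# Two-sided asymptotic Kolmogorov survival function, truncated when terms
# become negligible.
kolmogorov_sf <- function(lambda) {
  if (lambda <= 0) return(1)
  k <- 1:100
  terms <- (-1)^(k - 1) * exp(-2 * k^2 * lambda^2)
  min(1, max(0, 2 * sum(terms)))
}

#' Correlation pair filter with KS tie resolution
#'
#' Finds biomarker pairs whose Pearson correlation (computed on the raw,
#' post-imputation concentrations) exceeds `max_abs_correlation` in
#' absolute value, and within each such pair removes the member that
#' discriminates cases from controls less well: the one with the larger
#' two-sample KS p-value against the case/control response. Cliques of
#' mutually correlated markers are resolved greedily in descending `|r|`;
#' KS p ties fall to the marker later in schema order, so the result is
#' deterministic. Constant-valued markers (Pearson r undefined) are flagged
#' and treated as uncorrelated.
#'
#' @param dataset a [cohort_dataset].
#' @param candidates character vector of candidate biomarkers (>= 2).
#' @param labels optional case/control vector aligned with patients
#'   (defaults to the dataset labels).
#' @param config a [filter_config].
#' @return list with `kept` (character), and `removed` — a data.frame with
#'   columns `biomarker`, `partner`, `r`, `ks_p`, `partner_ks_p`, `reason`.
#' @export
correlation_ks_filter <- function(dataset, candidates = NULL, labels = NULL,
                                  config = filter_config()) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  candidates <- candidates %||% dataset$schema$biomarkers
  labels <- labels %||% cohort_labels(dataset)
  if (length(labels) != nrow(dataset$values))
    stop_input("labels must align with dataset patients")
  if (length(candidates) < 2)
    return(list(kept = candidates, removed = empty_removed()))

  X <- dataset$values[, candidates, drop = FALSE]
  is_case <- labels == "case"

  const <- apply(X, 2, function(v) diff(range(v)) == 0)
  if (any(const))
    message("constant-valued biomarkers treated as uncorrelated: ",
            paste(candidates[const], collapse = ", "))
  r <- suppressWarnings(cor(X))
  r[is.na(r)] <- 0
  diag(r) <- 0

  # KS p-value of each candidate against the binary response.
  ks_p <- vapply(candidates, function(bm)
    ks_two_sample(X[is_case, bm], X[!is_case, bm])$p_value, numeric(1))

  # Violating pairs in descending |r| (stable order for exact ties).
  ut <- which(upper.tri(r) & abs(r) > config$max_abs_correlation,
              arr.ind = TRUE)
  kept <- rep(TRUE, length(candidates))
  removed <- empty_removed()
  if (nrow(ut)) {
    ord <- order(-abs(r[ut]), ut[, 1], ut[, 2])
    ut <- ut[ord, , drop = FALSE]
    for (k in seq_len(nrow(ut))) {
      i <- ut[k, 1]; j <- ut[k, 2]
      if (!kept[i] || !kept[j]) next
      # drop the larger p (weaker case/control separation); ties drop the
      # later marker in schema order (j > i in upper triangle)
      drop_j <- ks_p[j] >= ks_p[i]
      d <- if (drop_j) j else i
      s <- if (drop_j) i else j
      kept[d] <- FALSE
      removed <- rbind(removed, data.frame(
        biomarker = candidates[d], partner = candidates[s],
        r = r[i, j], ks_p = ks_p[d], partner_ks_p = ks_p[s],
        reason = sprintf("|r|=%.3f with %s exceeds %.2f; larger KS p",
                         abs(r[i, j]), candidates[s],
                         config$max_abs_correlation),
        stringsAsFactors = FALSE))
    }
  }
  list(kept = candidates[kept], removed = removed)
}

empty_removed <- function() {
  data.frame(biomarker = character(), partner = character(),
             r = numeric(), ks_p = numeric(), partner_ks_p = numeric(),
             reason = character(), stringsAsFactors = FALSE)
}

#' Apply both filters and report
#'
#' Convenience wrapper running the imputation-rate filter then the
#' correlation/KS filter, returning the surviving candidate set and a
#' per-biomarker report suitable for CSV export.
#'
#' @inheritParams correlation_ks_filter
#' @return list with `kept` and `report` (data.frame: biomarker,
#'   imputed_fraction, status, reason).
#' @export
filter_features <- function(dataset, config = filter_config(),
                            candidates = NULL, labels = NULL) {
  candidates <- candidates %||% dataset$schema$biomarkers
  frac <- colMeans(dataset$imputed[, candidates, drop = FALSE])
  kept1 <- imputation_rate_filter(dataset, config, candidates)
  res <- if (length(kept1) >= 2)
    correlation_ks_filter(dataset, kept1, labels, config)
  else list(kept = kept1, removed = empty_removed())

  status <- ifelse(candidates %in% res$kept, "kept",
                   ifelse(candidates %in% kept1, "removed_correlation",
                          "removed_imputation"))
  reason <- character(length(candidates))
  reason[status == "removed_imputation"] <-
    sprintf("imputed fraction %.2f > %.2f",
            frac[status == "removed_imputation"], config$max_imputed_fraction)
  m <- match(candidates, res$removed$biomarker)
  reason[!is.na(m)] <- res$removed$reason[m[!is.na(m)]]
  list(kept = res$kept,
       report = data.frame(biomarker = candidates,
                           imputed_fraction = unname(frac),
                           status = status, reason = reason,
                           stringsAsFactors = FALSE))
}
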