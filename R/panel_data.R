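# Data model and I/O for multiplex EV-protein panels with left-censoring
# at the lower limit of detection (LLoD).

#' Panel schema: biomarker names and lower limits of detection
#'
#' A panel schema records the ordered biomarker names of a multiplex
#' immunoassay panel together with each biomarker's lower limit of
#' detection (LLoD) in pg/mL. Concentrations reported below the LLoD are
#' left-censored; downstream they are imputed to the LLoD itself.
#'
#' @param llod named numeric vector of strictly positive LLoDs (pg/mL);
#'   names are the biomarker names and fix the panel order.
#' @return an object of class `panel_schema` with elements `biomarkers`
#'   (character) and `llod` (named numeric).
#' @export
#' @examples
#' panel_schema(c(CA19_9 = 2.5, MUC1 = 10))
panel_schema <- function(llod) {
  if (is.null(names(llod)) || any(!nzchar(names(llod))))
    stop_input("llod must be a named numeric vector of biomarker LLoDs")
  if (anyDuplicated(names(llod)))
    stop_input("duplicate biomarker names in schema: %s",
               paste(unique(names(llod)[duplicated(names(llod))]), collapse = ", "))
  llod <- setNames(as.double(llod), names(llod))
  if (any(!is.finite(llod)) || any(llod <= 0))
    stop_input("all LLoDs must be finite and strictly positive")
  structure(list(biomarkers = names(llod), llod = llod), class = "panel_schema")
}

#' @export
print.panel_schema <- function(x, ...) {
  cat(sprintf("Panel schema: %d biomarkers, LLoD range %.3g-%.3g pg/mL\n",
              length(x$biomarkers), min(x$llod), max(x$llod)))
  invisible(x)
}

#' Read / write a panel schema as JSON
#'
#' The on-disk form is a flat JSON object `{biomarker: llod}`.
#'
#' @param path file path.
#' @return `read_schema` returns a [panel_schema]; `write_schema` its path,
#'   invisibly.
#' @export
read_schema <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  panel_schema(unlist(x))
}

#' @rdname read_schema
#' @param schema a [panel_schema].
#' @export
write_schema <- function(schema, path) {
  jsonlite::write_json(as.list(schema$llod), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

valid_stages <- c("I", "II", "none")

#' Construct a cohort dataset
#'
#' Bundles patient metadata with the patients x biomarkers concentration
#' matrix and the boolean imputation mask that records which cells were
#' set to the biomarker's LLoD (missing or below-detection readings).
#'
#' @param schema a [panel_schema].
#' @param patients data.frame with columns `patient_id`, `label`
#'   (`"case"`/`"control"`), `stage` (`"I"`, `"II"`, `"none"`), and
#'   `noted_condition` (free text, `"none"` if absent).
#' @param values numeric matrix (patients x biomarkers), strictly positive,
#'   columns in schema order.
#' @param imputed logical matrix of the same shape; where `TRUE` the value
#'   must equal the biomarker's LLoD exactly.
#' @return an object of class `cohort_dataset`.
#' @export
cohort_dataset <- function(schema, patients, values, imputed = NULL) {
  stopifnot(inherits(schema, "panel_schema"))
  req <- c("patient_id", "label", "stage", "noted_condition")
  if (!all(req %in% names(patients)))
    stop_input("patients table must have columns: %s", paste(req, collapse = ", "))
  patients <- as.data.frame(patients)[, req]
  patients$patient_id <- as.character(patients$patient_id)
  if (any(is.na(patients$patient_id) | !nzchar(patients$patient_id)))
    stop_input("missing patient_id")
  dup <- patients$patient_id[duplicated(patients$patient_id)]
  if (length(dup))
    stop_input("duplicate patient_id: %s", paste(unique(dup), collapse = ", "))
  if (!all(patients$label %in% c("case", "control")))
    stop_input("label must be 'case' or 'control'")
  if (!all(patients$stage %in% valid_stages))
    stop_input("stage must be one of %s", paste(valid_stages, collapse = ", "))
  bad <- patients$stage %in% c("I", "II") & patients$label != "case"
  if (any(bad))
    stop_input("staged patients must be cases: %s",
               paste(patients$patient_id[bad], collapse = ", "))
  bad <- patients$label == "control" & patients$stage != "none"
  if (any(bad))
    stop_input("controls must have stage 'none': %s",
               paste(patients$patient_id[bad], collapse = ", "))

  values <- as.matrix(values)
  if (is.null(imputed)) imputed <- matrix(FALSE, nrow(values), ncol(values))
  imputed <- as.matrix(imputed)
  if (!identical(dim(values), dim(imputed)))
    stop_input("values and imputed mask dimensions differ")
  if (nrow(values) != nrow(patients) || ncol(values) != length(schema$biomarkers))
    stop_input("values matrix must be %d patients x %d biomarkers",
               nrow(patients), length(schema$biomarkers))
  if (!is.null(colnames(values)) &&
      !identical(colnames(values), schema$biomarkers))
    stop_input("values columns must match schema biomarker order")
  dimnames(values) <- list(patients$patient_id, schema$biomarkers)
  dimnames(imputed) <- dimnames(values)
  storage.mode(values) <- "double"
  storage.mode(imputed) <- "logical"
  if (any(!is.finite(values)) || any(values <= 0))
    stop_input("all concentrations must be finite and strictly positive")
  off <- imputed & values != matrix(schema$llod, nrow(values), ncol(values), byrow = TRUE)
  if (any(off))
    stop_input("imputed cells must equal the biomarker LLoD exactly")

  structure(list(schema = schema, patients = patients,
                 values = values, imputed = imputed),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  n_case <- sum(x$patients$label == "case")
  cat(sprintf(paste0(
    "Cohort dataset: %d patients (%d cases [%d stage I, %d stage II], ",
    "%d controls), %d biomarkers, %.1f%% cells LLoD-imputed\n"),
    nrow(x$values), n_case,
    sum(x$patients$stage == "I"), sum(x$patients$stage == "II"),
    sum(x$patients$label == "control"),
    ncol(x$values), 100 * mean(x$imputed)))
  invisible(x)
}

#' Impute missing / below-LLoD readings to the LLoD
#'
#' Immunoassay readings that are missing or fall below the lower limit of
#' detection are left-censored: the true concentration is somewhere in
#' `(0, LLoD)`. Both kinds of cell are set to the biomarker's LLoD and
#' flagged in the returned mask, matching standard practice for multiplex
#' panel preprocessing. Values already at or above the LLoD are untouched,
#' so the operation is idempotent.
#'
#' @param raw numeric matrix (patients x biomarkers); `NA` marks missing or
#'   below-detection cells. Columns must be named with schema biomarkers.
#' @param schema a [panel_schema] covering every column.
#' @return list with `values` (no `NA`, all >= the column LLoD where
#'   imputed) and `imputed` (logical mask of replaced cells).
#' @export
#' @examples
#' sch <- panel_schema(c(A = 2.5, B = 1))
#' m <- matrix(c(10, NA, 0.5, 3), 2, 2, dimnames = list(NULL, c("A", "B")))
#' impute_llod(m, sch)
impute_llod <- function(raw, schema) {
  raw <- as.matrix(raw)
  if (is.null(colnames(raw)))
    stop_input("raw matrix must have biomarker column names")
  unknown <- setdiff(colnames(raw), schema$biomarkers)
  if (length(unknown))
    stop_input("columns not in schema: %s", paste(unknown, collapse = ", "))
  storage.mode(raw) <- "double"
  if (any(raw < 0, na.rm = TRUE))
    stop_input("negative concentrations are physically impossible")
  llod <- matrix(schema$llod[colnames(raw)], nrow(raw), ncol(raw), byrow = TRUE)
  mask <- is.na(raw) | raw < llod
  vals <- raw
  vals[mask] <- llod[mask]
  dimnames(mask) <- dimnames(vals) <- dimnames(raw)
  list(values = vals, imputed = mask)
}

#' Fraction of patients imputed to the LLoD for one biomarker
#'
#' @param dataset a [cohort_dataset].
#' @param biomarker biomarker name.
#' @return fraction in `[0, 1]`.
#' @export
imputation_fraction <- function(dataset, biomarker) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  if (!biomarker %in% dataset$schema$biomarkers)
    stop_input("unknown biomarker: %s", biomarker)
  mean(dataset$imputed[, biomarker])
}

#' Read a cohort from patients and measurements CSV files
#'
#' Expects the two-table layout of a de-identified panel export: a patients
#' table (`patient_id,label,stage,noted_condition`) and a measurements
#' table (`patient_id` plus one numeric column per biomarker). Cells that
#' are empty, `NA`, or written as `"<LLOD"` are treated as below-detection
#' and imputed to the biomarker's LLoD.
#'
#' @param patients_path CSV path for the patients table.
#' @param measurements_path CSV path for the measurements table.
#' @param schema a [panel_schema]; measurement columns must match it.
#' @return a validated [cohort_dataset].
#' @export
read_cohort <- function(patients_path, measurements_path, schema) {
  pats <- read.csv(patients_path, stringsAsFactors = FALSE,
                   colClasses = "character")
  meas <- read.csv(measurements_path, stringsAsFactors = FALSE,
                   check.names = FALSE)
  if (!"patient_id" %in% names(meas))
    stop_input("measurements file lacks a patient_id column")
  extra <- setdiff(names(meas), c("patient_id", schema$biomarkers))
  if (length(extra))
    stop_input("unknown biomarker columns in measurements: %s",
               paste(extra, collapse = ", "))
  missing_bm <- setdiff(schema$biomarkers, names(meas))
  if (length(missing_bm))
    stop_input("measurements missing biomarker columns: %s",
               paste(missing_bm, collapse = ", "))
  if (anyDuplicated(meas$patient_id))
    stop_input("duplicate patient_id in measurements: %s",
               paste(unique(meas$patient_id[duplicated(meas$patient_id)]),
                     collapse = ", "))
  ord <- match(pats$patient_id, meas$patient_id)
  if (any(is.na(ord)))
    stop_input("patients without measurements: %s",
               paste(pats$patient_id[is.na(ord)], collapse = ", "))
  meas <- meas[ord, , drop = FALSE]

  raw <- matrix(NA_real_, nrow(meas), length(schema$biomarkers),
                dimnames = list(NULL, schema$biomarkers))
  for (bm in schema$biomarkers) {
    colv <- meas[[bm]]
    if (is.character(colv)) {
      below <- grepl("^\\s*<\\s*LLOD\\s*$", colv, ignore.case = TRUE) |
        !nzchar(trimws(colv))
      num <- suppressWarnings(as.numeric(colv))
      bad <- which(!below & is.na(num) & !is.na(colv))
      if (length(bad))
        stop_input("non-numeric concentration in column %s, row %d: '%s'",
                   bm, bad[1], colv[bad[1]])
      num[below] <- NA_real_
      raw[, bm] <- num
    } else {
      raw[, bm] <- as.numeric(colv)
    }
  }
  imp <- impute_llod(raw, schema)
  cohort_dataset(schema, pats, imp$values, imp$imputed)
}

#' Write a cohort to patients and measurements CSV files
#'
#' Inverse of [read_cohort]: LLoD-imputed cells are written as `"<LLOD"` so
#' the censoring mask round-trips exactly. Numeric cells are written with
#' full precision (`digits = 17`).
#'
#' @param dataset a [cohort_dataset].
#' @param patients_path,measurements_path output CSV paths.
#' @return invisibly, the two paths.
#' @export
write_cohort <- function(dataset, patients_path, measurements_path) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  write.csv(dataset$patients, patients_path, row.names = FALSE, quote = TRUE)
  vals <- dataset$values
  out <- matrix("", nrow(vals), ncol(vals), dimnames = dimnames(vals))
  out[] <- formatC(vals, digits = 17, format = "g")
  out[dataset$imputed] <- "<LLOD"
  df <- data.frame(patient_id = dataset$patients$patient_id, out,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, measurements_path, row.names = FALSE, quote = TRUE)
  invisible(c(patients_path, measurements_path))
}

# Convenience accessors used throughout.
cohort_labels <- function(dataset) dataset$patients$label
cohort_is_case <- function(dataset) dataset$patients$label == "case"
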