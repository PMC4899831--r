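#' @include AllClasses.R
NULL

schemaContinuousNames <- c("age", "bmi", "systolic_bp", "hemoglobin",
                           "sodium", "cholesterol", "lymphocytes", "index_ef")
schemaCategoricalNames <- c("sex", "race", "ethnicity")

#' Fit the feature-encoding schema on training patients
#'
#' Computes z-score constants for the continuous features (the four labs,
#' the two vitals, age and the index EF), the observed levels of the
#' categorical demographics, and the comorbidity flag order, fixing the
#' deterministic canonical feature order: continuous, then one-hot dummies
#' (first level alphabetically is the reference and is dropped), then the 26
#' comorbidity flags. Constants come from training rows only, so encoding
#' test patients with this schema cannot leak test-set information.
#'
#' Medication classes deliberately do not enter the feature vector: the
#' medication plan is the class label the recommender predicts, and using it
#' as a feature would leak the label. Set `includeMedications = TRUE` to
#' append the five drug-class indicators for replication experiments.
#'
#' @param cohort cohort data.frame from [buildCohort()] (needs the
#'   continuous columns, demographics and flag columns; `plan` if
#'   `includeMedications`).
#' @param includeMedications append drug-class indicator features.
#' @return an [EncodingSchema-class].
#' @examples
#' sc <- generateCohort(defaultGeneratorConfig(nPatients = 120, seed = 4))
#' cohort <- buildCohort(cohortExtracts(sc))$cohort
#' fitSchema(cohort)
#' @export
fitSchema <- function(cohort, includeMedications = FALSE) {
  if (nrow(cohort) < 2) stop("need at least 2 training rows to fit a schema")
  cont <- data.frame(name = schemaContinuousNames,
                     mean = NA_real_, sd = NA_real_,
                     stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cont))) {
    v <- cohort[[cont$name[i]]]
    if (is.null(v)) stop("missing continuous feature column: ", cont$name[i])
    if (anyNA(v)) stop("NA in continuous feature: ", cont$name[i])
    cont$mean[i] <- mean(v)
    cont$sd[i] <- stats::sd(v)
    if (cont$sd[i] <= 0 || !is.finite(cont$sd[i]))
      stop("zero-variance continuous feature: ", cont$name[i])
  }
  categorical <- list()
  for (v in schemaCategoricalNames) {
    lev <- sort(unique(as.character(cohort[[v]])))
    if (length(lev) < 1) stop("no levels for categorical feature: ", v)
    categorical[[v]] <- lev
  }
  flagCols <- setdiff(names(cohort),
                      c("patient_id", schemaContinuousNames,
                        schemaCategoricalNames, "index_ef_date", "ef_delta",
                        "response", "plan"))
  flagCols <- flagCols[vapply(flagCols, function(f)
    all(cohort[[f]] %in% c(0L, 1L)), logical(1))]
  oneHot <- unlist(lapply(schemaCategoricalNames, function(v) {
    lev <- categorical[[v]]
    if (length(lev) > 1) paste(v, lev[-1], sep = "_") else character(0)
  }))
  fn <- c(cont$name, oneHot, flagCols)
  if (includeMedications) fn <- c(fn, paste0("med_", drugClasses()))
  schema <- new("EncodingSchema", continuous = cont,
                categorical = categorical, flags = flagCols,
                featureNames = fn)
  attr(schema, "includeMedications") <- includeMedications
  validObject(schema)
  schema
}

#' Encode patients as numeric feature vectors
#'
#' Applies a fitted [EncodingSchema-class]: continuous features are z-scored
#' with the training constants, categoricals are one-hot encoded (unseen
#' levels are an error, never a silent zero row), and comorbidity flags pass
#' through as 0/1. Output column order is the schema's canonical order; no
#' NaNs are ever emitted.
#'
#' @param cohort cohort data.frame rows to encode.
#' @param schema a fitted [EncodingSchema-class].
#' @return numeric matrix, one row per patient (rownames = patient ids),
#'   `length(featureNames(schema))` columns.
#' @examples
#' sc <- generateCohort(defaultGeneratorConfig(nPatients = 120, seed = 4))
#' cohort <- buildCohort(cohortExtracts(sc))$cohort
#' schema <- fitSchema(cohort)
#' X <- encodeFeatures(cohort, schema)
#' dim(X)
#' @export
encodeFeatures <- function(cohort, schema) {
  n <- nrow(cohort)
  X <- matrix(NA_real_, n, length(schema@featureNames),
              dimnames = list(cohort$patient_id, schema@featureNames))
  for (i in seq_len(nrow(schema@continuous))) {
    nm <- schema@continuous$name[i]
    v <- cohort[[nm]]
    if (is.null(v) || anyNA(v)) stop("missing values in feature: ", nm)
    X[, nm] <- (v - schema@continuous$mean[i]) / schema@continuous$sd[i]
  }
  for (v in names(schema@categorical)) {
    lev <- schema@categorical[[v]]
    vals <- as.character(cohort[[v]])
    unseen <- setdiff(unique(vals), lev)
    if (length(unseen) > 0)
      stop(sprintf("unseen level(s) for %s: %s", v,
                   paste(unseen, collapse = ", ")))
    for (l in lev[-1]) X[, paste(v, l, sep = "_")] <- as.numeric(vals == l)
  }
  for (f in schema@flags) {
    v <- cohort[[f]]
    if (is.null(v) || anyNA(v)) stop("missing values in flag: ", f)
    X[, f] <- as.numeric(v)
  }
  if (any(startsWith(schema@featureNames, "med_"))) {
    if (is.null(cohort$plan)) stop("plan column required for medication features")
    for (cl in drugClasses()) {
      X[, paste0("med_", cl)] <- vapply(cohort$plan, function(p)
        as.numeric(cl %in% planClasses(p)), numeric(1))
    }
  }
  if (anyNA(X)) stop("encoding produced missing values")
  X
}

#' Medication plan of each patient over the treatment window
#'
#' The plan is the set of distinct drug classes started within the treatment
#' window (default: index EF date to index + 365 days), in canonical string
#' form. Patients with no medication in the window get `NA` (untreated;
#' excluded from recommendation training).
#'
#' @param medications medications data.frame (`patient_id`, `drug_class`,
#'   `start_date`).
#' @param indexDates named character/Date vector of index dates, named by
#'   patient id; the returned vector covers exactly these patients.
#' @param planWindow window length in days (365).
#' @return named character vector of canonical plans (or `NA`).
#' @examples
#' meds <- data.frame(patient_id = "A",
#'                    drug_class = c("Statin", "BB", "Statin"),
#'                    start_date = c("2010-01-31", "2010-01-13", "2010-10-28"))
#' plansFromMedications(meds, c(A = "2010-01-01"))  # "BB+Statin"
#' @export
plansFromMedications <- function(medications, indexDates, planWindow = 365) {
  ids <- names(indexDates)
  out <- stats::setNames(rep(NA_character_, length(ids)), ids)
  if (nrow(medications) == 0) return(out)
  bad <- setdiff(unique(medications$drug_class), drugClasses())
  if (length(bad) > 0)
    stop("unknown drug class(es) in medications: ", paste(bad, collapse = ", "))
  medDate <- parseDates(medications$start_date)
  idx <- as.Date(indexDates[medications$patient_id])
  keep <- !is.na(idx) & !is.na(medDate) &
    medDate >= idx & medDate <= idx + planWindow
  kept <- medications[keep, , drop = FALSE]
  if (nrow(kept) == 0) return(out)
  sets <- tapply(kept$drug_class, kept$patient_id,
                 function(x) canonicalPlan(unique(x)))
  out[names(sets)] <- unname(sets)
  out
}
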