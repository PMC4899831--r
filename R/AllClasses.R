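#' @import methods
NULL

#' Drug classes and medication plans
#'
#' The five drug classes considered for heart-failure medication plans:
#' ACE inhibitors (ACEI), angiotensin receptor blockers (ARB), beta-blockers
#' (BB), calcium-channel blockers (CCB) and statins. A medication plan is a
#' nonempty subset of these classes; its canonical string form is the
#' alphabetically sorted, `"+"`-joined class list, e.g. `"ACEI+BB+Statin"`.
#' There are 31 distinct plans.
#'
#' @return `drugClasses()` returns the character vector of the five class
#'   names; `allPlans()` the canonical strings of all 31 nonempty subsets.
#' @examples
#' drugClasses()
#' head(allPlans())
#' @export
drugClasses <- function() c("ACEI", "ARB", "BB", "CCB", "Statin")

#' @rdname drugClasses
#' @export
allPlans <- function() {
  cls <- drugClasses()
  n <- length(cls)
  plans <- character(0)
  for (m in seq_len(2^n - 1)) {
    members <- cls[bitwAnd(m, 2^(seq_len(n) - 1)) > 0]
    plans <- c(plans, paste(members, collapse = "+"))
  }
  sort(plans)
}

#' Canonical medication-plan string
#'
#' Canonicalizes a set of drug classes into the sorted `"+"`-joined plan
#' string. Order- and duplicate-insensitive.
#'
#' @param classes character vector of drug classes (subset of
#'   [drugClasses()]), or a single already-joined `"+"` string.
#' @return length-1 character, the canonical plan.
#' @examples
#' canonicalPlan(c("Statin", "BB", "Statin"))  # "BB+Statin"
#' @export
canonicalPlan <- function(classes) {
  if (length(classes) == 1L && grepl("+", classes, fixed = TRUE))
    classes <- strsplit(classes, "+", fixed = TRUE)[[1]]
  classes <- unique(classes)
  bad <- setdiff(classes, drugClasses())
  if (length(bad) > 0)
    stop("unknown drug class(es): ", paste(bad, collapse = ", "))
  if (length(classes) == 0)
    stop("a medication plan must contain at least one drug class")
  paste(sort(classes), collapse = "+")
}

#' Drug classes of a canonical plan
#' @param plan canonical plan string.
#' @return character vector of classes.
#' @export
planClasses <- function(plan) strsplit(plan, "+", fixed = TRUE)[[1]]

# ---- GeneratorConfig --------------------------------------------------------

#' GeneratorConfig: parameters of the synthetic heart-failure cohort generator
#'
#' Holds every parameter of the synthetic cohort simulator: sample size, seed,
#' truncated-normal specifications for the continuous variables, prevalences
#' of the 26 CCW comorbidities, the medication-plan sampling distribution, the
#' overall good-responder rate, and the planted latent-structure parameters
#' (number of latent groups, centroid separation in SD units, plan adherence
#' and the plan-match response/typicality effect).
#'
#' @slot nPatients number of patients to simulate.
#' @slot seed integer RNG seed; equal seeds give byte-identical extracts.
#' @slot continuousSpecs data.frame with columns `name`, `mean`, `sd`,
#'   `lower`, `upper` (truncation bounds); the generator moment-matches so the
#'   truncated draws attain the configured mean/SD.
#' @slot comorbidityPrevalences named numeric, 26 probabilities in `[0,1]`.
#' @slot planFrequencies named numeric over canonical plans, summing to 1;
#'   the sampling distribution used for non-adherent plan assignment.
#' @slot responderRate overall probability of a good response.
#' @slot nLatentGroups number of planted latent phenotype groups.
#' @slot groupSeparation distance between latent group centroids, in units of
#'   the configured SDs; 0 disables planted feature structure.
#' @slot planGroupCoupling probability that a patient whose drawn plan is
#'   some group's preferred plan belongs to that latent group (otherwise the
#'   group is uniform). Plans themselves are always drawn from
#'   `planFrequencies`, so plan marginals are exact.
#' @slot planMatchEffect probability uplift of good response when the
#'   assigned plan equals the group's preferred plan; also scales the
#'   phenotype-typicality linkage (see the methods vignette). 0 means no
#'   feature-plan-outcome linkage at all.
#' @slot dispersionGain continuous-noise SD multiplier for non-archetype
#'   patients is `1 + dispersionGain * planMatchEffect`.
#' @slot comorbidityBlend non-archetype comorbidity probabilities are blended
#'   toward 0.5 by `min(comorbidityBlend * planMatchEffect, 1)`.
#' @slot ineligibleFraction fraction of patients planted to fail one of the
#'   four eligibility criteria (cycled over the criteria).
#' @slot demographics named numeric: `male`, `white`, `nonhispanic`
#'   proportions.
#' @export
setClass("GeneratorConfig", representation(
  nPatients = "integer",
  seed = "integer",
  continuousSpecs = "data.frame",
  comorbidityPrevalences = "numeric",
  planFrequencies = "numeric",
  responderRate = "numeric",
  nLatentGroups = "integer",
  groupSeparation = "numeric",
  planGroupCoupling = "numeric",
  planMatchEffect = "numeric",
  dispersionGain = "numeric",
  comorbidityBlend = "numeric",
  ineligibleFraction = "numeric",
  demographics = "numeric"
))

setValidity("GeneratorConfig", function(object) {
  msg <- character(0)
  if (object@nPatients < 1) msg <- c(msg, "nPatients must be positive")
  cs <- object@continuousSpecs
  need <- c("name", "mean", "sd", "lower", "upper")
  if (!all(need %in% names(cs)))
    msg <- c(msg, "continuousSpecs needs columns name, mean, sd, lower, upper")
  else {
    if (any(cs$sd <= 0)) msg <- c(msg, "all continuous sds must be > 0")
    if (any(cs$lower >= cs$upper))
      msg <- c(msg, "continuous lower bounds must be < upper bounds")
  }
  pv <- object@comorbidityPrevalences
  if (any(pv < 0 | pv > 1))
    msg <- c(msg, sprintf("comorbidity prevalence out of [0,1]: %s",
                          paste(names(pv)[pv < 0 | pv > 1], collapse = ", ")))
  pf <- object@planFrequencies
  if (abs(sum(pf) - 1) > 1e-9)
    msg <- c(msg, "planFrequencies must sum to 1 (within 1e-9)")
  if (any(pf < 0)) msg <- c(msg, "planFrequencies must be nonnegative")
  if (!all(names(pf) %in% allPlans()))
    msg <- c(msg, "planFrequencies names must be canonical nonempty plans")
  for (fld in c("responderRate", "planGroupCoupling", "planMatchEffect",
                "ineligibleFraction")) {
    v <- slot(object, fld)
    if (v < 0 || v > 1) msg <- c(msg, sprintf("%s must be in [0,1]", fld))
  }
  if (object@groupSeparation < 0) msg <- c(msg, "groupSeparation must be >= 0")
  if (object@nLatentGroups < 1) msg <- c(msg, "nLatentGroups must be positive")
  if (!all(c("male", "white", "nonhispanic") %in% names(object@demographics)))
    msg <- c(msg, "demographics needs male, white, nonhispanic")
  if (length(msg) == 0) TRUE else msg
})

# ---- SyntheticCohort --------------------------------------------------------

#' SyntheticCohort: generated extracts plus planted ground truth
#'
#' Container returned by [generateCohort()]: the four tabular extracts
#' (`patients`, `ef_measurements`, `diagnoses`, `medications`) plus the
#' planted ground truth (latent group, preferred plan, assigned plan, true
#' response label, planted eligibility flag and failure mode per patient).
#'
#' @slot extracts named list of four data.frames.
#' @slot groundTruth data.frame, one row per patient.
#' @slot config the [GeneratorConfig-class] used.
#' @export
setClass("SyntheticCohort", representation(
  extracts = "list",
  groundTruth = "data.frame",
  config = "GeneratorConfig"
))

setValidity("SyntheticCohort", function(object) {
  need <- c("patients", "ef_measurements", "diagnoses", "medications")
  if (!all(need %in% names(object@extracts)))
    return(paste("extracts must contain", paste(need, collapse = ", ")))
  gt <- object@groundTruth
  need_gt <- c("patient_id", "latent_group", "preferred_plan", "assigned_plan",
               "true_label", "planted_eligible", "planted_failure")
  if (!all(need_gt %in% names(gt)))
    return("groundTruth is missing required columns")
  if (!setequal(gt$patient_id, object@extracts$patients$patient_id))
    return("groundTruth and patients table must cover the same patients")
  TRUE
})

# ---- EncodingSchema ---------------------------------------------------------

#' EncodingSchema: fitted feature-encoding constants
#'
#' Standardization constants and categorical level maps fitted on training
#' patients only, defining the deterministic canonical feature order:
#' continuous features (z-scored) first, then one-hot indicator columns for
#' the categorical demographics (first level alphabetically is the reference
#' and is dropped), then the 26 comorbidity flags as 0/1.
#'
#' @slot continuous data.frame with columns `name`, `mean`, `sd` (training
#'   moments used for z-scoring).
#' @slot categorical named list: variable -> character vector of observed
#'   levels (sorted; first = reference).
#' @slot flags character vector of comorbidity flag column names, in order.
#' @slot featureNames full ordered vector of the d output feature names.
#' @export
setClass("EncodingSchema", representation(
  continuous = "data.frame",
  categorical = "list",
  flags = "character",
  featureNames = "character"
))

setValidity("EncodingSchema", function(object) {
  if (any(object@continuous$sd <= 0))
    return("continuous feature with non-positive sd")
  if (anyDuplicated(object@featureNames))
    return("duplicated feature names")
  TRUE
})

# ---- ClusteringResult -------------------------------------------------------

#' ClusteringResult: labeled clusters of good responders
#'
#' Result of [clusterResponders()] (and of [mergeSmallClusters()]): a
#' partition of the clustered patients, per-cluster centroids, the label plan
#' of each cluster, size fractions relative to the clustered population, and
#' the merge log.
#'
#' @slot method one of `"kmeans"`, `"hierarchical"`, `"supervised"`.
#' @slot assignment named integer vector, patient id -> cluster index.
#' @slot centroids numeric matrix, one row per cluster (arithmetic mean of
#'   member feature vectors; recomputed after any merge).
#' @slot labelPlans character, canonical label plan per cluster.
#' @slot sizeFractions numeric, members / clustered population per cluster.
#' @slot mergeLog data.frame with columns `small_plan`, `absorbed_into`,
#'   `similarity` (plan-set Jaccard), one row per executed merge.
#' @slot features the feature matrix of clustered patients (kept so merges
#'   can recompute centroids and so the metric can be estimated).
#' @export
setClass("ClusteringResult", representation(
  method = "character",
  assignment = "integer",
  centroids = "matrix",
  labelPlans = "character",
  sizeFractions = "numeric",
  mergeLog = "data.frame",
  features = "matrix"
))

setValidity("ClusteringResult", function(object) {
  k <- nrow(object@centroids)
  if (length(object@labelPlans) != k || length(object@sizeFractions) != k)
    return("labelPlans/sizeFractions length must equal number of clusters")
  a <- object@assignment
  if (length(a) > 0 && (min(a) < 1 || max(a) > k))
    return("assignment indices out of range")
  if (is.null(names(a)) || anyDuplicated(names(a)))
    return("assignment must be named by unique patient ids")
  if (abs(sum(object@sizeFractions) - 1) > 1e-8)
    return("sizeFractions must sum to 1 (assignment is a partition)")
  TRUE
})

# ---- SPSDMatrix -------------------------------------------------------------

#' SPSDMatrix: symmetric positive semi-definite similarity metric
#'
#' The matrix S of the generalized Mahalanobis distance
#' \eqn{d_S(x, C) = \sqrt{(x-\mu)^T S (x-\mu)}}. Validity enforces symmetry
#' (max asymmetry below 1e-10) and positive semi-definiteness (smallest
#' eigenvalue above -1e-8).
#'
#' @slot matrix d x d numeric matrix.
#' @slot provenance one of `"identity"`, `"pooled_inverse_covariance"`,
#'   `"per_cluster_inverse_covariance"`.
#' @slot shrinkageLambda shrinkage weight in `[0,1]` used when inverting an
#'   estimated covariance.
#' @export
setClass("SPSDMatrix", representation(
  matrix = "matrix",
  provenance = "character",
  shrinkageLambda = "numeric"
))

setValidity("SPSDMatrix", function(object) {
  M <- object@matrix
  if (nrow(M) != ncol(M)) return("matrix must be square")
  if (max(abs(M - t(M))) > 1e-10) return("matrix is not symmetric (tol 1e-10)")
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    return(sprintf("matrix is not positive semi-definite (min eigenvalue %.3g)",
                   min(ev)))
  if (object@shrinkageLambda < 0 || object@shrinkageLambda > 1)
    return("shrinkageLambda must be in [0,1]")
  TRUE
})
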