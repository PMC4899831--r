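# Shared fixture builders. Everything is generated in code; no data files.

# A built cohort with planted latent structure plus its ground truth.
plantedCohort <- function(n = 600, seed = 11, separation = 8, effect = 0.5,
                          groups = 4) {
  cfg <- defaultGeneratorConfig(nPatients = n, seed = seed,
                                nLatentGroups = groups,
                                groupSeparation = separation,
                                planMatchEffect = effect)
  sc <- generateCohort(cfg)
  built <- buildCohort(cohortExtracts(sc))
  gt <- groundTruth(sc)
  rownames(gt) <- gt$patient_id
  list(cohort = built$cohort, eligibility = built$eligibility, gt = gt,
       extracts = cohortExtracts(sc), config = cfg)
}

# Minimal hand-built extracts for eligibility edge cases: one row per event.
miniExtracts <- function(patients, ef, dx, meds = NULL) {
  if (is.null(meds))
    meds <- data.frame(patient_id = character(0), drug_class = character(0),
                       start_date = character(0), stringsAsFactors = FALSE)
  list(patients = patients, ef_measurements = ef, diagnoses = dx,
       medications = meds)
}

miniPatient <- function(id, ...) {
  base <- data.frame(patient_id = id, age = 70, sex = "M", race = "White",
                     ethnicity = "NonHispanic", bmi = 28, systolic_bp = 120,
                     hemoglobin = 13, sodium = 140, cholesterol = 150,
                     lymphocytes = 1.5, diabetes = 0L, stroke_tia = 0L,
                     stringsAsFactors = FALSE)
  over <- list(...)
  base[names(over)] <- over
  base
}

# Random SPSD matrix of dimension d via A^T A (optionally rank deficient).
randomSPSD <- function(d, rankDeficient = FALSE) {
  r <- if (rankDeficient) max(1, d - 1) else d
  A <- matrix(rnorm(r * d), r, d)
  M <- crossprod(A)
  (M + t(M)) / 2
}

# Independent element-wise expansion of the generalized Mahalanobis distance.
bruteMahalanobis <- function(x, mu, M) {
  d <- length(x)
  q <- 0
  for (i in seq_len(d)) for (j in seq_len(d))
    q <- q + (x[i] - mu[i]) * M[i, j] * (x[j] - mu[j])
  sqrt(max(q, 0))
}

# Build a supervised ClusteringResult directly from plan/size specs
# (features are separated blobs so centroid bookkeeping stays sane).
supervisedFromSizes <- function(plans, sizes, d = 3, mergeThreshold = 0) {
  n <- sum(sizes)
  ids <- sprintf("m%04d", seq_len(n))
  planVec <- rep(plans, sizes)
  X <- matrix(rnorm(n * d, mean = rep(seq_along(plans), sizes) * 10), n, d,
              dimnames = list(ids, paste0("f", seq_len(d))))
  clusterResponders(X, stats::setNames(planVec, ids), method = "supervised",
                    mergeThreshold = mergeThreshold)
}
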