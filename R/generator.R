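#' @include AllClasses.R
NULL

# Moments of a truncated normal with underlying (m, s) on [a, b].
truncNormMoments <- function(m, s, a, b) {
  alpha <- (a - m) / s
  beta <- (b - m) / s
  Z <- stats::pnorm(beta) - stats::pnorm(alpha)
  pa <- stats::dnorm(alpha)
  pb <- stats::dnorm(beta)
  mu <- m + s * (pa - pb) / Z
  v <- s^2 * (1 + (alpha * pa - beta * pb) / Z - ((pa - pb) / Z)^2)
  c(mean = unname(mu), sd = unname(sqrt(max(v, 0))))
}

# Underlying (m, s) such that the truncated normal on [a, b] has the target
# mean/sd. Truncation otherwise biases hard-bounded variables (EF is capped
# below 50 by design) away from their configured moments.
truncNormParams <- function(mean, sd, lower, upper) {
  if ((mean - lower) / sd > 6 && (upper - mean) / sd > 6)
    return(c(m = mean, s = sd))
  obj <- function(p) {
    mom <- truncNormMoments(p[1], exp(p[2]), lower, upper)
    (mom["mean"] - mean)^2 / sd^2 + (mom["sd"] - sd)^2 / sd^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  c(m = fit$par[1], s = exp(fit$par[2]))
}

# Inverse-CDF sampler for the truncated normal; m and s may be vectors.
rtruncnorm <- function(n, m, s, a, b) {
  pa <- stats::pnorm(a, m, s)
  pb <- stats::pnorm(b, m, s)
  stats::qnorm(pa + stats::runif(n) * (pb - pa), m, s)
}

# Latent-group centroid offsets (groups x variables), in configured-SD units,
# centered so the grand mean is untouched; raw pairwise centroid distance is
# `separation`. Because downstream encoding z-scores each variable by its
# marginal SD (which the planted between-group variance inflates), direction
# sets that pile the separation onto few variables end up with some group
# pairs much closer after scaling. Among seeded random orthonormal candidates
# we therefore keep the set that maximizes the minimum pairwise centroid
# distance in the (approximate) post-scaling geometry.
latentOffsets <- function(nGroups, nVars, separation, withinVar = 1.5,
                          nCandidates = 64) {
  if (separation == 0 || nGroups == 1)
    return(matrix(0, nGroups, nVars))
  drawDirs <- function() {
    if (nGroups <= nVars) {
      Q <- qr.Q(qr(matrix(stats::rnorm(nVars * nVars), nVars, nVars)))
      t(Q[, seq_len(nGroups), drop = FALSE])
    } else {
      d <- matrix(stats::rnorm(nGroups * nVars), nGroups, nVars)
      d / sqrt(rowSums(d^2))
    }
  }
  best <- NULL
  bestCrit <- -Inf
  for (cand in seq_len(nCandidates)) {
    off <- separation / sqrt(2) * drawDirs()
    off <- sweep(off, 2, colMeans(off))
    b <- colMeans(off^2) - colMeans(off)^2  # population between-group var
    scl <- b + withinVar
    dmin <- Inf
    for (g in seq_len(nGroups - 1)) for (h in (g + 1):nGroups) {
      d2 <- sum((off[g, ] - off[h, ])^2 / scl)
      if (d2 < dmin) dmin <- d2
    }
    if (dmin > bestCrit) {
      bestCrit <- dmin
      best <- off
    }
  }
  best
}

#' Default synthetic-cohort generator configuration
#'
#' Returns the generator configuration calibrated to the printed cohort
#' characteristics of the heart-failure study population: continuous
#' variables (age 77 +/- 13, BMI 28.4 +/- 10.8, baseline EF 37 +/- 9.8
#' truncated below 50, hemoglobin 13 +/- 1.9, sodium 140 +/- 6.9,
#' cholesterol 155 +/- 42, lymphocytes 1.53 +/- 0.78, systolic BP
#' 121 +/- 23), the 26 CCW comorbidity prevalences, a 57% good-responder
#' rate, and plan frequencies assigning 0.17 to ACEI+BB+Statin and 0.12 to
#' ACEI+BB with the residual mass spread uniformly over the remaining 29
#' nonempty plans.
#'
#' By default no latent structure is planted (`groupSeparation = 0`,
#' `planMatchEffect = 0`) so the simulated marginals reproduce the configured
#' targets; planted-structure experiments set those parameters explicitly.
#'
#' @param nPatients cohort size (default 1386, the study cohort size).
#' @param seed integer seed.
#' @param ... named overrides for any [GeneratorConfig-class] slot.
#' @return a validated [GeneratorConfig-class].
#' @examples
#' cfg <- defaultGeneratorConfig(nPatients = 200, seed = 7)
#' cfg
#' @export
defaultGeneratorConfig <- function(nPatients = 1386, seed = 1, ...) {
  specs <- data.frame(
    name  = c("age", "bmi", "systolic_bp", "hemoglobin", "sodium",
              "cholesterol", "lymphocytes", "ef"),
    mean  = c(77, 28.4, 121, 13, 140, 155, 1.53, 37),
    sd    = c(13, 10.8, 23, 1.9, 6.9, 42, 0.78, 9.8),
    lower = c(18, 12, 60, 5, 110, 50, 0.1, 5),
    upper = c(110, 70, 220, 20, 170, 400, 6, 50),
    stringsAsFactors = FALSE
  )
  # 26 CCW chronic conditions; the four without a printed prevalence
  # (related dementia, endometrial cancer, hip/pelvic fracture, lung cancer)
  # and the blank anemia cell carry editorial defaults.
  prev <- c(
    acute_myocardial_infarction = 0.281,
    acquired_hypothyroidism = 0.159,
    alzheimers = 0.499,
    related_dementia = 0.30,
    anemia = 0.50,
    asthma = 0.09,
    atrial_fibrillation = 0.508,
    benign_prostatic_hyperplasia = 0.103,
    breast_cancer = 0.012,
    cataract = 0.282,
    chronic_kidney_disease = 0.532,
    colorectal_cancer = 0.009,
    copd = 0.249,
    depression = 0.22,
    diabetes = 0.406,
    endometrial_cancer = 0.006,
    glaucoma = 0.086,
    hip_pelvic_fracture = 0.05,
    hyperlipidemia = 0.789,
    hypertension = 0.828,
    ischemic_heart_disease = 0.712,
    lung_cancer = 0.025,
    osteoporosis = 0.127,
    prostate_cancer = 0.06,
    rheumatoid_osteoarthritis = 0.386,
    stroke_tia = 0.114
  )
  plans <- allPlans()
  pf <- stats::setNames(rep(0, length(plans)), plans)
  pf["ACEI+BB+Statin"] <- 0.17
  pf["ACEI+BB"] <- 0.12
  rest <- setdiff(plans, c("ACEI+BB+Statin", "ACEI+BB"))
  pf[rest] <- (1 - 0.17 - 0.12) / length(rest)
  args <- list(
    nPatients = as.integer(nPatients),
    seed = as.integer(seed),
    continuousSpecs = specs,
    comorbidityPrevalences = prev,
    planFrequencies = pf,
    responderRate = 0.57,
    nLatentGroups = 4L,
    groupSeparation = 0,
    planGroupCoupling = 0.9,
    planMatchEffect = 0,
    dispersionGain = 0.5,
    comorbidityBlend = 2,
    ineligibleFraction = 0.1,
    demographics = c(male = 0.65, white = 0.96, nonhispanic = 0.90)
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(args))
  if (length(bad) > 0)
    stop("unknown GeneratorConfig field(s): ", paste(bad, collapse = ", "))
  args[names(dots)] <- dots
  args$nPatients <- as.integer(args$nPatients)
  args$seed <- as.integer(args$seed)
  args$nLatentGroups <- as.integer(args$nLatentGroups)
  obj <- do.call(new, c(list("GeneratorConfig"), args))
  validObject(obj)
  obj
}

#' Preferred plan of each latent group
#'
#' Latent groups are assigned the most frequent configured plans, in
#' descending frequency (ties broken by canonical plan string).
#'
#' @param config a [GeneratorConfig-class].
#' @return character vector of canonical plans, one per latent group.
#' @export
preferredPlans <- function(config) {
  pf <- config@planFrequencies
  ord <- order(-pf, names(pf))
  names(pf)[ord][seq_len(config@nLatentGroups)]
}

#' Generate a synthetic heart-failure cohort
#'
#' Simulates the four tabular extracts (patients, EF measurements, diagnoses,
#' medications) together with the planted ground truth. Each patient draws a
#' medication plan from `planFrequencies` (so realized plan marginals are
#' exact), belongs to the plan's latent group with probability
#' `planGroupCoupling` when the plan is some group's preferred plan
#' (uniform otherwise), and gets a response label whose probability is
#' uplifted by `planMatchEffect` when the plan matches the group's preferred
#' plan (the baseline is chosen so the marginal responder rate equals
#' `responderRate`). The response label is encoded in the EF trajectory:
#' good responders gain at least 10 EF points at a follow-up measurement
#' 180-365 days after the index measurement, poor responders do not.
#' A configured fraction of patients is planted to fail one of the four
#' eligibility criteria (no 428.x code; index EF >= 50%; follow-up outside
#' the 180-450 day window; exclusion diagnosis before the HF diagnosis).
#'
#' When `planMatchEffect > 0`, patients who are not "archetypes" (matched
#' plan and good response) are phenotypically dispersed: their continuous
#' noise SD is multiplied by `1 + dispersionGain * planMatchEffect` and
#' their comorbidity probabilities blended toward 0.5. This is the planted
#' feature-plan-response linkage that makes response to the right plan
#' visible in feature space; with `planMatchEffect = 0` features carry no
#' outcome information.
#'
#' Identical configurations (including seed) produce byte-identical
#' extracts.
#'
#' @param config a valid [GeneratorConfig-class].
#' @return a [SyntheticCohort-class].
#' @examples
#' sc <- generateCohort(defaultGeneratorConfig(nPatients = 100, seed = 1))
#' sc
#' head(cohortExtracts(sc)$patients[, 1:6])
#' @export
generateCohort <- function(config) {
  validObject(config)
  n <- config@nPatients
  G <- config@nLatentGroups
  e <- config@planMatchEffect
  withr::with_seed(config@seed, {
    ids <- sprintf("P%06d", seq_len(n))
    pref <- preferredPlans(config)
    cpl <- config@planGroupCoupling

    # plans are drawn from the configured frequencies, so the realized plan
    # marginals match them exactly; the latent group is then coupled to the
    # plan (a patient on a group's preferred plan belongs to that group with
    # probability planGroupCoupling, otherwise groups are uniform)
    pf <- config@planFrequencies
    plan <- sample(names(pf), n, replace = TRUE, prob = pf)
    planGroup <- match(plan, pref)
    coupled <- !is.na(planGroup) & stats::runif(n) < cpl
    group <- sample.int(G, n, replace = TRUE)
    group[coupled] <- planGroup[coupled]
    match <- plan == pref[group]

    # response: P(match) computed exactly from the config so the marginal
    # responder rate equals responderRate in expectation
    pMatch <- sum(pf[pref]) * (cpl + (1 - cpl) / G)
    p0 <- config@responderRate - e * pMatch
    pGood <- pmin(pmax(p0 + e * match, 0), 1)
    good <- stats::runif(n) < pGood
    arche <- good & match
    kappa <- 1 + config@dispersionGain * e

    # planted eligibility failures, cycled over the four criteria
    nFail <- floor(n * config@ineligibleFraction)
    failIds <- sort(sample.int(n, nFail))
    failMode <- integer(n)
    failMode[failIds] <- rep_len(1:4, nFail)

    # continuous variables: moment-matched truncated normals with latent
    # group offsets (in configured-SD units) and atypicality dispersion
    specs <- config@continuousSpecs
    off <- latentOffsets(G, nrow(specs), config@groupSeparation)
    cont <- matrix(NA_real_, n, nrow(specs),
                   dimnames = list(ids, specs$name))
    sMult <- ifelse(arche, 1, kappa)
    for (j in seq_len(nrow(specs))) {
      par <- truncNormParams(specs$mean[j], specs$sd[j],
                             specs$lower[j], specs$upper[j])
      mj <- par["m"] + off[group, j] * specs$sd[j]
      cont[, j] <- rtruncnorm(n, mj, par["s"] * sMult,
                              specs$lower[j], specs$upper[j])
    }
    # planted criterion-2 failures: index EF drawn at/above 50
    if ("ef" %in% specs$name) {
      i2 <- failMode == 2
      cont[i2, "ef"] <- stats::runif(sum(i2), 50, 65)
    }

    # comorbidity flags; non-archetypes blended toward 0.5 when e > 0
    prev <- config@comorbidityPrevalences
    blend <- min(config@comorbidityBlend * e, 1)
    flags <- matrix(0L, n, length(prev), dimnames = list(ids, names(prev)))
    for (j in seq_along(prev)) {
      pj <- rep(prev[j], n)
      pj[!arche] <- pj[!arche] + (0.5 - pj[!arche]) * blend
      flags[, j] <- as.integer(stats::runif(n) < pj)
    }

    dem <- config@demographics
    sex <- ifelse(stats::runif(n) < dem["male"], "M", "F")
    race <- ifelse(stats::runif(n) < dem["white"], "White", "Other")
    ethnicity <- ifelse(stats::runif(n) < dem["nonhispanic"],
                        "NonHispanic", "Hispanic")

    # event dates (ISO-8601); HF diagnosis anchors the timeline
    diagDate <- as.Date("2005-01-01") +
      sample.int(2922, n, replace = TRUE) - 1L  # through 2012-12-31
    efIndexOffset <- sample.int(31, n, replace = TRUE) - 1L  # 0..30 days
    efIndexDate <- diagDate + efIndexOffset
    fuOffset <- integer(n)
    fuOffset[good] <- 180L + sample.int(186, sum(good), replace = TRUE) - 1L
    fuOffset[!good] <- 180L + sample.int(271, sum(!good), replace = TRUE) - 1L
    fuOffset[failMode == 3] <- 500L  # outside the 180-450 day window
    delta <- numeric(n)
    delta[good] <- stats::runif(sum(good), 10.5, 25)
    delta[!good] <- stats::runif(sum(!good), -8, 8)
    # EF values are reported at 1 decimal; clamp so the planted index EF
    # stays strictly below 50 after rounding
    efIndex <- round(cont[, "ef"], 1)
    efIndex[failMode != 2] <- pmin(efIndex[failMode != 2], 49.9)
    efFollow <- round(pmin(pmax(efIndex + delta, 1), 95), 1)
    # keep planted poor responders below the +10 threshold after clamping
    efFollow[!good] <- pmin(efFollow[!good], efIndex[!good] + 9.5)

    patients <- data.frame(
      patient_id = ids, age = round(cont[, "age"], 1), sex = sex,
      race = race, ethnicity = ethnicity,
      bmi = round(cont[, "bmi"], 1),
      systolic_bp = round(cont[, "systolic_bp"], 1),
      hemoglobin = round(cont[, "hemoglobin"], 2),
      sodium = round(cont[, "sodium"], 1),
      cholesterol = round(cont[, "cholesterol"], 1),
      lymphocytes = round(cont[, "lymphocytes"], 3),
      stringsAsFactors = FALSE
    )
    patients <- cbind(patients, as.data.frame(flags))
    rownames(patients) <- NULL

    ef_measurements <- data.frame(
      patient_id = rep(ids, 2),
      date = format(c(efIndexDate, efIndexDate + fuOffset)),
      ef = c(efIndex, efFollow),
      stringsAsFactors = FALSE
    )
    ef_measurements <- ef_measurements[order(ef_measurements$patient_id,
                                             ef_measurements$date), ]
    rownames(ef_measurements) <- NULL

    hfCode <- sample(c("428.0", "428.1", "428.9"), n, replace = TRUE)
    hfCode[failMode == 1] <- "401.9"  # hypertension, not HF: criterion 1 fails
    diagnoses <- data.frame(
      patient_id = ids, date = format(diagDate), code = hfCode,
      stringsAsFactors = FALSE
    )
    i4 <- failMode == 4
    if (any(i4)) {
      diagnoses <- rbind(diagnoses, data.frame(
        patient_id = ids[i4], date = format(diagDate[i4] - 100L),
        code = "425.4", stringsAsFactors = FALSE  # cardiomyopathy before HF
      ))
    }
    diagnoses <- diagnoses[order(diagnoses$patient_id, diagnoses$date), ]
    rownames(diagnoses) <- NULL

    planList <- lapply(plan, planClasses)
    nMeds <- lengths(planList)
    medOffsets <- sample.int(301, sum(nMeds), replace = TRUE) - 1L
    medications <- data.frame(
      patient_id = rep(ids, nMeds),
      drug_class = unlist(planList),
      start_date = format(rep(efIndexDate, nMeds) + medOffsets),
      stringsAsFactors = FALSE
    )
    medications <- medications[order(medications$patient_id,
                                     medications$drug_class), ]
    rownames(medications) <- NULL

    gt <- data.frame(
      patient_id = ids,
      latent_group = group,
      preferred_plan = pref[group],
      assigned_plan = plan,
      true_label = ifelse(good, "good", "poor"),
      planted_eligible = failMode == 0L,
      planted_failure = ifelse(failMode == 0L, "none",
                               as.character(failMode)),
      stringsAsFactors = FALSE
    )
  })
  new("SyntheticCohort",
      extracts = list(patients = patients,
                      ef_measurements = ef_measurements,
                      diagnoses = diagnoses,
                      medications = medications),
      groundTruth = gt,
      config = config)
}

#' Write / read the cohort extracts as CSV
#'
#' Writes the four extracts (plus `ground_truth.csv` for synthetic cohorts)
#' as RFC-4180 CSV with ISO-8601 dates; `readCohortExtracts()` reads them
#' back losslessly.
#'
#' @param x a [SyntheticCohort-class] or a named list of the four extract
#'   data.frames.
#' @param dir output directory (created if missing).
#' @return `writeCohortExtracts()` returns the directory invisibly;
#'   `readCohortExtracts()` returns a named list of data.frames.
#' @export
writeCohortExtracts <- function(x, dir) {
  if (is(x, "SyntheticCohort")) {
    tabs <- c(x@extracts, list(ground_truth = x@groundTruth))
  } else tabs <- x
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(tabs)) {
    utils::write.csv(tabs[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE, quote = TRUE)
  }
  invisible(dir)
}

#' @rdname writeCohortExtracts
#' @export
readCohortExtracts <- function(dir) {
  need <- c("patients", "ef_measurements", "diagnoses", "medications")
  out <- list()
  for (nm in need) {
    f <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(f)) stop("missing extract: ", f)
    out[[nm]] <- utils::read.csv(f, stringsAsFactors = FALSE,
                                 colClasses = "character")
  }
  out$patients <- utils::type.convert(out$patients, as.is = TRUE)
  out$ef_measurements$ef <- as.numeric(out$ef_measurements$ef)
  gtf <- file.path(dir, "ground_truth.csv")
  if (file.exists(gtf))
    out$ground_truth <- utils::read.csv(gtf, stringsAsFactors = FALSE)
  out
}
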