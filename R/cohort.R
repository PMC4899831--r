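#' @include AllClasses.R
NULL

#' Eligibility windows and thresholds
#'
#' Bundle of the date windows and thresholds used by [applyEligibility()] and
#' [labelResponse()]. All windows are in days (calendar-month arithmetic is
#' avoided for determinism): the index EF must lie within `indexWindow` days
#' of the earliest heart-failure diagnosis, the follow-up EF within
#' `[followupMin, followupMax]` days after the index EF (closed interval),
#' and a good response requires at least `responseThreshold` EF points of
#' improvement at a follow-up within `responseWindow` days of treatment
#' initiation.
#'
#' @param indexWindow days around the HF diagnosis for the index EF (30).
#' @param followupMin,followupMax follow-up window after the index EF, in
#'   days (180, 450; i.e. 6 to 15 months).
#' @param responseWindow days after treatment initiation within which the
#'   follow-up must occur to count as a good response (365).
#' @param responseThreshold EF improvement threshold, absolute percentage
#'   points by default (10).
#' @param relativeResponse if `TRUE`, the threshold is interpreted as a
#'   relative increase: `(followup - index) / index * 100`.
#' @param hfPrefix ICD-9-CM prefix defining a heart-failure diagnosis.
#' @param exclusionPrefixes ICD-9-CM prefixes of the exclusion diagnoses
#'   (coronary artery disease, myocarditis, cardiomyopathy, aortic/mitral
#'   stenosis); no single canonical code list exists for these named
#'   conditions, so this default set is a documented editorial choice.
#' @param initiationFromMedication if `TRUE`, treatment initiation is the
#'   earliest medication start date instead of the index EF date.
#' @return a named list.
#' @export
eligibilityWindows <- function(indexWindow = 30,
                               followupMin = 180,
                               followupMax = 450,
                               responseWindow = 365,
                               responseThreshold = 10,
                               relativeResponse = FALSE,
                               hfPrefix = "428",
                               exclusionPrefixes = c("414", "422", "429.0",
                                                     "425", "424.1", "394.0",
                                                     "396"),
                               initiationFromMedication = FALSE) {
  list(indexWindow = indexWindow, followupMin = followupMin,
       followupMax = followupMax, responseWindow = responseWindow,
       responseThreshold = responseThreshold,
       relativeResponse = relativeResponse, hfPrefix = hfPrefix,
       exclusionPrefixes = exclusionPrefixes,
       initiationFromMedication = initiationFromMedication)
}

parseDates <- function(x) {
  d <- as.Date(x, format = "%Y-%m-%d")
  d[is.na(x) | x == ""] <- NA
  d
}

codeMatchesPrefix <- function(code, prefixes) {
  hit <- rep(FALSE, length(code))
  for (p in prefixes) hit <- hit | startsWith(code, p)
  hit
}

#' Apply the four cohort eligibility criteria
#'
#' Evaluates, per patient: (1) any diagnosis with the heart-failure ICD-9
#' prefix (428.x); (2) an EF measurement below 50% within `indexWindow` days
#' of the earliest HF diagnosis (the earliest such, ties by value, is the
#' index EF); (3) another EF measurement 180-450 days after the index EF
#' (earliest in window is the follow-up EF); (4) no exclusion diagnosis
#' strictly before the HF diagnosis date. Records with malformed dates or
#' codes are collected as invalid, never silently dropped.
#'
#' @param extracts named list with `patients`, `ef_measurements`,
#'   `diagnoses`, `medications` data.frames (see [readCohortExtracts()]).
#' @param windows an [eligibilityWindows()] list.
#' @return data.frame with one row per patient: `patient_id`, `status`
#'   (`eligible` / `ineligible` / `invalid`), `eligible` (logical),
#'   `failed_criteria` (comma-joined subset of `1,2,3,4,incomplete_data`),
#'   index/follow-up EF dates and values, and `validation_error`.
#' @examples
#' sc <- generateCohort(defaultGeneratorConfig(nPatients = 60, seed = 2))
#' el <- applyEligibility(cohortExtracts(sc), eligibilityWindows())
#' table(el$status)
#' @export
applyEligibility <- function(extracts, windows = eligibilityWindows()) {
  pts <- extracts$patients
  ef <- extracts$ef_measurements
  dx <- extracts$diagnoses
  ids <- pts$patient_id
  n <- length(ids)

  efDate <- parseDates(ef$date)
  dxDate <- parseDates(dx$date)
  efBad <- is.na(efDate) | !is.finite(ef$ef) | ef$ef <= 0 | ef$ef > 100
  dxBad <- is.na(dxDate) | is.na(dx$code) | dx$code == ""
  invalidIds <- unique(c(ef$patient_id[efBad], dx$patient_id[dxBad]))

  # earliest HF diagnosis per patient
  isHF <- codeMatchesPrefix(dx$code, windows$hfPrefix) & !dxBad
  hfFirst <- tapply(as.integer(dxDate[isHF]), dx$patient_id[isHF], min)
  hfDate <- as.Date(unname(hfFirst[ids]), origin = "1970-01-01")

  # index EF: earliest EF < 50 within indexWindow days of the HF diagnosis
  efOk <- !efBad
  efPid <- ef$patient_id
  efInt <- as.integer(efDate)
  hfOfEf <- hfFirst[efPid]
  inIdx <- efOk & !is.na(hfOfEf) & ef$ef < 50 &
    abs(efInt - hfOfEf) <= windows$indexWindow
  pickEarliest <- function(keep) {
    idx <- which(keep)
    if (length(idx) == 0)
      return(data.frame(patient_id = character(0), date = integer(0),
                        ef = numeric(0)))
    o <- idx[order(efPid[idx], efInt[idx], ef$ef[idx])]
    first <- o[!duplicated(efPid[o])]
    data.frame(patient_id = efPid[first], date = efInt[first],
               ef = ef$ef[first], stringsAsFactors = FALSE)
  }
  idxTab <- pickEarliest(inIdx)
  idxDate <- stats::setNames(idxTab$date, idxTab$patient_id)[ids]
  idxEf <- stats::setNames(idxTab$ef, idxTab$patient_id)[ids]

  # follow-up EF: earliest in [followupMin, followupMax] days after index
  idxOfEf <- idxDate[match(efPid, ids)]
  gap <- efInt - idxOfEf
  inFu <- efOk & !is.na(idxOfEf) & gap >= windows$followupMin &
    gap <= windows$followupMax
  fuTab <- pickEarliest(inFu)
  fuDate <- stats::setNames(fuTab$date, fuTab$patient_id)[ids]
  fuEf <- stats::setNames(fuTab$ef, fuTab$patient_id)[ids]

  # exclusion diagnoses strictly before the HF diagnosis
  isExcl <- codeMatchesPrefix(dx$code, windows$exclusionPrefixes) & !dxBad
  hfOfDx <- hfFirst[dx$patient_id]
  exclBefore <- isExcl & !is.na(hfOfDx) & as.integer(dxDate) < hfOfDx
  exclIds <- unique(dx$patient_id[exclBefore])

  # complete-case requirement on every modeling feature column
  present <- setdiff(names(pts), "patient_id")
  incomplete <- rowSums(is.na(pts[, present, drop = FALSE]) |
                          pts[, present, drop = FALSE] == "") > 0

  # criteria anchored on a missing prerequisite (no HF diagnosis, no index
  # EF) are indeterminate and not reported as separate failures
  failed <- vector("list", n)
  for (i in seq_len(n)) {
    f <- character(0)
    if (is.na(hfDate[i])) {
      f <- c(f, "1")
    } else if (is.na(idxEf[i])) {
      f <- c(f, "2")
    } else if (is.na(fuEf[i])) {
      f <- c(f, "3")
    }
    if (!is.na(hfDate[i]) && ids[i] %in% exclIds) f <- c(f, "4")
    if (incomplete[i]) f <- c(f, "incomplete_data")
    failed[[i]] <- f
  }
  isInvalid <- ids %in% invalidIds
  eligible <- lengths(failed) == 0 & !isInvalid
  status <- ifelse(isInvalid, "invalid",
                   ifelse(eligible, "eligible", "ineligible"))
  valErr <- ifelse(isInvalid, "malformed date/code/EF in event tables", "")

  data.frame(
    patient_id = ids,
    status = unname(status),
    eligible = unname(eligible),
    failed_criteria = unname(vapply(failed, paste, "", collapse = ",")),
    index_ef_date = unname(format(as.Date(idxDate, origin = "1970-01-01"))),
    index_ef = unname(idxEf),
    followup_ef_date = unname(format(as.Date(fuDate, origin = "1970-01-01"))),
    followup_ef = unname(fuEf),
    validation_error = unname(valErr),
    stringsAsFactors = FALSE
  )
}

#' Label therapy response from the EF trajectory
#'
#' A patient has a good response if the follow-up EF exceeds the index EF by
#' at least `responseThreshold` (absolute percentage points by default) and
#' the follow-up falls within `responseWindow` days of treatment initiation
#' (default: the index EF date; optionally the earliest medication start).
#'
#' @param eligibility data.frame from [applyEligibility()]; only eligible
#'   rows are labeled (calling on ineligible rows is an error).
#' @param windows an [eligibilityWindows()] list.
#' @param medications optional medications table, required when
#'   `initiationFromMedication` is set.
#' @return data.frame: `patient_id`, `label` (`good`/`poor`), `ef_delta`.
#' @examples
#' sc <- generateCohort(defaultGeneratorConfig(nPatients = 60, seed = 2))
#' el <- applyEligibility(cohortExtracts(sc))
#' lab <- labelResponse(el[el$eligible, ])
#' table(lab$label)
#' @export
labelResponse <- function(eligibility, windows = eligibilityWindows(),
                          medications = NULL) {
  if (!all(eligibility$eligible))
    stop("labelResponse() requires eligible patients only")
  idxEf <- eligibility$index_ef
  fuEf <- eligibility$followup_ef
  delta <- if (windows$relativeResponse) {
    (fuEf - idxEf) / idxEf * 100
  } else {
    fuEf - idxEf
  }
  init <- as.Date(eligibility$index_ef_date)
  if (windows$initiationFromMedication) {
    if (is.null(medications))
      stop("medications table required for initiationFromMedication")
    medDate <- parseDates(medications$start_date)
    first <- tapply(as.integer(medDate), medications$patient_id, min,
                    na.rm = TRUE)
    medInit <- as.Date(unname(first[eligibility$patient_id]),
                       origin = "1970-01-01")
    init[!is.na(medInit)] <- medInit[!is.na(medInit)]
  }
  inWindow <- as.integer(as.Date(eligibility$followup_ef_date) - init) <=
    windows$responseWindow
  good <- delta >= windows$responseThreshold & inWindow
  data.frame(patient_id = eligibility$patient_id,
             label = ifelse(good, "good", "poor"),
             ef_delta = delta, stringsAsFactors = FALSE)
}

#' Build the analysis cohort from raw extracts
#'
#' Runs [applyEligibility()], labels responses for the eligible patients,
#' extracts each eligible patient's medication plan over the treatment
#' window, and joins the patient features into a single analysis table.
#' Patients with no medication in the window are retained with `plan = NA`
#' (they are excluded from recommendation training downstream).
#'
#' @param extracts named list of the four extract data.frames.
#' @param windows an [eligibilityWindows()] list.
#' @param planWindow days after the index EF date within which medication
#'   starts define the plan (365).
#' @return list with `cohort` (one row per eligible patient: features,
#'   `index_ef`, `ef_delta`, `response`, `plan`), `exclusions` (per-patient
#'   failed criteria for the non-eligible), and `eligibility` (the full
#'   [applyEligibility()] table).
#' @examples
#' sc <- generateCohort(defaultGeneratorConfig(nPatients = 80, seed = 3))
#' built <- buildCohort(cohortExtracts(sc))
#' table(built$cohort$response)
#' @export
buildCohort <- function(extracts, windows = eligibilityWindows(),
                        planWindow = 365) {
  el <- applyEligibility(extracts, windows)
  elig <- el[el$eligible, , drop = FALSE]
  lab <- labelResponse(elig, windows, extracts$medications)
  plans <- plansFromMedications(extracts$medications,
                                stats::setNames(elig$index_ef_date,
                                                elig$patient_id),
                                planWindow = planWindow)
  cohort <- merge(extracts$patients, elig[, c("patient_id", "index_ef",
                                              "index_ef_date")],
                  by = "patient_id")
  cohort <- merge(cohort, lab, by = "patient_id")
  cohort$plan <- unname(plans[cohort$patient_id])
  names(cohort)[names(cohort) == "label"] <- "response"
  cohort <- cohort[order(cohort$patient_id), ]
  rownames(cohort) <- NULL
  exclusions <- el[!el$eligible,
                   c("patient_id", "status", "failed_criteria",
                     "validation_error"), drop = FALSE]
  rownames(exclusions) <- NULL
  list(cohort = cohort, exclusions = exclusions, eligibility = el)
}
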