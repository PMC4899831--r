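#' @include AllClasses.R
NULL

#' Repeated seeded stratified train/test splits
#'
#' Generates `nRuns` independent random splits, stratified on the response
#' label so each run preserves the responder fraction. The train size is
#' `round(n * trainFraction)` exactly, allocated across strata by largest
#' remainder (so a 1386-patient cohort at 0.7 always splits 970 / 416).
#' Train and test are disjoint and exhaustive in every run; equal seeds give
#' identical splits.
#'
#' @param labels named character vector (patient id -> `good`/`poor`).
#' @param nRuns number of independent splits (10).
#' @param trainFraction fraction of patients used for training (0.7).
#' @param seed integer seed.
#' @return list of `nRuns` lists with elements `train` and `test` (patient
#'   id vectors).
#' @examples
#' labs <- setNames(rep(c("good", "poor"), c(790, 596)), sprintf("P%04d", 1:1386))
#' sp <- splitRuns(labs, nRuns = 2, seed = 1)
#' lengths(sp[[1]])  # 970, 416
#' @export
splitRuns <- function(labels, nRuns = 10, trainFraction = 0.7, seed = 1) {
  if (length(labels) == 0) stop("empty cohort")
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must be in (0, 1)")
  strata <- split(names(labels), labels)
  if (any(lengths(strata) < 2))
    stop("cohort too small to stratify: a response stratum has < 2 patients")
  nTrain <- floor(length(labels) * trainFraction + 0.5)
  base <- vapply(strata, function(s) floor(length(s) * trainFraction),
                 numeric(1))
  fracPart <- vapply(strata, function(s) length(s) * trainFraction,
                     numeric(1)) - base
  extra <- nTrain - sum(base)
  take <- base
  if (extra > 0) {
    ord <- order(-fracPart, names(strata))
    take[ord[seq_len(extra)]] <- take[ord[seq_len(extra)]] + 1
  }
  withr::with_seed(seed, {
    lapply(seq_len(nRuns), function(r) {
      train <- unlist(lapply(names(strata), function(g) {
        s <- strata[[g]]
        sample(s, take[g])
      }), use.names = FALSE)
      list(train = sort(train),
           test = sort(setdiff(names(labels), train)))
    })
  })
}

#' Score a recommendation against the observed plan and response
#'
#' The binary outcome is 1 when the patient was a good responder AND the
#' recommended plan equals the observed plan (canonical string equality);
#' the continuous score is the negated distance to the winning cluster
#' (larger = more confident); the binary prediction is the plan match
#' itself. All three feed [computeMetrics()].
#'
#' @param recommendations data.frame from [recommendPlans()].
#' @param observedPlans named character vector of observed canonical plans.
#' @param responses named character vector of `good`/`poor` labels.
#' @return data.frame: `patient_id`, `outcome` (0/1), `score`, `prediction`
#'   (0/1).
#' @export
scoreRecommendations <- function(recommendations, observedPlans, responses) {
  ids <- recommendations$patient_id
  obs <- observedPlans[ids]
  resp <- responses[ids]
  if (anyNA(obs) || anyNA(resp))
    stop("every test patient needs an observed plan and response label")
  m <- recommendations$recommended_plan == obs
  data.frame(
    patient_id = ids,
    outcome = as.integer(m & resp == "good"),
    score = -recommendations$distance,
    prediction = as.integer(m),
    stringsAsFactors = FALSE
  )
}

#' Trapezoidal and rank-based AUC
#'
#' `aucTrapezoid()` traces the empirical ROC over all distinct score values
#' and integrates by the trapezoidal rule (ties handled by the diagonal
#' segment, so it equals the Mann-Whitney value exactly);
#' `aucMannWhitney()` computes the rank-sum formulation
#' \eqn{(\sum_{pos} r_i - n_1(n_1+1)/2) / (n_1 n_0)} with midranks. Both
#' require at least one positive and one negative outcome.
#'
#' @param score numeric scores, larger = more positive.
#' @param outcome 0/1 (or logical) outcomes.
#' @return AUC in `[0, 1]`.
#' @examples
#' aucTrapezoid(c(3, 2, 1), c(1, 0, 0))  # 1
#' aucMannWhitney(c(3, 2, 1), c(1, 1, 0))
#' @export
aucTrapezoid <- function(score, outcome) {
  outcome <- as.integer(outcome)
  n1 <- sum(outcome == 1)
  n0 <- sum(outcome == 0)
  if (n1 == 0 || n0 == 0)
    stop("AUC undefined: outcomes contain a single class")
  o <- order(score, decreasing = TRUE)
  s <- score[o]
  y <- outcome[o]
  # cumulative counts at each distinct threshold (descending)
  lastOfTie <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y)[lastOfTie]
  fp <- cumsum(1 - y)[lastOfTie]
  tpr <- c(0, tp / n1)
  fpr <- c(0, fp / n0)
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

#' @rdname aucTrapezoid
#' @export
aucMannWhitney <- function(score, outcome) {
  outcome <- as.integer(outcome)
  n1 <- sum(outcome == 1)
  n0 <- sum(outcome == 0)
  if (n1 == 0 || n0 == 0)
    stop("AUC undefined: outcomes contain a single class")
  r <- rank(score)
  (sum(r[outcome == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion metrics and AUC for one evaluation run
#'
#' Builds the confusion matrix of `prediction` against `outcome` and
#' reports specificity = TN/(TN+FP), sensitivity = TP/(TP+FN),
#' F1 = 2PR/(P+R), accuracy = (TP+TN)/n, and the AUC of `score` against
#' `outcome`. The AUC integrates the exact empirical ROC over all distinct
#' scores (identical to the Mann-Whitney value); `cutPoints` (score
#' percentiles, ascending, starting at 50) define the reported ROC
#' operating points only.
#'
#' @param outcome 0/1 outcomes.
#' @param score continuous scores.
#' @param prediction 0/1 predictions.
#' @param cutPoints ascending percentile cut points, first = 50.
#' @return list with `metrics` (one-row data.frame: specificity,
#'   sensitivity, f1, accuracy, auc, TP/FP/TN/FN) and `roc` (data.frame of
#'   cut point, threshold, FPR, TPR, anchored at (0,0) and (1,1)).
#' @examples
#' computeMetrics(outcome = c(1, 1, 1, 1, 0, 0, 0, 0, 0, 1),
#'                score = c(9, 8, 7, 3, 6, 2, 1, 0.5, 0.2, 5),
#'                prediction = c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0))$metrics
#' @export
computeMetrics <- function(outcome, score, prediction,
                           cutPoints = seq(50, 95, by = 5)) {
  outcome <- as.integer(outcome)
  prediction <- as.integer(prediction)
  if (any(diff(cutPoints) <= 0) || cutPoints[1] != 50)
    stop("cutPoints must be ascending and start at 50")
  tp <- sum(prediction == 1 & outcome == 1)
  fp <- sum(prediction == 1 & outcome == 0)
  tn <- sum(prediction == 0 & outcome == 0)
  fn <- sum(prediction == 0 & outcome == 1)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0)
    2 * prec * sens / (prec + sens) else NA_real_
  acc <- (tp + tn) / length(outcome)
  auc <- aucTrapezoid(score, outcome)
  thr <- stats::quantile(score, probs = cutPoints / 100, names = FALSE,
                         type = 7)
  n1 <- sum(outcome == 1)
  n0 <- sum(outcome == 0)
  roc <- data.frame(
    cut_point = c(NA, cutPoints, NA),
    threshold = c(-Inf, thr, Inf),
    fpr = c(1, vapply(thr, function(t) sum(score >= t & outcome == 0) / n0,
                      numeric(1)), 0),
    tpr = c(1, vapply(thr, function(t) sum(score >= t & outcome == 1) / n1,
                      numeric(1)), 0)
  )
  list(metrics = data.frame(specificity = spec, sensitivity = sens, f1 = f1,
                            accuracy = acc, auc = auc, tp = tp, fp = fp,
                            tn = tn, fn = fn),
       roc = roc)
}

#' Medication-plan frequencies by EF interval
#'
#' Tabulates the most frequent plans within half-open index-EF bins
#' `[0,10), [10,20), [20,30), [30,40), [40,50)`. Empty bins are reported
#' with zero rows.
#'
#' @param cohort cohort data.frame with `index_ef` and `plan` columns.
#' @param binEdges ascending bin edges (default `seq(0, 50, 10)`).
#' @param topN plans reported per bin (5).
#' @return data.frame: `ef_bin`, `plan`, `count`, `rank`.
#' @examples
#' sc <- generateCohort(defaultGeneratorConfig(nPatients = 300, seed = 6))
#' cohort <- buildCohort(cohortExtracts(sc))$cohort
#' head(planFrequencyByEF(cohort))
#' @export
planFrequencyByEF <- function(cohort, binEdges = seq(0, 50, 10), topN = 5) {
  keep <- !is.na(cohort$plan) & !is.na(cohort$index_ef)
  co <- cohort[keep, , drop = FALSE]
  labs <- sprintf("[%g,%g)", binEdges[-length(binEdges)], binEdges[-1])
  bin <- cut(co$index_ef, breaks = binEdges, right = FALSE, labels = labs)
  out <- NULL
  for (b in labs) {
    plans <- co$plan[!is.na(bin) & bin == b]
    if (length(plans) == 0) next
    tab <- sort(table(plans), decreasing = TRUE)
    top <- utils::head(names(tab)[order(-as.numeric(tab), names(tab))], topN)
    out <- rbind(out, data.frame(ef_bin = b, plan = top,
                                 count = as.numeric(tab[top]),
                                 rank = seq_along(top),
                                 stringsAsFactors = FALSE))
  }
  if (is.null(out))
    out <- data.frame(ef_bin = character(0), plan = character(0),
                      count = numeric(0), rank = integer(0))
  out
}

#' End-to-end cross-validated evaluation of the recommendation pipeline
#'
#' Reproduces the study's validation protocol: `nRuns` repeated seeded
#' stratified 70/30 splits; per run, the encoding schema is fitted on the
#' training patients, good responders are clustered by each requested
#' method (supervised clusters are merged at the 5% threshold), the SPSD
#' metric is estimated, every test patient receives a recommendation, and
#' specificity / sensitivity / F1 / accuracy / AUC are computed from the
#' plan-match outcome. Metrics are averaged over runs (with SDs).
#'
#' @param cohort cohort data.frame from [buildCohort()] (rows with missing
#'   plans are dropped with a message).
#' @param methods subset of `c("supervised", "hierarchical", "kmeans")`.
#' @param k clusters for the unsupervised methods (7).
#' @param nRuns number of repeated splits (10).
#' @param trainFraction training fraction (0.7).
#' @param cutPoints ROC cut points (score percentiles from 50).
#' @param seed integer master seed; run r uses `seed + r` for clustering.
#' @param mergeThreshold small-cluster threshold (0.05).
#' @param provenance metric provenance for [estimateSimilarityMetric()].
#' @param shrinkageLambda covariance shrinkage (0.1).
#' @param mergeUnsupervised merge small unsupervised clusters too (FALSE).
#' @return list with `summary` (per-method mean and SD of each metric),
#'   `perRun` (per run x method metrics and confusion counts) and `roc`
#'   (per run x method operating points).
#' @examples
#' \donttest{
#' sc <- generateCohort(defaultGeneratorConfig(nPatients = 400, seed = 1,
#'                                             groupSeparation = 8,
#'                                             planMatchEffect = 0.5))
#' cohort <- buildCohort(cohortExtracts(sc))$cohort
#' ev <- evaluateMethods(cohort, methods = "kmeans", k = 4, nRuns = 2, seed = 1)
#' ev$summary
#' }
#' @export
evaluateMethods <- function(cohort,
                            methods = c("supervised", "hierarchical", "kmeans"),
                            k = 7, nRuns = 10, trainFraction = 0.7,
                            cutPoints = seq(50, 95, by = 5), seed = 1,
                            mergeThreshold = 0.05,
                            provenance = "pooled_inverse_covariance",
                            shrinkageLambda = 0.1,
                            mergeUnsupervised = FALSE) {
  methods <- match.arg(methods, c("supervised", "hierarchical", "kmeans"),
                       several.ok = TRUE)
  drop <- is.na(cohort$plan)
  if (any(drop)) {
    message(sum(drop), " untreated patient(s) without a plan dropped")
    cohort <- cohort[!drop, , drop = FALSE]
  }
  labels <- stats::setNames(cohort$response, cohort$patient_id)
  plans <- stats::setNames(cohort$plan, cohort$patient_id)
  splits <- splitRuns(labels, nRuns = nRuns, trainFraction = trainFraction,
                      seed = seed)
  perRun <- NULL
  rocAll <- NULL
  for (r in seq_len(nRuns)) {
    tr <- cohort[cohort$patient_id %in% splits[[r]]$train, , drop = FALSE]
    te <- cohort[cohort$patient_id %in% splits[[r]]$test, , drop = FALSE]
    schema <- fitSchema(tr)
    Xtr <- encodeFeatures(tr, schema)
    Xte <- encodeFeatures(te, schema)
    good <- tr$patient_id[tr$response == "good"]
    Xg <- Xtr[good, , drop = FALSE]
    for (m in methods) {
      cl <- clusterResponders(Xg, plans, method = m, k = k,
                              seed = seed + r,
                              mergeThreshold = mergeThreshold,
                              mergeUnsupervised = mergeUnsupervised)
      S <- estimateSimilarityMetric(cl, provenance,
                                    shrinkageLambda = shrinkageLambda)
      rec <- recommendPlans(Xte, cl, S)
      sc <- scoreRecommendations(rec, plans, labels)
      met <- computeMetrics(sc$outcome, sc$score, sc$prediction, cutPoints)
      perRun <- rbind(perRun, cbind(run = r, method = m, met$metrics))
      rocAll <- rbind(rocAll, cbind(run = r, method = m, met$roc))
    }
  }
  cols <- c("specificity", "sensitivity", "f1", "accuracy", "auc")
  summ <- do.call(rbind, lapply(unique(perRun$method), function(m) {
    sub <- perRun[perRun$method == m, cols, drop = FALSE]
    data.frame(method = m,
               as.list(colMeans(sub)),
               stats::setNames(as.list(vapply(sub, stats::sd, numeric(1))),
                               paste0(cols, "_sd")))
  }))
  list(summary = summ, perRun = perRun, roc = rocAll)
}
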