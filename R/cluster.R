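#' @include AllClasses.R
NULL

# k-means++ seeding (Arthur & Vassilvitskii): first center uniform, each
# subsequent center drawn with probability proportional to squared distance
# to the nearest chosen center. Uses the current RNG stream.
kmeansPPCenters <- function(X, k) {
  n <- nrow(X)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums(sweep(X, 2, X[centers[1], ])^2)
  for (j in seq_len(k - 1)) {
    if (all(d2 == 0)) {
      centers[j + 1] <- sample.int(n, 1)
    } else {
      centers[j + 1] <- sample.int(n, 1, prob = d2)
    }
    d2 <- pmin(d2, rowSums(sweep(X, 2, X[centers[j + 1], ])^2))
  }
  X[centers, , drop = FALSE]
}

planJaccard <- function(a, b) {
  sa <- planClasses(a)
  sb <- planClasses(b)
  length(intersect(sa, sb)) / length(union(sa, sb))
}

buildResult <- function(method, X, assign, plans, mergeLog = NULL) {
  k <- max(assign)
  centroids <- matrix(NA_real_, k, ncol(X),
                      dimnames = list(NULL, colnames(X)))
  for (j in seq_len(k))
    centroids[j, ] <- colMeans(X[assign == j, , drop = FALSE])
  labels <- vapply(seq_len(k), function(j)
    labelClusterPlan(plans[names(assign)[assign == j]], plans), "")
  sizes <- tabulate(assign, nbins = k)
  if (is.null(mergeLog))
    mergeLog <- data.frame(small_plan = character(0),
                           absorbed_into = character(0),
                           similarity = numeric(0), stringsAsFactors = FALSE)
  new("ClusteringResult", method = method, assignment = assign,
      centroids = centroids, labelPlans = labels,
      sizeFractions = sizes / length(assign), mergeLog = mergeLog,
      features = X)
}

#' Modal medication plan of a cluster
#'
#' Returns the most frequent plan among cluster members; ties are broken by
#' the plan's frequency in the whole training population, then by the
#' lexicographically smallest canonical string.
#'
#' @param memberPlans character vector of the members' canonical plans.
#' @param globalPlans character vector of all training patients' plans (for
#'   the tie-break).
#' @return length-1 character, the label plan.
#' @examples
#' labelClusterPlan(c("ACEI+BB", "ACEI+BB", "ACEI"), c("ACEI+BB", "ACEI"))
#' @export
labelClusterPlan <- function(memberPlans, globalPlans = memberPlans) {
  if (length(memberPlans) == 0) stop("cannot label an empty cluster")
  tab <- table(memberPlans)
  gtab <- table(globalPlans)
  cand <- names(tab)
  gfreq <- as.numeric(gtab[cand])
  gfreq[is.na(gfreq)] <- 0
  ord <- order(-as.numeric(tab), -gfreq, cand)
  cand[ord][1]
}

#' Cluster good responders by the three strategies
#'
#' Builds labeled clusters over the supplied (good-responder) patients.
#' `"kmeans"` runs Lloyd's algorithm with seeded k-means++ initialization;
#' `"hierarchical"` runs agglomerative clustering with Ward linkage
#' (`ward.D2`) on Euclidean distances of the encoded features, cut at `k`;
#' `"supervised"` forms one cluster per distinct canonical plan (each
#' cluster plan-pure, its label the defining plan) and then applies
#' [mergeSmallClusters()]. Unsupervised clusters are labeled with the modal
#' member plan via [labelClusterPlan()].
#'
#' @param X numeric feature matrix (rownames = patient ids), typically from
#'   [encodeFeatures()] restricted to good responders.
#' @param plans named character vector of canonical plans covering the rows
#'   of `X`.
#' @param method `"kmeans"`, `"hierarchical"` or `"supervised"`.
#' @param k number of clusters for the unsupervised methods (default 7;
#'   in practice selected by cross-validation).
#' @param seed integer seed for the stochastic k-means initialization.
#' @param mergeThreshold small-cluster threshold passed to
#'   [mergeSmallClusters()] for the supervised method (and for unsupervised
#'   methods when `mergeUnsupervised = TRUE`).
#' @param mergeUnsupervised also merge small unsupervised clusters.
#' @param nStart seeded k-means++ restarts; the solution with the smallest
#'   total within-cluster sum of squares is kept (10).
#' @return a [ClusteringResult-class].
#' @examples
#' sc <- generateCohort(defaultGeneratorConfig(nPatients = 200, seed = 5,
#'                                             groupSeparation = 8,
#'                                             planMatchEffect = 0.5))
#' built <- buildCohort(cohortExtracts(sc))$cohort
#' good <- built[built$response == "good" & !is.na(built$plan), ]
#' X <- encodeFeatures(good, fitSchema(good))
#' clusterResponders(X, setNames(good$plan, good$patient_id),
#'                   method = "kmeans", k = 4, seed = 1)
#' @export
clusterResponders <- function(X, plans, method = c("kmeans", "hierarchical",
                                                   "supervised"),
                              k = 7, seed = 1, mergeThreshold = 0.05,
                              mergeUnsupervised = FALSE, nStart = 10) {
  method <- match.arg(method)
  ids <- rownames(X)
  if (is.null(ids)) stop("feature matrix must have patient-id rownames")
  if (!all(ids %in% names(plans)))
    stop("every clustered patient needs a plan")
  plans <- plans[ids]
  if (anyNA(plans)) stop("every clustered patient needs a non-missing plan")

  if (method == "supervised") {
    lev <- sort(unique(plans))
    assign <- stats::setNames(match(plans, lev), ids)
    res <- buildResult(method, X, assign, plans)
    # supervised clustering yields many plan-pure clusters; the study's 5%
    # rule merges the small ones into similar-plan large ones
    return(mergeSmallClusters(res, plans, threshold = mergeThreshold))
  }

  if (k < 2) stop("k must be >= 2")
  if (nrow(unique(X)) < k)
    stop("k exceeds the number of distinct points")
  if (method == "kmeans") {
    km <- withr::with_seed(seed, {
      best <- NULL
      for (s in seq_len(nStart)) {
        fit <- tryCatch(
          stats::kmeans(X, centers = kmeansPPCenters(X, k), iter.max = 100,
                        algorithm = "Lloyd"),
          error = function(e) NULL, warning = function(w) NULL)
        if (is.null(fit) && s == nStart) {
          # persistent empty cluster: one final re-seeded attempt, else error
          fit <- stats::kmeans(X, centers = kmeansPPCenters(X, k),
                               iter.max = 100, algorithm = "Lloyd")
        }
        if (!is.null(fit) &&
            (is.null(best) || fit$tot.withinss < best$tot.withinss))
          best <- fit
      }
      best
    })
    assign <- stats::setNames(km$cluster, ids)
  } else {
    hc <- stats::hclust(stats::dist(X), method = "ward.D2")
    assign <- stats::setNames(stats::cutree(hc, k = k), ids)
  }
  res <- buildResult(method, X, stats::setNames(as.integer(assign), ids),
                     plans)
  if (mergeUnsupervised)
    res <- mergeSmallClusters(res, plans, threshold = mergeThreshold)
  res
}

#' Merge small clusters into plan-similar large ones
#'
#' Implements the 5% small-cluster rule: iteratively, the smallest cluster
#' holding less than `threshold` of the clustered population is absorbed
#' into the large cluster (at or above threshold) whose label plan has
#' maximal Jaccard similarity of drug-class sets with the small cluster's
#' plan. Ties prefer a strict superset plan, then the largest cluster, then
#' the lexicographically smallest plan. Absorbed members adopt the
#' absorber's label; centroids are recomputed; every step is recorded in the
#' merge log. If no large cluster exists the smallest cluster is merged into
#' its best-Jaccard peer regardless of size (documented fallback).
#' Terminates when all clusters meet the threshold or one cluster remains.
#'
#' @param result a [ClusteringResult-class].
#' @param plans named plans of the clustered patients (only used to re-label
#'   nothing: absorbers keep their label; retained for interface symmetry).
#' @param threshold minimum size fraction (0.05).
#' @return a [ClusteringResult-class] with the merges applied.
#' @examples
#' # see the package tests for a worked small-cluster absorption example
#' @export
mergeSmallClusters <- function(result, plans = NULL, threshold = 0.05) {
  assign <- result@assignment
  labels <- result@labelPlans
  X <- result@features
  n <- length(assign)
  log <- result@mergeLog
  repeat {
    k <- length(labels)
    sizes <- tabulate(assign, nbins = k)
    frac <- sizes / n
    small <- which(frac < threshold)
    if (length(small) == 0 || k <= 1) break
    s <- small[order(sizes[small], small)][1]
    cand <- setdiff(which(frac >= threshold), s)
    if (length(cand) == 0) cand <- setdiff(seq_len(k), s)
    jac <- vapply(cand, function(j) planJaccard(labels[s], labels[j]),
                  numeric(1))
    superset <- vapply(cand, function(j)
      all(planClasses(labels[s]) %in% planClasses(labels[j])) &&
        length(planClasses(labels[j])) > length(planClasses(labels[s])),
      logical(1))
    ord <- order(-jac, -superset, -sizes[cand], labels[cand])
    target <- cand[ord][1]
    log <- rbind(log, data.frame(small_plan = labels[s],
                                 absorbed_into = labels[target],
                                 similarity = jac[ord][1],
                                 stringsAsFactors = FALSE))
    assign[assign == s] <- target
    # drop cluster s, reindex
    keep <- setdiff(seq_len(k), s)
    remap <- stats::setNames(seq_along(keep), keep)
    assign <- stats::setNames(as.integer(remap[as.character(assign)]),
                              names(assign))
    labels <- labels[keep]
  }
  k <- length(labels)
  centroids <- matrix(NA_real_, k, ncol(X),
                      dimnames = list(NULL, colnames(X)))
  for (j in seq_len(k))
    centroids[j, ] <- colMeans(X[assign == j, , drop = FALSE])
  new("ClusteringResult", method = result@method, assignment = assign,
      centroids = centroids, labelPlans = labels,
      sizeFractions = tabulate(assign, nbins = k) / n, mergeLog = log,
      features = X)
}
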