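#' @include AllClasses.R
NULL

shrinkCovariance <- function(S, lambda) {
  (1 - lambda) * S + lambda * diag(diag(S), nrow(S))
}

# identity detection enables an exact Euclidean fast path
isIdentityMatrix <- function(M) {
  nrow(M) == ncol(M) && all(M == diag(nrow(M)))
}

#' Estimate the SPSD similarity metric
#'
#' Constructs the symmetric positive semi-definite matrix S of the
#' generalized Mahalanobis distance. Provenances:
#' \describe{
#'   \item{identity}{S = I; the distance reduces to Euclidean, appropriate
#'     for the z-scored feature space.}
#'   \item{pooled_inverse_covariance}{Moore-Penrose pseudo-inverse of the
#'     shrunk pooled within-cluster covariance
#'     \eqn{(1-\lambda)\hat\Sigma + \lambda\,\mathrm{diag}(\hat\Sigma)}
#'     (the package default, \eqn{\lambda = 0.1}).}
#'   \item{per_cluster_inverse_covariance}{one shrunk inverse covariance per
#'     cluster. Distances computed under per-cluster metrics are not
#'     comparable as a single metric across clusters; a warning records the
#'     caveat.}
#' }
#' When fewer than d + 1 points are available for a covariance provenance,
#' the identity is returned with a warning.
#'
#' @param result a [ClusteringResult-class] (supplies features and the
#'   cluster assignment for within-cluster centering).
#' @param provenance metric construction, see above.
#' @param shrinkageLambda shrinkage weight in `[0,1]` (0.1).
#' @return an [SPSDMatrix-class], or a list of them (one per cluster) for
#'   the per-cluster provenance.
#' @examples
#' X <- matrix(rnorm(300), 100, 3, dimnames = list(sprintf("P%03d", 1:100),
#'                                                 c("a", "b", "c")))
#' plans <- setNames(rep(c("ACEI", "BB"), 50), rownames(X))
#' cl <- clusterResponders(X, plans, method = "supervised")
#' estimateSimilarityMetric(cl, "identity")
#' @export
estimateSimilarityMetric <- function(result,
                                     provenance = c("pooled_inverse_covariance",
                                                    "identity",
                                                    "per_cluster_inverse_covariance"),
                                     shrinkageLambda = 0.1) {
  provenance <- match.arg(provenance)
  X <- result@features
  d <- ncol(X)
  if (provenance == "identity")
    return(new("SPSDMatrix", matrix = diag(d), provenance = provenance,
               shrinkageLambda = shrinkageLambda))
  assign <- result@assignment
  if (provenance == "pooled_inverse_covariance") {
    if (nrow(X) < d + 1) {
      warning("fewer than d+1 training points; falling back to identity metric")
      return(new("SPSDMatrix", matrix = diag(d), provenance = "identity",
                 shrinkageLambda = shrinkageLambda))
    }
    Xc <- X - result@centroids[assign, , drop = FALSE]
    k <- nrow(result@centroids)
    Sigma <- crossprod(Xc) / max(nrow(X) - k, 1)
    M <- MASS::ginv(shrinkCovariance(Sigma, shrinkageLambda))
    M <- (M + t(M)) / 2
    return(new("SPSDMatrix", matrix = M, provenance = provenance,
               shrinkageLambda = shrinkageLambda))
  }
  warning("per-cluster metrics are not mutually comparable as a single ",
          "distance; rankings mix different scales")
  lapply(seq_len(nrow(result@centroids)), function(j) {
    Xj <- X[assign == j, , drop = FALSE]
    if (nrow(Xj) < d + 1) {
      M <- diag(d)
    } else {
      Xc <- sweep(Xj, 2, colMeans(Xj))
      Sigma <- crossprod(Xc) / (nrow(Xj) - 1)
      M <- MASS::ginv(shrinkCovariance(Sigma, shrinkageLambda))
      M <- (M + t(M)) / 2
    }
    new("SPSDMatrix", matrix = M, provenance = provenance,
        shrinkageLambda = shrinkageLambda)
  })
}

#' Generalized Mahalanobis distance to a cluster centroid
#'
#' Computes \eqn{d_S(x, C) = \sqrt{(x-\mu)^T S (x-\mu)}} for an SPSD matrix
#' S. Quadratic forms that are slightly negative from floating-point error
#' (above -1e-10) are clamped to zero; anything below that is an SPSD
#' violation and an error.
#'
#' @param x numeric feature vector.
#' @param mu cluster centroid, same length as `x`.
#' @param S an [SPSDMatrix-class] or a plain symmetric matrix.
#' @return nonnegative scalar distance.
#' @examples
#' S <- new("SPSDMatrix", matrix = diag(2), provenance = "identity",
#'          shrinkageLambda = 0)
#' mahalanobisDistance(c(3, 4), c(0, 0), S)  # 5
#' @export
mahalanobisDistance <- function(x, mu, S) {
  M <- if (is(S, "SPSDMatrix")) S@matrix else S
  if (length(x) != length(mu) || length(x) != nrow(M))
    stop("dimension mismatch between x, mu and S")
  diff <- x - mu
  if (isIdentityMatrix(M)) return(sqrt(sum(diff^2)))
  q <- drop(crossprod(diff, M %*% diff))
  if (q < -1e-10)
    stop(sprintf("SPSD violation: quadratic form = %.3g < -1e-10", q))
  sqrt(max(q, 0))
}

clusterDistanceMatrix <- function(X, result, S) {
  k <- nrow(result@centroids)
  D <- matrix(NA_real_, nrow(X), k,
              dimnames = list(rownames(X), NULL))
  perCluster <- is.list(S)
  for (j in seq_len(k)) {
    M <- if (perCluster) S[[j]]@matrix else
      if (is(S, "SPSDMatrix")) S@matrix else S
    diff <- sweep(X, 2, result@centroids[j, ])
    q <- if (isIdentityMatrix(M)) rowSums(diff^2) else
      rowSums((diff %*% M) * diff)
    if (any(q < -1e-10))
      stop("SPSD violation in distance computation")
    D[, j] <- sqrt(pmax(q, 0))
  }
  D
}

#' Recommend medication plans by nearest cluster
#'
#' For each patient, computes the generalized Mahalanobis distance to every
#' cluster centroid, ranks clusters by ascending distance (ties broken
#' deterministically: larger cluster first, then lexicographically smallest
#' label plan, then cluster index) and recommends the label plan of the
#' nearest cluster. The margin is the runner-up distance minus the winning
#' distance (`NA` when only one cluster exists).
#'
#' @param X numeric feature matrix of patients to score (encoded with the
#'   training schema), or a single feature vector.
#' @param result a [ClusteringResult-class] with at least one cluster.
#' @param S an [SPSDMatrix-class], plain matrix, or list of per-cluster
#'   [SPSDMatrix-class] objects.
#' @return data.frame with one row per patient: `patient_id`,
#'   `recommended_plan`, `cluster_id`, `distance`, `margin`, plus the full
#'   distance matrix as attribute `"distances"`.
#' @examples
#' X <- matrix(rnorm(200), 50, 4, dimnames = list(sprintf("P%02d", 1:50),
#'                                                letters[1:4]))
#' plans <- setNames(rep(c("ACEI", "ACEI+BB"), 25), rownames(X))
#' cl <- clusterResponders(X, plans, method = "supervised")
#' head(recommendPlans(X[1:5, ], cl, estimateSimilarityMetric(cl, "identity")))
#' @export
recommendPlans <- function(X, result, S) {
  if (is.null(dim(X))) X <- matrix(X, 1, dimnames = list("patient", NULL))
  k <- nrow(result@centroids)
  if (k < 1) stop("empty clustering")
  if (ncol(X) != ncol(result@centroids))
    stop("feature dimension does not match the clustering")
  D <- clusterDistanceMatrix(X, result, S)
  sizes <- tabulate(result@assignment, nbins = k)
  labels <- result@labelPlans
  pickOrder <- function(drow) {
    order(drow, -sizes, labels, seq_len(k))
  }
  win <- integer(nrow(X))
  second <- rep(NA_integer_, nrow(X))
  for (i in seq_len(nrow(X))) {
    o <- pickOrder(D[i, ])
    win[i] <- o[1]
    if (k > 1) second[i] <- o[2]
  }
  data.frame(
    patient_id = rownames(X),
    recommended_plan = labels[win],
    cluster_id = win,
    distance = D[cbind(seq_len(nrow(X)), win)],
    margin = if (k > 1) D[cbind(seq_len(nrow(X)), second)] -
      D[cbind(seq_len(nrow(X)), win)] else NA_real_,
    stringsAsFactors = FALSE
  ) |> structure(distances = D)
}
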