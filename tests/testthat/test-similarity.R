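identityS <- function(d) new("SPSDMatrix", matrix = diag(d),
                             provenance = "identity", shrinkageLambda = 0)

test_that("the distance reduces to its closed-form special cases", {
  expect_equal(mahalanobisDistance(c(1, 2, 3), c(1, 2, 3), identityS(3)), 0)
  expect_equal(mahalanobisDistance(c(3, 4), c(0, 0), identityS(2)), 5)
  # (1,2) under diag(2,1): q = 2*1 + 1*4 = 6
  S <- new("SPSDMatrix", matrix = diag(c(2, 1)), provenance = "identity",
           shrinkageLambda = 0)
  expect_equal(mahalanobisDistance(c(1, 2), c(0, 0), S), sqrt(6))
  expect_error(mahalanobisDistance(c(1, 2, 3), c(0, 0), identityS(2)),
               "dimension")
})

test_that("the distance matches an element-wise quadratic-form oracle", {
  withr::local_seed(7)
  for (rep in seq_len(200)) {
    d <- sample(2:6, 1)
    M <- randomSPSD(d, rankDeficient = rep %% 4 == 0)
    x <- rnorm(d)
    mu <- rnorm(d)
    expect_lt(abs(mahalanobisDistance(x, mu, M) - bruteMahalanobis(x, mu, M)),
              1e-10)
  }
})

test_that("the distance agrees with the classical Mahalanobis form", {
  # with S the inverse covariance, d_S^2 is stats::mahalanobis
  withr::local_seed(13)
  A <- matrix(rnorm(25), 5, 5)
  Sigma <- crossprod(A) + diag(5)
  M <- solve(Sigma)
  M <- (M + t(M)) / 2
  x <- rnorm(5); mu <- rnorm(5)
  expect_equal(mahalanobisDistance(x, mu, M)^2,
               unname(stats::mahalanobis(x, mu, Sigma)), tolerance = 1e-10)
})

test_that("SPSD validity rejects asymmetric and indefinite matrices", {
  expect_error(new("SPSDMatrix", matrix = matrix(c(1, 0.5, 0, 1), 2),
                   provenance = "identity", shrinkageLambda = 0),
               "symmetric")
  expect_error(new("SPSDMatrix", matrix = diag(c(1, -1)),
                   provenance = "identity", shrinkageLambda = 0),
               "semi-definite")
  # slight negative eigenvalues from floating error are tolerated
  ok <- new("SPSDMatrix", matrix = diag(c(1, -1e-9)),
            provenance = "identity", shrinkageLambda = 0)
  expect_s4_class(ok, "SPSDMatrix")
})

test_that("pooled inverse covariance recovers identity on whitened data", {
  withr::local_seed(17)
  n <- 5000; d <- 4
  X <- matrix(rnorm(n * d), n, d,
              dimnames = list(sprintf("p%04d", 1:n), paste0("f", 1:d)))
  plans <- stats::setNames(rep(c("ACEI", "BB"), n / 2), rownames(X))
  cl <- clusterResponders(X, plans, method = "supervised", mergeThreshold = 0)
  S <- estimateSimilarityMetric(cl, "pooled_inverse_covariance",
                                shrinkageLambda = 0)
  expect_equal(metricMatrix(S), diag(d), tolerance = 0.1)
  ev <- eigen(metricMatrix(S), symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8)
})

test_that("estimation falls back to the identity when data are scarce", {
  withr::local_seed(19)
  X <- matrix(rnorm(3 * 5), 3, 5, dimnames = list(c("a", "b", "c"), NULL))
  plans <- stats::setNames(rep("ACEI", 3), rownames(X))
  cl <- clusterResponders(X, plans, method = "supervised", mergeThreshold = 0)
  expect_warning(S <- estimateSimilarityMetric(cl, "pooled_inverse_covariance"),
                 "identity")
  expect_equal(metricMatrix(S), diag(5))
})

test_that("recommendation picks the nearest cluster with a Euclidean oracle", {
  withr::local_seed(23)
  cents <- rbind(c(0, 0), c(10, 0), c(0, 10))
  X <- do.call(rbind, lapply(1:3, function(g)
    sweep(matrix(rnorm(40), 20, 2), 2, cents[g, ], "+")))
  rownames(X) <- sprintf("p%03d", 1:60)
  colnames(X) <- c("f1", "f2")
  plans <- stats::setNames(rep(c("ACEI", "BB", "CCB"), each = 20), rownames(X))
  cl <- clusterResponders(X, plans, method = "supervised", mergeThreshold = 0)
  S <- identityS(2)
  x <- c(8.5, 1)  # nearest centroid 2
  rec <- recommendPlans(x, cl, S)
  euclid <- sqrt(rowSums(sweep(clusterCentroids(cl), 2, x)^2))
  expect_equal(rec$cluster_id, unname(which.min(euclid)))
  expect_equal(rec$recommended_plan,
               clusterPlans(cl)[which.min(euclid)])
  expect_equal(rec$distance, min(euclid), tolerance = 1e-12)
  expect_equal(rec$margin, sort(euclid)[2] - min(euclid), tolerance = 1e-12)
  # a point at a centroid has distance zero
  rec0 <- recommendPlans(clusterCentroids(cl)[3, ], cl, S)
  expect_equal(rec0$distance, 0)
  expect_equal(rec0$recommended_plan, clusterPlans(cl)[3])
})

test_that("single-cluster recommendation returns its plan with NA margin", {
  withr::local_seed(29)
  X <- matrix(rnorm(20), 10, 2, dimnames = list(sprintf("p%02d", 1:10), NULL))
  plans <- stats::setNames(rep("ACEI+BB", 10), rownames(X))
  cl <- clusterResponders(X, plans, method = "supervised", mergeThreshold = 0)
  rec <- recommendPlans(c(0, 0), cl, identityS(2))
  expect_equal(rec$recommended_plan, "ACEI+BB")
  expect_true(is.na(rec$margin))
})

test_that("equidistant ties resolve to the larger cluster", {
  X <- rbind(a1 = c(-1, 0), a2 = c(-3, 0), a3 = c(-2, 1), a4 = c(-2, -1),
             b1 = c(2.5, 0), b2 = c(1.5, 0))
  colnames(X) <- c("f1", "f2")
  plans <- stats::setNames(c(rep("Statin", 4), rep("ACEI", 2)), rownames(X))
  cl <- clusterResponders(X, plans, method = "supervised", mergeThreshold = 0)
  # centroids at (-2, 0) and (2, 0); origin is equidistant
  rec <- recommendPlans(c(0, 0), cl, identityS(2))
  expect_equal(rec$recommended_plan, "Statin")  # the 4-member cluster
})

test_that("sqrt vs raw quadratic form cannot change any ranking", {
  withr::local_seed(31)
  for (rep in 1:20) {
    d <- 4
    M <- randomSPSD(d)
    cents <- matrix(rnorm(5 * d), 5, d)
    x <- rnorm(d)
    q <- apply(cents, 1, function(mu)
      drop(crossprod(x - mu, M %*% (x - mu))))
    expect_identical(order(sqrt(q)), order(q))
  }
})

test_that("per-cluster metrics are supported but flagged", {
  withr::local_seed(37)
  X <- matrix(rnorm(400), 100, 4,
              dimnames = list(sprintf("p%03d", 1:100), paste0("f", 1:4)))
  plans <- stats::setNames(rep(c("ACEI", "BB"), 50), rownames(X))
  cl <- clusterResponders(X, plans, method = "supervised", mergeThreshold = 0)
  expect_warning(Sl <- estimateSimilarityMetric(cl,
                   "per_cluster_inverse_covariance"), "not mutually comparable")
  expect_length(Sl, 2)
  rec <- recommendPlans(X[1:5, ], cl, Sl)
  expect_equal(nrow(rec), 5)
  expect_true(all(rec$distance >= 0))
})
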