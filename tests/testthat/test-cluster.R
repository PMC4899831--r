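blobs <- function(n = 60, g = 3, d = 4, sep = 10, seed = 1) {
  withr::with_seed(seed, {
    grp <- rep(seq_len(g), each = n)
    X <- matrix(rnorm(n * g * d), n * g, d) + sep * (grp %o% rep(1, d)) / sqrt(d)
    rownames(X) <- sprintf("b%04d", seq_len(n * g))
    colnames(X) <- paste0("f", seq_len(d))
    list(X = X, grp = grp)
  })
}

test_that("well-separated planted blobs are recovered exactly", {
  skip_if_not_installed("mclust")
  b <- blobs()
  plans <- stats::setNames(rep(c("ACEI", "BB", "Statin"), each = 60),
                           rownames(b$X))
  for (m in c("kmeans", "hierarchical")) {
    cl <- clusterResponders(b$X, plans, method = m, k = 3, seed = 2)
    expect_equal(mclust::adjustedRandIndex(clusterAssignment(cl), b$grp), 1,
                 label = m)
    # modal labeling: each recovered blob is plan-pure here
    expect_setequal(clusterPlans(cl), c("ACEI", "BB", "Statin"))
  }
})

test_that("k-means is deterministic given the seed", {
  b <- blobs(n = 30)
  plans <- stats::setNames(rep("ACEI", nrow(b$X)), rownames(b$X))
  c1 <- clusterResponders(b$X, plans, method = "kmeans", k = 3, seed = 7)
  c2 <- clusterResponders(b$X, plans, method = "kmeans", k = 3, seed = 7)
  expect_identical(clusterAssignment(c1), clusterAssignment(c2))
  expect_identical(clusterCentroids(c1), clusterCentroids(c2))
})

test_that("degenerate k equal to n gives zero within-cluster variance", {
  withr::with_seed(5, {
    X <- matrix(rnorm(24), 8, 3, dimnames = list(letters[1:8], NULL))
  })
  plans <- stats::setNames(rep("BB", 8), letters[1:8])
  cl <- clusterResponders(X, plans, method = "kmeans", k = 8, seed = 1)
  wss <- sum((X[names(clusterAssignment(cl)), ] -
                clusterCentroids(cl)[clusterAssignment(cl), ])^2)
  expect_equal(wss, 0)
  expect_error(clusterResponders(X, plans, method = "kmeans", k = 9, seed = 1),
               "distinct")
})

test_that("supervised clustering is one plan-pure cluster per plan", {
  res <- supervisedFromSizes(c("ACEI", "ACEI+BB"), c(40, 60))
  expect_equal(nClusters(res), 2)
  expect_equal(nrow(mergeLog(res)), 0)
  expect_setequal(clusterPlans(res), c("ACEI", "ACEI+BB"))
  # 28 observed plans give 28 pre-merge clusters
  withr::with_seed(8, {
    res28 <- supervisedFromSizes(allPlans()[1:28],
                                 sample(5:15, 28, replace = TRUE))
  })
  expect_equal(nClusters(res28), 28)
  expect_setequal(clusterPlans(res28), allPlans()[1:28])
})

test_that("cluster labels are modal plans with the documented tie-breaks", {
  expect_equal(labelClusterPlan(c("ACEI+BB", "ACEI+BB", "ACEI+BB", "ACEI+BB",
                                  "ACEI+BB", "ACEI", "ACEI", "ACEI")),
               "ACEI+BB")
  # tie inside the cluster, broken by global frequency
  expect_equal(labelClusterPlan(c("ACEI", "ACEI", "BB", "BB"),
                                c(rep("ACEI", 5), rep("BB", 9))), "BB")
  # full tie falls back to the lexicographically smallest plan
  expect_equal(labelClusterPlan(c("BB", "ACEI"), c("BB", "ACEI")), "ACEI")
  expect_equal(labelClusterPlan("CCB"), "CCB")
  expect_error(labelClusterPlan(character(0)), "empty")
})

test_that("the worked small-cluster absorption merges into the superset plan", {
  res <- supervisedFromSizes(
    c("ACEI+BB+CCB+Statin", "ACEI+BB", "ACEI+CCB+Statin"),
    c(60, 57, 3))
  merged <- mergeSmallClusters(res, threshold = 0.05)
  log <- mergeLog(merged)
  expect_equal(nrow(log), 1)
  expect_equal(log$small_plan, "ACEI+CCB+Statin")
  expect_equal(log$absorbed_into, "ACEI+BB+CCB+Statin")
  expect_equal(log$similarity, 3 / 4)
  expect_equal(nClusters(merged), 2)
  expect_true(all(sizeFractions(merged) >= 0.05))
  # absorbed members adopt the absorber's label
  a <- clusterAssignment(merged)
  expect_equal(unname(table(a)[as.character(which(clusterPlans(merged) ==
    "ACEI+BB+CCB+Statin"))]), 63)
})

test_that("merging clusters at or above threshold is a no-op", {
  res <- supervisedFromSizes(c("ACEI", "BB+Statin"), c(50, 50))
  merged <- mergeSmallClusters(res, threshold = 0.05)
  expect_equal(nrow(mergeLog(merged)), 0)
  expect_equal(clusterPlans(merged), clusterPlans(res))
  expect_identical(clusterAssignment(merged), clusterAssignment(res))
})

test_that("randomized merges agree with brute-force best-target enumeration", {
  withr::local_seed(101)
  for (rep in seq_len(100)) {
    k <- sample(3:7, 1)
    plans <- sample(allPlans(), k)
    sizes <- sample(2:40, k, replace = TRUE)
    # ensure at least one large cluster most of the time
    sizes[sample.int(k, 1)] <- 60
    res <- supervisedFromSizes(plans, sizes)
    # cluster indices follow the sorted plan order
    lev <- sort(plans)
    sizes <- sizes[match(lev, plans)]
    plans <- lev
    frac <- sizes / sum(sizes)
    small <- which(frac < 0.05)
    merged <- mergeSmallClusters(res, threshold = 0.05)
    # postcondition: everything at threshold or a single cluster
    expect_true(min(sizeFractions(merged)) >= 0.05 ||
                  nClusters(merged) == 1)
    # partition preserved
    expect_length(clusterAssignment(merged), sum(sizes))
    expect_equal(sum(sizeFractions(merged)), 1, tolerance = 1e-12)
    if (length(small) > 0) {
      # brute-force oracle for the FIRST merge step
      jac <- function(a, b) {
        sa <- planClasses(a); sb <- planClasses(b)
        length(intersect(sa, sb)) / length(union(sa, sb))
      }
      s <- small[order(sizes[small], small)][1]
      cand <- setdiff(which(frac >= 0.05), s)
      if (length(cand) == 0) cand <- setdiff(seq_len(k), s)
      js <- vapply(cand, function(j) jac(plans[s], plans[j]), numeric(1))
      sup <- vapply(cand, function(j)
        all(planClasses(plans[s]) %in% planClasses(plans[j])) &&
          length(planClasses(plans[j])) > length(planClasses(plans[s])),
        logical(1))
      bestTarget <- cand[order(-js, -sup, -sizes[cand], plans[cand])][1]
      log <- mergeLog(merged)
      expect_equal(log$small_plan[1], plans[s])
      expect_equal(log$absorbed_into[1], plans[bestTarget])
      # merging strictly decreases the cluster count each step
      expect_lte(nrow(log), k - 1)
      expect_equal(nClusters(merged), k - nrow(log))
    }
  }
})

test_that("merging proceeds even when no cluster meets the threshold", {
  res <- supervisedFromSizes(c("ACEI", "BB", "CCB+Statin"), c(2, 2, 2),
                             mergeThreshold = 0)
  merged <- mergeSmallClusters(res, threshold = 0.5)
  expect_true(min(sizeFractions(merged)) >= 0.5 || nClusters(merged) == 1)
})

test_that("centroids are member means, recomputed after merging", {
  res <- supervisedFromSizes(c("ACEI+BB", "ACEI"), c(50, 2))
  merged <- mergeSmallClusters(res, threshold = 0.05)
  expect_equal(nClusters(merged), 1)
  expect_equal(clusterCentroids(merged)[1, ],
               colMeans(merged@features), tolerance = 1e-12)
})
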