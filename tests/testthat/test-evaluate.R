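test_that("stratified splits reproduce the printed 970/416 arithmetic", {
  labs <- stats::setNames(rep(c("good", "poor"), c(790, 596)),
                          sprintf("P%04d", 1:1386))
  sp <- splitRuns(labs, nRuns = 10, trainFraction = 0.7, seed = 4)
  for (r in seq_len(10)) {
    expect_length(sp[[r]]$train, 970)
    expect_length(sp[[r]]$test, 416)
    expect_length(intersect(sp[[r]]$train, sp[[r]]$test), 0)
    expect_setequal(c(sp[[r]]$train, sp[[r]]$test), names(labs))
    # stratification keeps the responder mix
    expect_equal(sum(labs[sp[[r]]$train] == "good"), 553)
  }
  expect_identical(sp, splitRuns(labs, nRuns = 10, trainFraction = 0.7,
                                 seed = 4))
  expect_false(identical(sp[[1]]$train, sp[[2]]$train))
})

test_that("split sizes stay exact for awkward stratum sizes", {
  # fractional parts of the strata can sum past 1; largest-remainder
  # allocation must still hit round(n * fraction) exactly
  labs <- stats::setNames(rep(c("good", "poor"), c(797, 589)),
                          sprintf("P%04d", 1:1386))
  sp <- splitRuns(labs, nRuns = 2, trainFraction = 0.7, seed = 1)
  expect_length(sp[[1]]$train, 970)
  expect_length(sp[[1]]$test, 416)
  expect_error(splitRuns(stats::setNames("good", "P1")), "stratify")
})

test_that("scoring encodes the plan-match-among-responders outcome", {
  rec <- data.frame(patient_id = c("a", "b", "c", "d"),
                    recommended_plan = c("ACEI", "ACEI", "BB", "BB"),
                    cluster_id = 1L, distance = c(1, 2, 3, 4),
                    margin = 1, stringsAsFactors = FALSE)
  plans <- c(a = "ACEI", b = "BB", c = "BB", d = "BB")
  resp <- c(a = "good", b = "good", c = "poor", d = "good")
  sc <- scoreRecommendations(rec, plans, resp)
  expect_equal(sc$outcome, c(1L, 0L, 0L, 1L))     # match&good, mismatch, poor
  expect_equal(sc$prediction, c(1L, 0L, 1L, 1L))
  expect_equal(sc$score, -c(1, 2, 3, 4))
  expect_error(scoreRecommendations(rec, plans[1:2], resp), "every test")
})

test_that("confusion metrics match hand-computed contingency arithmetic", {
  # TP=3, FP=1, TN=5, FN=1
  outcome <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  prediction <- c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0)
  score <- c(9, 8, 7, 3, 6, 5, 4, 2, 1, 0.5)
  m <- computeMetrics(outcome, score, prediction)$metrics
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 5 / 6)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$f1, 2 * (3 / 4) * (3 / 4) / (3 / 4 + 3 / 4))
  expect_equal(m[, c("tp", "fp", "tn", "fn")],
               data.frame(tp = 3L, fp = 1L, tn = 5L, fn = 1L))
})

test_that("metrics obey positive/negative exchange symmetry", {
  withr::local_seed(41)
  for (rep in 1:10) {
    outcome <- rbinom(50, 1, 0.4)
    if (length(unique(outcome)) < 2) next
    prediction <- rbinom(50, 1, 0.5)
    score <- rnorm(50)
    a <- computeMetrics(outcome, score, prediction)$metrics
    b <- computeMetrics(1 - outcome, -score, 1 - prediction)$metrics
    expect_equal(a$sensitivity, b$specificity)
    expect_equal(a$specificity, b$sensitivity)
    expect_equal(a$accuracy, b$accuracy)
  }
})

test_that("trapezoidal and rank AUC agree to 1e-9, including ties", {
  expect_equal(aucTrapezoid(c(3, 2, 1), c(1, 0, 0)), 1.0)
  withr::local_seed(43)
  for (rep in 1:50) {
    n <- sample(10:80, 1)
    score <- sample(1:8, n, replace = TRUE) + rnorm(n) * (rep %% 2)
    outcome <- rbinom(n, 1, 0.5)
    if (length(unique(outcome)) < 2) next
    expect_lt(abs(aucTrapezoid(score, outcome) -
                    aucMannWhitney(score, outcome)), 1e-9)
  }
  expect_error(aucTrapezoid(1:3, c(1, 1, 1)), "single class")
})

test_that("AUC matches an independent library implementation", {
  skip_if_not_installed("pROC")
  withr::local_seed(47)
  score <- rnorm(200)
  outcome <- rbinom(200, 1, plogis(score))
  expect_equal(aucTrapezoid(score, outcome),
               as.numeric(pROC::auc(pROC::roc(outcome, score, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("scores independent of outcomes give a chance-level AUC", {
  withr::local_seed(53)
  score <- rnorm(10000)
  outcome <- rbinom(10000, 1, 0.5)
  expect_lt(abs(aucTrapezoid(score, outcome) - 0.5), 0.02)
})

test_that("ROC operating points honor the configured cut points", {
  outcome <- rep(c(1, 0), 50)
  score <- seq(1, 100)
  r <- computeMetrics(outcome, score, rep(1, 100), cutPoints = c(50, 75))$roc
  expect_equal(nrow(r), 4)  # two cut points plus the +/-Inf anchors
  expect_equal(r$fpr[c(1, 4)], c(1, 0))
  expect_equal(r$tpr[c(1, 4)], c(1, 0))
  expect_true(all(diff(r$fpr) <= 0) && all(diff(r$tpr) <= 0))
  expect_error(computeMetrics(outcome, score, rep(1, 100),
                              cutPoints = c(60, 70)), "start at 50")
})

test_that("plan frequencies by EF bin use half-open intervals", {
  co <- data.frame(patient_id = sprintf("p%02d", 1:6),
                   index_ef = c(9.9, 10, 19.9, 20, 35, 45),
                   plan = c("ACEI", "ACEI", "BB", "BB", "ACEI", "BB"),
                   stringsAsFactors = FALSE)
  tab <- planFrequencyByEF(co)
  expect_equal(tab$count[tab$ef_bin == "[0,10)"], 1)
  expect_equal(sum(tab$count[tab$ef_bin == "[10,20)"]), 2)  # EF 10 and 19.9
  expect_equal(tab$plan[tab$ef_bin == "[40,50)"], "BB")
  # a single-plan cohort tops every nonempty bin
  co$plan <- "ACEI+BB"
  tab1 <- planFrequencyByEF(co)
  expect_true(all(tab1$plan == "ACEI+BB"))
})

test_that("the default synthetic cohort's modal plan is ACEI+BB+Statin", {
  pc <- plantedCohort(n = 1000, seed = 61, separation = 0, effect = 0)
  tab <- sort(table(pc$cohort$plan), decreasing = TRUE)
  expect_equal(names(tab)[1], "ACEI+BB+Statin")
  byEf <- planFrequencyByEF(pc$cohort)
  top2 <- byEf$plan[byEf$ef_bin == "[30,40)" & byEf$rank <= 2]
  expect_true("ACEI+BB+Statin" %in% top2)
})

test_that("the evaluation protocol is reproducible end to end", {
  pc <- plantedCohort(n = 500, seed = 67)
  ev1 <- evaluateMethods(pc$cohort, methods = c("kmeans", "supervised"),
                         k = 4, nRuns = 2, seed = 3)
  ev2 <- evaluateMethods(pc$cohort, methods = c("kmeans", "supervised"),
                         k = 4, nRuns = 2, seed = 3)
  expect_identical(ev1, ev2)
  expect_true(all(ev1$summary$auc >= 0 & ev1$summary$auc <= 1))
  nTest <- nrow(pc$cohort) - round(nrow(pc$cohort) * 0.7)
  expect_true(all(ev1$perRun$tp + ev1$perRun$fp + ev1$perRun$tn +
                    ev1$perRun$fn == nTest))
})
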