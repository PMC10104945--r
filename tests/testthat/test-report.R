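# Territory aggregation, rank AUC, Welch comparison, cohort evaluation.

test_that("the territory map partitions the 16 segments 6/5/5", {
  map <- territoryMap()
  expect_setequal(unlist(map), 1:16)
  expect_equal(lengths(map), c(LAD = 6L, CX = 5L, RCA = 5L))
  expect_setequal(map$LAD, c(1, 2, 7, 8, 13, 14))
  expect_setequal(map$CX, c(5, 6, 11, 12, 16))
  expect_setequal(map$RCA, c(3, 4, 9, 10, 15))
})

mkMetrics <- function(strain = rep(-15, 16), sr = rep(-1, 16),
                      psiV = rep(5, 16)) {
  data.frame(segmentId = 1:16, peakSystolicStrain = strain,
             peakSystolicSR = sr, psi = psiV)
}

test_that("territory means are unweighted over contributing segments", {
  m <- mkMetrics()
  m$peakSystolicStrain[territoryMap()$LAD] <- -10
  tm <- territoryMeans(m)
  expect_equal(tm$peakSystolicStrain[tm$territory == "LAD"], -10)
  # RCA = {3,4,9,10,15} with values -1..-5
  m <- mkMetrics()
  m$peakSystolicStrain[c(3, 4, 9, 10, 15)] <- c(-1, -2, -3, -4, -5)
  tm <- territoryMeans(m)
  expect_equal(tm$peakSystolicStrain[tm$territory == "RCA"], -3)
  # permuting rows changes nothing
  mp <- m[sample(16), ]
  expect_equal(territoryMeans(mp), tm)
  # missing segments are skipped and counted
  m$peakSystolicStrain[3] <- NA
  m$peakSystolicSR[3] <- NA
  m$psi[3] <- NA
  tm <- territoryMeans(m)
  expect_equal(tm$peakSystolicStrain[tm$territory == "RCA"],
               mean(c(-2, -3, -4, -5)))
  expect_equal(tm$n[tm$territory == "RCA"], 4L)
})

test_that("global means average all contributing segments", {
  expect_equal(globalMeans(mkMetrics())$peakSystolicStrain, -15)
  m <- mkMetrics(strain = c(rep(-10, 8), rep(-20, 8)))
  expect_equal(globalMeans(m)$peakSystolicStrain, -15)
  m$peakSystolicStrain[5] <- NA
  g <- globalMeans(m)
  expect_equal(g$peakSystolicStrain, mean(m$peakSystolicStrain, na.rm = TRUE))
  expect_equal(g$n, 15L)
})

test_that("rank AUC equals brute-force pair counting", {
  expect_equal(aucCI(c(3, 4, 5, 1, 2), c(TRUE, TRUE, TRUE, FALSE, FALSE),
                     nBoot = 50)$auc, 1.0)
  expect_equal(aucCI(rep(2, 6), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                     nBoot = 50)$auc, 0.5)
  expect_equal(aucCI(c(3, 1, 2, 0), c(TRUE, TRUE, FALSE, FALSE),
                     nBoot = 50)$auc, 0.75)
  expect_error(aucCI(1:4, rep(TRUE, 4), nBoot = 10), "both classes")
  set.seed(29)
  for (i in 1:40) {
    n <- sample(4:50, 1)
    labels <- c(TRUE, FALSE, runif(n - 2) > 0.5)
    scores <- round(rnorm(n), sample(0:2, 1))  # coarse rounding forces ties
    a <- aucCI(scores, labels, nBoot = 2)$auc
    expect_equal(a, oraclePairAUC(scores, labels), tolerance = 1e-12)
    # invariance under strictly monotone transforms
    expect_equal(aucCI(exp(scores / 3), labels, nBoot = 2)$auc, a,
                 tolerance = 1e-12)
  }
})

test_that("rank AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(41)
  scores <- rnorm(60)
  labels <- runif(60) > 0.6
  a <- aucCI(scores, labels, nBoot = 2)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(response = labels,
                                        predictor = scores,
                                        direction = "<", quiet = TRUE)))
  expect_equal(a, ref, tolerance = 1e-12)
})

test_that("bootstrap confidence intervals bracket the AUC and are seeded", {
  set.seed(2)
  scores <- c(rnorm(20, 1), rnorm(20))
  labels <- rep(c(TRUE, FALSE), each = 20)
  a1 <- aucCI(scores, labels, nBoot = 400, seed = 5L)
  a2 <- aucCI(scores, labels, nBoot = 400, seed = 5L)
  expect_identical(a1, a2)
  expect_lte(a1$ciLo, a1$auc)
  expect_gte(a1$ciHi, a1$auc)
})

test_that("the Welch comparison matches the closed-form formula", {
  w <- twoSampleT(c(10, 12, 14), c(11, 13))
  o <- oracleWelch(c(10, 12, 14), c(11, 13))
  expect_equal(w$t, o$t, tolerance = 1e-9)
  expect_equal(w$p, o$p, tolerance = 1e-9)
  # identical degenerate groups: t = 0, p = 1 by convention
  w <- twoSampleT(c(2, 2, 2), c(2, 2))
  expect_equal(w$t, 0)
  expect_equal(w$p, 1)
  # clear separation
  w <- twoSampleT(c(1, 2, 3), c(11, 12, 13))
  expect_gt(abs(w$t), 10)
  expect_lt(w$p, 0.001)
})

test_that("cohort evaluation separates separable metrics", {
  tab <- data.frame(
    occluded = rep(c(TRUE, FALSE), each = 6),
    good = c(rnorm(6, 10), rnorm(6, 0)),   # separable
    flat = rep(1, 12))                     # identical distributions
  ev <- evaluateCohort(tab, metrics = c("good", "flat"), nBoot = 100)
  expect_equal(ev$auc[ev$metric == "good"], 1.0)
  expect_equal(ev$auc[ev$metric == "flat"], 0.5)
})
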