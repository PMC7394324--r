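test_that("confusion tables tally with label 1 positive", {
  expect_equal(confusionCounts(c(1, 0), c(1, 0)),
               c(TP = 1L, FP = 0L, TN = 1L, FN = 0L, N = 2L))
  expect_equal(confusionCounts(c(1, 1), c(0, 0))[["FN"]], 2L)
  expect_equal(confusionCounts(c(1, 0, 1, 0), c(1, 1, 0, 0)),
               c(TP = 1L, FP = 1L, TN = 1L, FN = 1L, N = 4L))
  expect_error(confusionCounts(c(1, 0), c(1)), "equal-length")
  expect_error(confusionCounts(c(1, 2), c(1, 0)), "binary")
})

test_that("metrics evaluate their defining formulas", {
  expect_equal(computeMetrics(c(TP = 50, TN = 50, FP = 0, FN = 0)),
               c(Sn = 1, Sp = 1, Acc = 1, MCC = 1))
  m <- computeMetrics(c(TP = 70, FN = 30, TN = 80, FP = 20))
  expect_equal(m[["Sn"]], 0.70)
  expect_equal(m[["Sp"]], 0.80)
  expect_equal(m[["Acc"]], 0.75)
  expect_equal(m[["MCC"]], 5000 / sqrt(90 * 100 * 100 * 110),
               tolerance = 1e-12)
})

test_that("zero denominators define the affected metric as 0", {
  m <- computeMetrics(c(TP = 10, FN = 0, TN = 0, FP = 10))
  expect_equal(unname(m), c(1, 0, 0.5, 0))
  expect_equal(computeMetrics(c(TP = 0, FN = 0, TN = 5,
                                FP = 0))[["Sn"]], 0)
})

test_that("metrics match direct recomputation on random tables", {
  set.seed(17)
  for (i in 1:20) {
    cts <- c(TP = sample(0:40, 1), FP = sample(0:40, 1),
             TN = sample(0:40, 1), FN = sample(0:40, 1))
    if (sum(cts) == 0) cts["TN"] <- 1
    m <- computeMetrics(cts)
    tp <- cts[["TP"]]; fp <- cts[["FP"]]
    tn <- cts[["TN"]]; fn <- cts[["FN"]]
    expSn <- if (tp + fn == 0) 0 else tp / (tp + fn)
    expSp <- if (tn + fp == 0) 0 else tn / (tn + fp)
    den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    expMcc <- if (den == 0) 0 else (tn * tp - fn * fp) / den
    expect_equal(m[["Sn"]], expSn)
    expect_equal(m[["Sp"]], expSp)
    expect_equal(m[["Acc"]], (tp + tn) / sum(cts))
    expect_equal(m[["MCC"]], expMcc, tolerance = 1e-12)
  }
})

test_that("MCC obeys relabeling symmetries", {
  set.seed(23)
  for (i in 1:10) {
    truth <- sample(0:1, 30, replace = TRUE)
    pred <- sample(0:1, 30, replace = TRUE)
    if (length(unique(truth)) < 2) truth[1:2] <- c(0, 1)
    m <- computeMetrics(confusionCounts(truth, pred))[["MCC"]]
    mSwap <- computeMetrics(confusionCounts(1 - truth,
                                            1 - pred))[["MCC"]]
    mFlip <- computeMetrics(confusionCounts(truth, 1 - pred))[["MCC"]]
    expect_equal(mSwap, m, tolerance = 1e-12)
    expect_equal(mFlip, -m, tolerance = 1e-12)
  }
})

test_that("AUC equals the pairwise-comparison probability", {
  expect_equal(rocAuc(c(1, 1, 0, 0), c(4, 3, 2, 1)), 1)
  expect_equal(rocAuc(c(1, 0, 1, 0), c(2, 2, 2, 2)), 0.5)
  expect_equal(rocAuc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1)), 0.75)
  expect_error(rocAuc(c(1, 1), c(0.2, 0.3)), "both classes")

  set.seed(29)
  for (i in 1:10) {
    n <- sample(5:40, 1)
    truth <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
    scores <- round(rnorm(n), 1)  # force some ties
    expect_equal(rocAuc(truth, scores), aucOracle(truth, scores),
                 tolerance = 1e-12)
  }
})

test_that("ROC points sweep from (0,0) to (1,1)", {
  pts <- rocPoints(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1))
  expect_equal(pts$fpr[1], 0)
  expect_equal(pts$tpr[1], 0)
  expect_equal(pts$fpr[nrow(pts)], 1)
  expect_equal(pts$tpr[nrow(pts)], 1)
})

test_that("repeated k-fold CV is exhaustive, stratified, deterministic", {
  ds <- separableDataset(50, p = 6, gap = 8, seed = 8)
  cv <- cvConfig(k = 5, repeats = 3, seed = 99)
  s1 <- runKFoldCV(ds, kernel = kernelParams(gamma = 0.25), cv = cv)
  expect_s4_class(s1, "CVSummary")
  expect_equal(nrow(perRunMetrics(s1)), 3L)
  # near-perfect separation: every mean metric at 1
  expect_equal(unname(metricMeans(s1)), rep(1, 5))
  # same seed -> identical summary, bit for bit
  s2 <- runKFoldCV(ds, kernel = kernelParams(gamma = 0.25), cv = cv)
  expect_identical(perRunMetrics(s1), perRunMetrics(s2))
  expect_error(runKFoldCV(ds, cv = cvConfig(k = 60, repeats = 1)),
               "at least k")
})

test_that("label-permuted data scores at chance", {
  set.seed(41)
  ds <- randomDataset(500, 8, posFrac = 0.3, seed = 41)
  s <- runKFoldCV(ds, C = 8, kernel = kernelParams(gamma = 0.125),
                  cv = cvConfig(k = 10, repeats = 5, seed = 6))
  expect_lte(abs(mean(perRunMetrics(s)$MCC)), 0.1)
  expect_lte(abs(mean(perRunMetrics(s)$AUC) - 0.5), 0.1)
})

test_that("per-run spread brackets the reported means", {
  ds <- separableDataset(60, p = 4, gap = 1.2, seed = 15)
  s <- runKFoldCV(ds, cv = cvConfig(k = 6, repeats = 4, seed = 2))
  pr <- perRunMetrics(s)
  m <- metricMeans(s)
  for (col in c("Sn", "Sp", "Acc", "MCC", "AUC")) {
    expect_gte(m[[col]], min(pr[[col]]))
    expect_lte(m[[col]], max(pr[[col]]))
    expect_true(is.finite(sd(pr[[col]])))
  }
})

test_that("jackknife is a deterministic leave-one-out pass", {
  ds <- separableDataset(24, p = 4, gap = 8, seed = 19)
  j1 <- runJackknife(ds, kernel = kernelParams(gamma = 0.25))
  j2 <- runJackknife(ds, kernel = kernelParams(gamma = 0.25))
  expect_identical(perRunMetrics(j1), perRunMetrics(j2))
  expect_equal(j1@k, 24L)
  expect_equal(metricMeans(j1)[["Acc"]], 1)
  expect_error(runJackknife(subsetDataset(ds, 1:2)), "n >= 3")

  # LOO accuracy close to the k-fold estimate on a harder fixture
  ds2 <- separableDataset(60, p = 4, gap = 1.5, seed = 21)
  loo <- metricMeans(runJackknife(ds2))[["Acc"]]
  kf <- metricMeans(runKFoldCV(ds2, cv = cvConfig(k = 10, repeats = 5,
                                                  seed = 3)))[["Acc"]]
  expect_lte(abs(loo - kf), 0.15)
})

test_that("window-size scan re-runs the pipeline per delta", {
  bundle <- tinyBundle()
  cv <- cvConfig(k = 3, repeats = 1, seed = 1)
  tab <- windowSizeScan(bundle, deltas = 3L, C = 8,
                        kernel = kernelParams(gamma = 0.125),
                        cv = cv, knn = knnFilterConfig(k = 0))
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$dim, 24L)
  expect_error(windowSizeScan(bundle, deltas = c(3L, 4L)), "odd")
})

test_that("paired t-test honours its degenerate conventions", {
  a <- c(0.7, 0.72, 0.69, 0.71)
  expect_equal(pairedMetricTest(a, a)$p.value, 1)
  expect_equal(pairedMetricTest(a + 1, a)$p.value, 0)

  d <- c(0.02, 0.03, 0.01, 0.02, 0.02)
  b <- c(0.70, 0.71, 0.72, 0.70, 0.69)
  res <- pairedMetricTest(b + d, b)
  tExpected <- mean(d) / (sd(d) / sqrt(5))  # closed form
  expect_equal(res$t, tExpected, tolerance = 1e-12)
  expect_lt(res$p.value, 0.01)
  expect_error(pairedMetricTest(1, 1), "length >= 2")
})

test_that("CV result CSVs mirror the summary layout", {
  ds <- separableDataset(30, p = 4, gap = 4, seed = 2)
  sums <- list("3-fold" = runKFoldCV(ds, cv = cvConfig(3, 2, 1)),
               "5-fold" = runKFoldCV(ds, cv = cvConfig(5, 2, 1)))
  dir <- withr::local_tempdir()
  paths <- writeCvResults(sums, dir)
  runs <- read.csv(file.path(dir, "cv_runs.csv"))
  expect_equal(nrow(runs), 4L)
  smry <- read.csv(file.path(dir, "cv_summary.csv"))
  expect_equal(smry$scheme, c("3-fold", "5-fold"))
  expect_true(all(c("Sn", "Sp", "Acc", "MCC", "AUC") %in%
                    names(smry)))
})
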