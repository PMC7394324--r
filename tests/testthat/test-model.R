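identityScaler <- function(p) {
  structure(list(min = rep(0, p), max = rep(1, p)),
            class = "ScalerParams")
}

manualModel <- function(sv, coefs, bias, gamma = 0.03125, coef0 = 0,
                        degree = 3L, C = 512) {
  p <- ncol(sv)
  new("PolySVM", supportVectors = sv, dualCoefs = coefs, bias = bias,
      gamma = gamma, coef0 = coef0, degree = as.integer(degree),
      cost = C, scalerMin = rep(0, p), scalerMax = rep(1, p))
}

test_that("polynomial kernel follows the libsvm convention", {
  kp <- kernelParams()  # gamma = 0.03125, coef0 = 0, degree = 3
  expect_equal(polynomialKernel(c(1, 0), c(0, 1), kp), 0)
  u <- c(4, 4); v <- c(4, 4)       # <u,v> = 32
  expect_equal(polynomialKernel(u, v, kp), 1)
  u2 <- c(8, 0); v2 <- c(8, 0)     # <u,v> = 64
  expect_equal(polynomialKernel(u2, v2, kp), 8)
  expect_error(polynomialKernel(1:3, 1:2, kp), "dimension")
  expect_error(kernelParams(gamma = 0), "positive")
})

test_that("kernel is symmetric with a PSD Gram matrix for coef0 >= 0", {
  set.seed(7)
  for (i in 1:5) {
    x <- matrix(rnorm(40), 8, 5)
    kp <- kernelParams(gamma = runif(1, 0.01, 1),
                       coef0 = runif(1, 0, 2),
                       degree = sample(1:4, 1))
    G <- polynomialKernel(x, x, kp)
    expect_equal(G, t(G))
    expect_gte(min(eigen(G, symmetric = TRUE,
                         only.values = TRUE)$values), -1e-8)
  }
})

test_that("a minimal separable pair trains with correct signs", {
  ds <- new("GlycDataset",
            x = rbind(c(0, 0), c(1, 1)), y = c(0L, 1L),
            keys = data.frame(protein_id = c("a", "b"),
                              position = 1:2))
  m <- trainSVM(ds, C = 512, kernel = kernelParams(gamma = 1,
                                                   coef0 = 1))
  expect_equal(nrow(m@supportVectors), 2L)
  expect_identical(predictLabel(m, ds@x), c(0L, 1L))
  # solver KKT condition: dual coefficients sum to zero
  expect_lt(abs(sum(m@dualCoefs)), 1e-6)
  expect_true(all(abs(m@dualCoefs) <= m@cost + 1e-8))
})

test_that("training separates two-class blobs and matches libsvm", {
  ds <- separableDataset(20, p = 4, gap = 6, seed = 12)
  m <- trainSVM(ds, C = 512)
  pred <- predictLabel(m, ds@x)
  expect_gte(mean(pred == ds@y), 0.9)

  # dual route: our kernel-sum evaluation of the stored model agrees in
  # sign with the solver's own predictions on fresh points
  set.seed(13)
  xnew <- matrix(rnorm(40), 10, 4)
  xs <- applyScaler(ds@x, fitScaler(ds@x))
  fit <- e1071::svm(xs, factor(ifelse(ds@y == 1, "pos", "neg"),
                               levels = c("pos", "neg")),
                    scale = FALSE, kernel = "polynomial", degree = 3,
                    gamma = 0.03125, coef0 = 0, cost = 512,
                    type = "C-classification")
  xnewScaled <- applyScaler(xnew, fitScaler(ds@x))
  libsvmPred <- as.integer(predict(fit, xnewScaled) == "pos")
  expect_identical(predictLabel(m, xnew), libsvmPred)

  expect_error(trainSVM(subsetDataset(ds, ds@y == 1L)), "both classes")
})

test_that("decision values are the stored kernel expansion", {
  # single support vector, unit dual weight, zero bias
  sv <- matrix(c(0.2, 0.4, 0.6), 1)
  m <- manualModel(sv, 1, 0)
  x <- c(0.1, 0.9, 0.5)
  expect_equal(decisionValue(m, x),
               polynomialKernel(sv[1, ], x, kernelParams()))
  # linearity in the bias
  m2 <- manualModel(sv, 1, 0.5)
  expect_equal(decisionValue(m2, x), decisionValue(m, x) + 0.5)
  expect_error(decisionValue(m, c(1, 2)), "features")
})

test_that("decision values match a brute-force Gram oracle", {
  for (s in 1:5) {
    ds <- separableDataset(10, p = 6, gap = 2, seed = 20 + s)
    m <- trainSVM(ds, C = 512)
    xs <- applyScaler(ds@x, structure(list(min = m@scalerMin,
                                           max = m@scalerMax),
                                      class = "ScalerParams"))
    got <- decisionValue(m, ds@x)
    for (i in seq_len(nrow(xs))) {
      manual <- 0
      for (j in seq_len(nrow(m@supportVectors)))
        manual <- manual + m@dualCoefs[j] *
          (0.03125 * sum(m@supportVectors[j, ] * xs[i, ]))^3
      expect_lt(abs(got[i] - (manual + m@bias)), 1e-8)
    }
  }
})

test_that("labels follow the sign convention with zero mapping to 0", {
  sv <- matrix(c(1, 1), 1)
  expect_equal(predictLabel(manualModel(sv, 1, 2.3 -
    polynomialKernel(c(1, 1), c(0.3, 0.7), kernelParams())),
    c(0.3, 0.7)), 1L)
  expect_equal(predictLabel(manualModel(sv, 1, -0.1 -
    polynomialKernel(c(1, 1), c(0.3, 0.7), kernelParams())),
    c(0.3, 0.7)), 0L)
  # decision exactly zero -> negative class
  m0 <- manualModel(sv, 1,
                    -polynomialKernel(c(1, 1), c(0.3, 0.7),
                                      kernelParams()))
  expect_equal(decisionValue(m0, c(0.3, 0.7)), 0)
  expect_equal(predictLabel(m0, c(0.3, 0.7)), 0L)
})

test_that("training is deterministic and models serialize exactly", {
  ds <- separableDataset(30, p = 5, gap = 2, seed = 42)
  m1 <- trainSVM(ds, C = 512)
  m2 <- trainSVM(ds, C = 512)
  expect_identical(decisionValue(m1, ds@x), decisionValue(m2, ds@x))

  f <- withr::local_tempfile(fileext = ".txt")
  writeModel(m1, f)
  back <- readModel(f)
  expect_identical(decisionValue(back, ds@x), decisionValue(m1, ds@x))
  expect_identical(back@degree, m1@degree)
  g <- withr::local_tempfile()
  writeLines("bogus v9", g)
  expect_error(readModel(g), "version")
})

test_that("grid search maximises CV score with smallest-C tie-break", {
  ds <- separableDataset(30, p = 4, gap = 4, seed = 3)
  cv <- cvConfig(k = 3, repeats = 1, seed = 5)
  one <- gridSearch(ds, Cgrid = 2, gammaGrid = 0.5, cv = cv)
  expect_equal(unname(one$best), c(2, 0.5))

  # clearly separable data scores 1 in many cells: the smallest C
  # (then gamma) among the maximisers must win
  res <- gridSearch(ds, Cgrid = c(1, 512), gammaGrid = c(0.03125, 0.5),
                    cv = cv)
  best <- res$table[res$table$score == max(res$table$score), ]
  expect_equal(res$best[["C"]], min(best$C))
  expect_equal(res$score, max(res$table$score))

  # a grid containing the canonical (512, 0.03125) cell returns a pair
  # achieving the maximal score in its own table
  res2 <- gridSearch(ds, Cgrid = c(8, 512),
                     gammaGrid = c(0.03125, 0.25), cv = cv)
  got <- res2$table[res2$table$C == res2$best[["C"]] &
                      res2$table$gamma == res2$best[["gamma"]], ]
  expect_equal(got$score, max(res2$table$score))
  expect_error(gridSearch(ds, Cgrid = numeric(0)), "non-empty")
})
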