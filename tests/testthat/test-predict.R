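test_that("fold assignment is balanced, exhaustive and seeded", {
  f <- makeFolds(100, 10, seed = 1)
  expect_equal(as.numeric(table(f)), rep(10, 10))
  f2 <- makeFolds(101, 10, seed = 1)
  expect_equal(sort(as.numeric(table(f2))), c(rep(10, 9), 11))
  expect_identical(makeFolds(57, 10, seed = 9), makeFolds(57, 10, seed = 9))
  expect_false(identical(makeFolds(57, 10, seed = 9), makeFolds(57, 10, seed = 10)))
  expect_error(makeFolds(50, 1), ">= 2")
  expect_error(makeFolds(5, 10), "at least k")
})

test_that("standardization is leakage-safe and guards zero variance", {
  set.seed(84)
  tr <- matrix(stats::rnorm(20 * 4), 20, 4)
  tr[, 3] <- 7  # constant column
  te <- matrix(stats::rnorm(5 * 4), 5, 4)
  std <- standardizeTrainApply(tr, te)
  expect_equal(colMeans(std$train), rep(0, 4))
  expect_equal(apply(std$train[, -3], 2, stats::sd), rep(1, 3))
  expect_true(all(std$train[, 3] == 0) && all(std$test[, 3] == 0))
  # a test row at the train mean maps to zero
  stdm <- standardizeTrainApply(tr, matrix(colMeans(tr), 1))
  expect_equal(as.numeric(stdm$test[, -3]), rep(0, 3))
  # permuting test rows cannot change the fitted parameters
  stdp <- standardizeTrainApply(tr, te[5:1, ])
  expect_identical(std$center, stdp$center)
  expect_identical(std$scale, stdp$scale)
})

test_that("ridge reduces to OLS at alpha 0 and shrinks to the mean", {
  X <- matrix(c(-1, 0, 1), 3, 1)  # centered single feature
  fit <- ridgeFit(X, c(1, 2, 3), 0)
  expect_equal(fit@coefficients, 1)
  expect_equal(fit@intercept, 2)
  expect_equal(predict(fit, X), c(1, 2, 3))
  big <- ridgeFit(X, c(1, 2, 3), 1e12)
  expect_lt(max(abs(big@coefficients)), 1e-9)
  expect_equal(predict(big, X), rep(2, 3), tolerance = 1e-9)
  expect_error(ridgeFit(X, c(1, 2, 3), -1), "alpha")
})

test_that("ridge matches the augmented least-squares oracle in both regimes", {
  set.seed(85)
  for (dims in list(c(20, 50), c(50, 20))) {
    X <- matrix(stats::rnorm(dims[1] * dims[2]), dims[1], dims[2])
    y <- stats::rnorm(dims[1])
    for (alpha in c(0.01, 1, 100)) {
      fit <- ridgeFit(X, y, alpha)
      expect_lt(max(abs(fit@coefficients - oracleRidge(X, y, alpha))), 1e-6)
    }
  }
})

test_that("alpha tuning prefers weak shrinkage for clean signal", {
  grid <- defaultAlphaGrid()
  set.seed(86)
  X <- matrix(stats::rnorm(200 * 100), 200, 100)
  y <- X[, 1:3] %*% c(1, 1, 1)  # noiseless
  a <- tuneAlpha(X, as.numeric(y), grid, seed = 2)
  expect_lte(a, grid[6])  # lower half of the 13-point grid
  expect_identical(tuneAlpha(X, as.numeric(y), 3.5, seed = 2), 3.5)
})

test_that("alpha tuning does not pile onto the grid minimum for pure noise", {
  grid <- defaultAlphaGrid()
  picks <- vapply(1:50, function(s) {
    set.seed(s)
    X <- matrix(stats::rnorm(100 * 60), 100, 60)
    tuneAlpha(X, stats::rnorm(100), grid, innerK = 5, seed = s)
  }, numeric(1))
  expect_lt(mean(picks == grid[1]), 0.5)
})

test_that("cross-validated prediction recovers a planted linear signal", {
  n <- 300
  gen <- function(seed) {
    set.seed(seed)
    X <- matrix(stats::rnorm(n * 200), n, 200)
    y <- as.numeric(X[, 1:10] %*% rep(0.3, 10) + stats::rnorm(n, sd = 0.5))
    list(X = X, y = y)
  }
  d <- gen(870)
  cv <- crossValidatedPredict(d$X, d$y, k = 10, seed = 3)
  r <- stats::cor(predictedScores(cv), observedScores(cv))
  # oracle band from independent replicates of the same generative process
  oracle <- vapply(1:6, function(i) {
    di <- gen(880 + i)
    cvi <- crossValidatedPredict(di$X, di$y, k = 10, seed = 3 + i)
    stats::cor(predictedScores(cvi), observedScores(cvi))
  }, numeric(1))
  expect_gt(r, mean(oracle) - 4 * stats::sd(oracle))
  expect_lt(r, mean(oracle) + 4 * stats::sd(oracle))
  # every subject predicted exactly once
  expect_true(all(is.finite(predictedScores(cv))))
  expect_identical(length(foldModels(cv)), 10L)
})

test_that("permuted outcomes give chance-level out-of-fold correlation", {
  set.seed(88)
  X <- matrix(stats::rnorm(150 * 80), 150, 80)
  y <- as.numeric(X[, 1:5] %*% rep(0.5, 5) + stats::rnorm(150, sd = 0.5))
  yp <- sample(y)
  cv <- crossValidatedPredict(X, yp, k = 5, seed = 4)
  expect_lt(abs(stats::cor(predictedScores(cv), yp)), 0.3)
})

test_that("predictions are invariant to feature order", {
  set.seed(89)
  X <- matrix(stats::rnorm(80 * 30), 80, 30)
  y <- stats::rnorm(80)
  perm <- sample(30)
  cv1 <- crossValidatedPredict(X, y, k = 5, seed = 5)
  cv2 <- crossValidatedPredict(X[, perm], y, k = 5, seed = 5)
  expect_equal(predictedScores(cv1), predictedScores(cv2), tolerance = 1e-9)
  b1 <- foldModels(cv1)[[1]]@coefficients
  b2 <- foldModels(cv2)[[1]]@coefficients
  expect_equal(b1[perm], b2, tolerance = 1e-9)
})

test_that("corrupting held-out outcomes never touches the training side", {
  set.seed(90)
  X <- matrix(stats::rnorm(60 * 40), 60, 40)
  y <- stats::rnorm(60)
  folds <- makeFolds(60, 5, seed = 6)
  y2 <- y
  y2[folds == 1] <- 1000 * stats::rnorm(sum(folds == 1))
  cv <- crossValidatedPredict(X, y, folds = folds, seed = 6)
  cv2 <- crossValidatedPredict(X, y2, folds = folds, seed = 6)
  m <- foldModels(cv)[[1]]; m2 <- foldModels(cv2)[[1]]
  expect_identical(m@coefficients, m2@coefficients)
  expect_identical(m@alpha, m2@alpha)
  expect_identical(m@featureCenter, m2@featureCenter)
  expect_identical(m@featureScale, m2@featureScale)
  expect_identical(predictedScores(cv)[folds == 1],
                   predictedScores(cv2)[folds == 1])
})

test_that("univariate selection finds planted edges and guards degenerates", {
  set.seed(91)
  n <- 500
  z <- stats::rnorm(n)
  X <- matrix(stats::rnorm(n * 103), n, 103)
  planted <- c(5, 50, 99)
  for (e in planted) X[, e] <- 0.5 * z + sqrt(0.75) * stats::rnorm(n)
  sel <- univariateSelect(X, z, 3)
  expect_setequal(sel, planted)
  expect_identical(univariateSelect(X, z, 103), order(-abs(stats::cor(X, z)),
                                                      1:103))
  Xc <- cbind(rep(1, 20), stats::rnorm(20), rep(2, 20))
  yc <- stats::rnorm(20)
  expect_setequal(univariateSelect(Xc, yc, 1), 2L)
  expect_error(univariateSelect(Xc, yc, 0), "positive")
  expect_error(univariateSelect(Xc, yc, 9), "exceeds")
})

test_that("feature selection happens inside each training fold", {
  set.seed(92)
  X <- matrix(stats::rnorm(100 * 50), 100, 50)
  y <- as.numeric(X[, 7] + stats::rnorm(100, sd = 0.3))
  cv <- crossValidatedPredict(X, y, k = 5, seed = 7, selectK = 5)
  for (m in foldModels(cv)) {
    expect_length(m@selected, 5L)
    expect_length(m@coefficients, 5L)
  }
  full <- foldCoefficients(cv, full = TRUE)
  expect_true(all(lengths(full) == 50L))
  expect_gt(stats::cor(predictedScores(cv), y), 0.5)
})

test_that("condition concatenation orders by condition then edge with provenance", {
  set.seed(93)
  mk <- function() {
    m <- matrix(stats::rnorm(6 * 4), 6, 4)
    rownames(m) <- paste0("s", 1:6)
    m
  }
  out <- concatenateConditions(list(rest = mk(), mid = mk()))
  expect_identical(ncol(out$X), 8L)
  expect_identical(out$provenance$condition, rep(c("rest", "mid"), each = 4))
  expect_identical(out$provenance$edge, rep(1:4, 2))
  # provenance round-trip: every column maps to a unique (condition, edge)
  expect_false(anyDuplicated(out$provenance[, c("condition", "edge")]) > 0)
  # single condition is the identity
  one <- concatenateConditions(list(rest = mk()))
  expect_identical(ncol(one$X), 4L)
  # mismatched subjects are named
  b <- mk(); rownames(b)[2] <- "s99"
  expect_error(concatenateConditions(list(rest = mk(), mid = b)), "s99")
})

test_that("partial correlation matches Pearson and the recursive formula", {
  set.seed(94)
  x <- stats::rnorm(30); y <- stats::rnorm(30)
  expect_equal(partialCorr(x, y), stats::cor(x, y))
  expect_equal(partialCorr(x, x), 1)
  # toy n = 6 with one covariate vs the recursive formula
  x6 <- c(1.2, -0.5, 0.3, 2.2, -1.4, 0.6)
  y6 <- c(0.7, -1.1, 0.2, 1.9, -0.8, 0.1)
  z6 <- c(0.2, 0.5, -1.2, 0.9, -0.3, 1.1)
  expect_equal(partialCorr(x6, y6, cbind(z6)), oraclePartialCorr1(x6, y6, z6),
               tolerance = 1e-12)
  Zc <- cbind(z = z6, z2 = 2 * z6)
  expect_warning(rp <- partialCorr(x6, y6, Zc), "collinear")
  expect_equal(rp, oraclePartialCorr1(x6, y6, z6), tolerance = 1e-12)
  expect_error(partialCorr(x6, y6[1:5]), "equal length")
})

test_that("bootstrap performance interval behaves at the edges", {
  set.seed(95)
  z <- stats::rnorm(200)
  pred <- 0.5 * z + stats::rnorm(200)
  obs <- z + stats::rnorm(200, sd = 0.5)
  Z <- cbind(motion = z + stats::rnorm(200))
  pe <- bootstrapPerformance(pred, obs, Z, nBoot = 1000, seed = 8)
  ci <- confInt(pe)
  expect_lte(ci[1], rpEstimate(pe))
  expect_gte(ci[2], rpEstimate(pe))
  expect_identical(pe@covariates, "motion")
  # nBoot = 1 collapses to the single resample value
  pe1 <- bootstrapPerformance(pred, obs, Z, nBoot = 1, seed = 8)
  expect_equal(confInt(pe1)[["lower"]], confInt(pe1)[["upper"]])
})

test_that("combined conditions beat single conditions in expectation", {
  nSeed <- 20
  res <- vapply(seq_len(nSeed), function(s) {
    set.seed(1000 + s)
    n <- 200; nN <- 30; nE <- nN * (nN - 1) / 2
    sc <- stats::rnorm(n)
    s1 <- ConnectomeSignalSpec(nN, sample.int(nE, 30), 0.25)
    s2 <- ConnectomeSignalSpec(nN, sample.int(nE, 30), 0.25)
    E1 <- generateConnectomes(sc, s1, seed = s, format = "edges")
    E2 <- generateConnectomes(sc, s2, seed = s + 20000, format = "edges")
    rownames(E1) <- rownames(E2) <- sprintf("s%03d", 1:n)
    comb <- concatenateConditions(list(c1 = E1, c2 = E2))$X
    f <- makeFolds(n, 10, s)
    r1 <- stats::cor(predictedScores(
      crossValidatedPredict(E1, sc, folds = f, seed = s)), sc)
    r2 <- stats::cor(predictedScores(
      crossValidatedPredict(E2, sc, folds = f, seed = s)), sc)
    rc <- stats::cor(predictedScores(
      crossValidatedPredict(comb, sc, folds = f, seed = s)), sc)
    c(r1, r2, rc)
  }, numeric(3))
  means <- rowMeans(res)
  expect_gt(means[3], means[1])
  expect_gt(means[3], means[2])
})

test_that("motion covariate assembly matches the two specified covariate sets", {
  m1 <- generateMotion(20, seed = 96)
  Z <- motionCovariates(m1)
  expect_identical(colnames(Z), c("meanFfd", "meanRotation",
                                  "maxDisplacement", "nFrames"))
  m2 <- generateMotion(20, seed = 97)
  Zc <- motionCovariates(list(rest = m1, task = m2))
  expect_equal(Zc[, "meanFfd"], (m1$meanFfd + m2$meanFfd) / 2)
  expect_equal(Zc[, "nFrames"], as.numeric(m1$nFrames + m2$nFrames))
})
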