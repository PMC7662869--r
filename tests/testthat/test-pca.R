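test_that("rank-2 input puts all explained variance in two components", {
  set.seed(51)
  X <- matrix(stats::rnorm(100 * 2), 100, 2) %*% matrix(stats::rnorm(2 * 6), 2, 6)
  suppressWarnings(m <- fitPca(X))
  expect_equal(sum(explainedVariance(m)[1:2]), 1, tolerance = 1e-10)
  expect_lte(nComponents(m), 3)  # truncated at numerical rank
})

test_that("full set of components reconstructs the input", {
  set.seed(52)
  X <- matrix(stats::rnorm(60 * 5), 60, 5)
  m <- fitPca(X)
  S <- projectScores(X, m)
  rec <- S %*% t(componentLoadings(m)) + rep(1, 60) %o% m@center
  expect_equal(unname(rec), unname(X), tolerance = 1e-10)
  expect_equal(sum(explainedVariance(m)), 1, tolerance = 1e-8)
})

test_that("loadings agree with the covariance eigendecomposition oracle", {
  set.seed(53)
  X <- matrix(stats::rnorm(200 * 7), 200, 7)
  L <- componentLoadings(fitPca(X))
  V <- eigen(stats::cov(X), symmetric = TRUE)$vectors
  for (k in 1:7) {
    expect_equal(abs(sum(L[, k] * V[, k])), 1, tolerance = 1e-8,
                 label = sprintf("component %d colinear with eigenvector", k))
  }
})

test_that("projection is self-consistent, centered, and variance-ordered", {
  set.seed(54)
  X <- matrix(stats::rnorm(150 * 6), 150, 6)
  m <- fitPca(X)
  S <- projectScores(X, m)
  # all-mean subject scores zero on every component
  expect_equal(as.numeric(projectScores(matrix(m@center, 1), m)), rep(0, 6),
               tolerance = 1e-12)
  v <- apply(S, 2, stats::var)
  expect_false(is.unsorted(rev(v)))
  expect_identical(unname(which.max(v)), 1L)
})

test_that("dimensionality selection recovers a planted rank-3 signal", {
  set.seed(55)
  F3 <- matrix(stats::rnorm(500 * 3, sd = 3), 500, 3)
  L3 <- matrix(stats::rnorm(30 * 3), 30, 3) / sqrt(3)
  X <- F3 %*% t(L3) + matrix(stats::rnorm(500 * 30), 500, 30)
  expect_identical(selectDimensionality(X), 3L)
})

test_that("white noise selects the minimal rank most often", {
  picks <- vapply(1:100, function(s) {
    set.seed(s)
    selectDimensionality(matrix(stats::rnorm(1000 * 10), 1000, 10))
  }, integer(1))
  tb <- table(picks)
  expect_identical(names(tb)[which.max(tb)], "1")
})

test_that("evidence agrees with an independent literal reimplementation", {
  set.seed(56)
  X <- matrix(stats::rnorm(120 * 9), 120, 9)
  lam <- eigen(stats::cov(X), symmetric = TRUE, only.values = TRUE)$values
  for (k in 1:8) {
    expect_equal(cpmrisk:::.laplaceEvidence(lam, k, 120),
                 oracleLaplaceEvidence(lam, k, 120), tolerance = 1e-10)
  }
})

test_that("alignment recovers a permuted, sign-flipped copy exactly", {
  set.seed(57)
  ref <- componentLoadings(fitPca(matrix(stats::rnorm(80 * 5), 80, 5)))
  perm <- c(3, 1, 5, 2, 4)
  flip <- c(-1, 1, -1, -1, 1)
  scrambled <- sweep(ref[, perm], 2, flip, "*")
  out <- alignLoadings(ref, scrambled)
  expect_equal(unname(out), unname(ref), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(attr(out, "order"), order(perm))
})

test_that("bootstrap flags strong loadings reliable and null loadings not", {
  spec <- linearTwoBlockSpec()
  # add a pure-noise item with zero loading on both factors
  L <- rbind(spec@itemLoadings, null1 = c(0, 0))
  spec2 <- FactorSpec(L, skewSeverity = 0)
  sim <- generateItemResponses(2000, spec2, seed = 58)
  X <- scale(responseValues(sim$responses))
  ref <- fitPca(X, nComponents = 2)
  b <- bootstrapLoadings(X, ref, nBoot = 500, seed = 59)
  rel <- reliableLoadings(b)
  # block-A items load reliably on the first (strongest) component
  expect_true(all(rel[c("a1", "a2", "a3", "a4"), 1]))
  expect_false(rel["null1", 1])
  expect_false(rel["null1", 2])
  expect_identical(b@nBoot, 500L)
  bounds <- loadingBounds(b)
  expect_true(all(bounds$lower <= bounds$upper))
})

test_that("similarity is 1 for identical and sign-flipped models, > 0.9 across halves", {
  spec <- linearTwoBlockSpec()
  sim <- generateItemResponses(4000, spec, seed = 60)
  X <- scale(responseValues(sim$responses))
  mA <- fitPca(X[1:2000, ], nComponents = 2)
  expect_equal(unname(loadingSimilarity(mA, mA)), c(1, 1))
  flipped <- -componentLoadings(mA)
  expect_equal(unname(loadingSimilarity(mA, flipped)), c(1, 1), tolerance = 1e-12)
  mB <- fitPca(X[2001:4000, ], nComponents = 2)
  expect_gt(loadingSimilarity(mA, mB)[1], 0.9)
})

test_that("MDS embeds exactly embeddable configurations and matches its oracle", {
  # three collinear items: distances reproduce exactly in 1-2 dimensions
  t_ <- seq(0, 1, length.out = 40)
  X <- cbind(i1 = t_, i2 = 2 * t_, i3 = 4 * t_)
  out <- itemMds(X)
  expect_equal(as.matrix(stats::dist(out$coordinates)), as.matrix(out$distances),
               tolerance = 1e-8, ignore_attr = TRUE)
  # duplicated item lands at distance zero from its copy
  set.seed(61)
  Y <- matrix(stats::rnorm(50 * 3), 50, 3)
  Y <- cbind(Y, Y[, 3])
  colnames(Y) <- c("a", "b", "c", "c_copy")
  out2 <- itemMds(Y)
  expect_lt(stats::dist(out2$coordinates[c("c", "c_copy"), ])[1], 1e-8)
  # agreement with the double-centered-Gram eigendecomposition oracle
  set.seed(62)
  Z <- matrix(stats::rnorm(60 * 5), 60, 5)
  colnames(Z) <- letters[1:5]
  ours <- itemMds(Z)$coordinates
  theirs <- oracleMds(stats::dist(t(Z)))
  expect_equal(abs(unname(ours)), abs(theirs), tolerance = 1e-8)
  expect_error(itemMds(Z[, 1:2]), "3 items")
})

test_that("the full behavioral pipeline recovers the two planted factors", {
  spec <- twoBlockFactorSpec(skewSeverity = 1)
  sim <- generateItemResponses(2000, spec, seed = 63)
  model <- fitComponentModel(sim$responses, nComponents = 2)
  S <- projectScores(sim$responses, model)
  # oracle threshold: independent replicates of the same generative process
  oracle <- vapply(1:5, function(r) {
    simO <- generateItemResponses(2000, spec, seed = 70 + r)
    mO <- fitComponentModel(simO$responses, nComponents = 2)
    SO <- projectScores(simO$responses, mO)
    max(abs(stats::cor(SO[, 1], simO$factors)))
  }, numeric(1))
  threshold <- mean(oracle) - 4 * stats::sd(oracle)
  expect_gt(max(abs(stats::cor(S[, 1], sim$factors))), threshold)
  # the two fitted components separate the two factors
  C <- abs(stats::cor(S[, 1:2], sim$factors))
  expect_gt(min(apply(C, 2, max)), 0.5)
})
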