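test_that("edge vectorization uses canonical row-major upper-triangle order", {
  M <- labeledSymmetricMatrix(4)
  v <- vectorizeEdges(M)
  # (1,2),(1,3),(1,4),(2,3),(2,4),(3,4)
  expect_equal(as.numeric(v), c(12, 13, 14, 23, 24, 34))
  expect_identical(length(v), 6L)
  p <- edgePairs(4)
  expect_equal(M[p], as.numeric(v))
})

test_that("vectorize/devectorize round-trips exactly", {
  set.seed(71)
  for (n in c(3, 5, 12)) {
    M <- matrix(stats::rnorm(n * n), n)
    M <- M + t(M); diag(M) <- 0
    rt <- connMatrix(devectorizeEdges(vectorizeEdges(M), n))
    expect_identical(rt, M)
  }
  expect_error(devectorizeEdges(1:5, 4), "expected 6")
})

test_that("a 268-node matrix yields 35,778 edges", {
  expect_identical(length(vectorizeEdges(matrix(0, 268, 268))), 35778L)
  expect_identical(nrow(edgePairs(268)), 35778L)
})

test_that("confound design expands 6 motion parameters to 24 columns", {
  set.seed(72)
  mp <- matrix(stats::rnorm(50 * 6), 50, 6)
  C <- buildConfoundMatrix(mp)
  motCols <- grep("^mot", colnames(C))
  expect_identical(length(motCols), 24L)
  expect_identical(colnames(C)[1], "intercept")
  # derivative columns: backward differences with first frame 0
  expect_equal(unname(C[, "mot1_d"]), c(0, diff(mp[, 1])))
  expect_equal(unname(C[, "mot3_sq"]), mp[, 3]^2)
  # constant motion: derivative columns all zero
  C0 <- buildConfoundMatrix(matrix(1, 50, 6))
  expect_true(all(C0[, grep("_d$|_dsq$", colnames(C0))] == 0))
  # drift columns have zero mean (orthogonal to the intercept)
  expect_equal(unname(colSums(C[, grep("^drift", colnames(C))])), rep(0, 3),
               tolerance = 1e-10)
  expect_error(buildConfoundMatrix(mp[, 1:5]), "6 columns")
})

test_that("confound regression projects exactly and matches the normal equations", {
  set.seed(73)
  C <- cbind(1, stats::rnorm(40), stats::rnorm(40))
  # series equal to a confound column vanishes
  res <- regressConfounds(rbind(C[, 2], C[, 3]), C)
  expect_lt(max(abs(res)), 1e-10)
  # intercept-only design demeans
  S <- matrix(stats::rnorm(3 * 40), 3, 40)
  resI <- regressConfounds(S, matrix(1, 40, 1))
  expect_equal(resI, S - rowMeans(S), tolerance = 1e-12, ignore_attr = TRUE)
  # residuals orthogonal to every confound column; 5-node toy vs lsq oracle
  S5 <- matrix(stats::rnorm(5 * 40), 5, 40)
  C5 <- cbind(1, stats::poly(1:40, 2), stats::rnorm(40))
  r5 <- regressConfounds(S5, C5)
  expect_lt(max(abs(r5 %*% C5)), 1e-9)
  oracle <- t(t(S5) - C5 %*% solve(crossprod(C5), crossprod(C5, t(S5))))
  expect_equal(r5, oracle, tolerance = 1e-9)
  # collinear columns dropped with a warning
  expect_warning(regressConfounds(S5, cbind(C5, C5[, 2])), "collinear")
})

test_that("temporal smoothing preserves DC, matches the kernel, reduces variance", {
  S <- matrix(3, 2, 60)
  expect_equal(temporalSmooth(S), S, tolerance = 1e-12, ignore_attr = TRUE)
  # unit impulse at the center reproduces the normalized Gaussian kernel
  imp <- matrix(0, 1, 101); imp[51] <- 1
  sm <- temporalSmooth(imp, sigma = 1.95)
  h <- ceiling(4 * 1.95)
  k <- stats::dnorm(-h:h, sd = 1.95); k <- k / sum(k)
  expect_equal(as.numeric(sm[1, (51 - h):(51 + h)]), rev(k), tolerance = 1e-12)
  expect_equal(sum(sm), 1, tolerance = 1e-12)
  set.seed(74)
  W <- matrix(stats::rnorm(4 * 500), 4, 500)
  expect_true(all(apply(temporalSmooth(W), 1, stats::var) <
                  apply(W, 1, stats::var)))
  expect_error(temporalSmooth(W, sigma = 0), "positive")
  expect_error(temporalSmooth(W[, 1:4, drop = FALSE]), "5 frames")
})

test_that("connectivity is Fisher-z of clipped Pearson correlation", {
  pair <- exactCorrPair(0.5, 400, seed = 75)
  z <- connMatrix(computeConnectivity(pair))
  expect_equal(z[1, 2], atanh(0.5), tolerance = 1e-10)
  expect_equal(z[1, 2], 0.5493, tolerance = 1e-4)
  # orthogonal series give edge 0
  pair0 <- exactCorrPair(0, 400, seed = 76)
  expect_equal(connMatrix(computeConnectivity(pair0))[1, 2], 0, tolerance = 1e-12)
  # perfectly correlated series are clipped before atanh (finite result)
  dup <- rbind(pair[1, ], pair[1, ] * 2)
  expect_true(all(is.finite(connMatrix(computeConnectivity(dup)))))
  # symmetric, zero diagonal; constant nodes named in the error
  set.seed(77)
  S <- matrix(stats::rnorm(4 * 100), 4, 100,
              dimnames = list(paste0("node", 1:4), NULL))
  z4 <- connMatrix(computeConnectivity(S))
  expect_equal(z4, t(z4))
  expect_equal(diag(z4), rep(0, 4), ignore_attr = TRUE)
  S[2, ] <- 5
  expect_error(computeConnectivity(S), "node2")
})

test_that("motion QC applies strict thresholds with reasons", {
  th <- QcThresholds()
  fail1 <- qcMotion(list(meanFfd = 0.16, maxDisplacement = 0, maxRotation = 0), th)
  expect_false(fail1$pass)
  expect_length(fail1$reasons, 1L)
  # exactly at thresholds passes ("more than" is strict)
  expect_true(qcMotion(list(meanFfd = 0.15, maxDisplacement = 2,
                            maxRotation = 3), th)$pass)
  expect_true(qcMotion(list(meanFfd = 0, maxDisplacement = 0,
                            maxRotation = 0), th)$pass)
  all3 <- qcMotion(list(meanFfd = 1, maxDisplacement = 9, maxRotation = 9), th)
  expect_length(all3$reasons, 3L)
})

test_that("worsening motion never converts fail to pass", {
  th <- QcThresholds()
  set.seed(78)
  for (i in 1:50) {
    m <- list(meanFfd = stats::runif(1, 0, 0.3),
              maxDisplacement = stats::runif(1, 0, 4),
              maxRotation = stats::runif(1, 0, 6))
    worse <- lapply(m, function(v) v + stats::runif(1, 0, 2))
    if (!qcMotion(m, th)$pass) expect_false(qcMotion(worse, th)$pass)
  }
})

test_that("run aggregation averages Fisher-z matrices", {
  set.seed(79)
  M <- labeledSymmetricMatrix(5) / 100
  cm <- ConnectivityMatrix(M)
  expect_equal(connMatrix(aggregateRuns(list(cm))), M)
  expect_equal(connMatrix(aggregateRuns(list(cm, ConnectivityMatrix(-M)))),
               matrix(0, 5, 5))
  expect_equal(connMatrix(aggregateRuns(list(cm, cm, cm))), M)
  expect_error(aggregateRuns(list()), "excluded")
})

test_that("pipeline order is regression-confounds first, then smoothing", {
  sim <- generateTimeseries(6, 300, confoundAmplitudes = c(0.5, 0.8, 0.5),
                            seed = 80)
  run <- TimeSeriesRun(sim$series, sim$motionParams,
                       tissue = sim$confounds[, c("csf", "wm", "global")])
  out <- processRun(run)
  C <- buildConfoundMatrix(run)
  manual <- computeConnectivity(temporalSmooth(regressConfounds(run@series, C)))
  expect_equal(connMatrix(out), connMatrix(manual))
  swapped <- computeConnectivity(regressConfounds(temporalSmooth(run@series), C))
  expect_gt(max(abs(connMatrix(out) - connMatrix(swapped))), 1e-6)
})

test_that("connectivity of residuals ignores added confound combinations", {
  sim <- generateTimeseries(5, 400, seed = 81)
  C <- cbind(1, scale(sim$confounds))
  base <- computeConnectivity(regressConfounds(sim$series, C))
  set.seed(82)
  spiked <- sim$series + t(C %*% matrix(stats::rnorm(ncol(C) * 5), ncol(C), 5))
  spikedOut <- computeConnectivity(regressConfounds(spiked, C))
  expect_equal(connMatrix(base), connMatrix(spikedOut), tolerance = 1e-8)
})

test_that("qcReport summarizes runs and aggregation uses passing runs", {
  m <- generateMotion(50, seed = 83)
  rep_ <- qcReport(m)
  expect_identical(nrow(rep_), 50L)
  expect_identical(rep_$pass, !nzchar(rep_$reasons))
})
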