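# Independent oracles, written against the textbook definitions rather than
# the package's code paths.

# Ridge via the augmented least-squares system: stacking sqrt(alpha) * I
# under X and zeros under the centered outcome turns the penalized problem
# into an ordinary least-squares fit.
oracleRidge <- function(X, y, alpha) {
  p <- ncol(X)
  Xa <- rbind(X, sqrt(alpha) * diag(p))
  ya <- c(y - mean(y), rep(0, p))
  stats::lsfit(Xa, ya, intercept = FALSE)$coefficients
}

# First-order partial correlation by the recursive formula.
oraclePartialCorr1 <- function(x, y, z) {
  rxy <- stats::cor(x, y)
  rxz <- stats::cor(x, z)
  ryz <- stats::cor(y, z)
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

# Yeo-Johnson log-likelihood by direct formula (variance of the transformed
# sample plus the Jacobian term) over a fixed lambda grid; returns argmax.
oracleYjGridLambda <- function(x, step = 0.01) {
  yj <- function(v, l) {
    out <- numeric(length(v))
    pos <- v >= 0
    out[pos] <- if (abs(l) < 1e-12) log(v[pos] + 1) else ((v[pos] + 1)^l - 1) / l
    out[!pos] <- if (abs(l - 2) < 1e-12) -log(-v[!pos] + 1)
                 else -((-v[!pos] + 1)^(2 - l) - 1) / (2 - l)
    out
  }
  grid <- seq(-5, 5, by = step)
  n <- length(x)
  ll <- vapply(grid, function(l) {
    z <- yj(x, l)
    s2 <- mean((z - mean(z))^2)
    -n / 2 * log(s2) + (l - 1) * sum(sign(x) * log(abs(x) + 1))
  }, numeric(1))
  grid[which.max(ll)]
}

# Laplace log-evidence for probabilistic PCA at rank k, literal loop-style
# transcription of the model-selection formula (second, independent path).
oracleLaplaceEvidence <- function(lam, k, n) {
  p <- length(lam)
  eps <- 1e-15
  if (lam[k] < eps) return(-Inf)
  logpU <- -k * log(2)
  for (i in 1:k)
    logpU <- logpU + lgamma((p - i + 1) / 2) - ((p - i + 1) / 2) * log(pi)
  t1 <- 0
  for (i in 1:k) t1 <- t1 - (n / 2) * log(lam[i])
  v <- max(eps, mean(lam[(k + 1):p]))
  t2 <- -(n * (p - k) / 2) * log(v)
  m <- p * k - k * (k + 1) / 2
  t3 <- ((m + k) / 2) * log(2 * pi)
  lamhat <- c(lam[1:k], rep(v, p - k))
  logAz <- 0
  for (i in 1:k) {
    for (j in (i + 1):p) {
      logAz <- logAz + log(lam[i] - lam[j]) +
        log(1 / lamhat[j] - 1 / lamhat[i]) + log(n)
    }
  }
  logpU + t1 + t2 + t3 - logAz / 2 - (k / 2) * log(n)
}

# Classical MDS by double-centering the squared-distance matrix and
# eigendecomposing the Gram matrix.
oracleMds <- function(D, k = 2) {
  D <- as.matrix(D)
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  eg <- eigen(B, symmetric = TRUE)
  eg$vectors[, 1:k, drop = FALSE] %*% diag(sqrt(pmax(eg$values[1:k], 0)), k)
}

# Sample skewness (method-of-moments).
sampleSkewness <- function(x) {
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  mean((x - m)^3) / s^3
}

# Two exactly-correlated series: returns a 2 x nFrames matrix whose rows
# have sample correlation exactly r.
exactCorrPair <- function(r, nFrames, seed = 1) {
  set.seed(seed)
  a <- stats::rnorm(nFrames)
  b0 <- stats::rnorm(nFrames)
  b0 <- stats::residuals(stats::lm(b0 ~ a))
  za <- as.numeric(scale(a))
  zb <- as.numeric(scale(b0))
  rbind(za, r * za + sqrt(1 - r^2) * zb)
}
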