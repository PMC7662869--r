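# Shared fixture builders (all generated in code at test time).

# Two-block linear-Gaussian item model with distinct block strengths (so the
# component order is stable) and its population loading structure under the
# package's sign convention.
linearTwoBlockSpec <- function() {
  L <- rbind(
    a1 = c(0.85, 0), a2 = c(0.80, 0), a3 = c(0.75, 0), a4 = c(0.70, 0),
    b1 = c(0, 0.65), b2 = c(0, 0.60), b3 = c(0, 0.55), b4 = c(0, 0.50)
  )
  colnames(L) <- c("f1", "f2")
  FactorSpec(L, skewSeverity = 0)
}

populationLoadings <- function(spec, k = 2) {
  L <- spec@itemLoadings
  Sig <- L %*% spec@factorCov %*% t(L)
  diag(Sig) <- 1
  truth <- eigen(Sig, symmetric = TRUE)$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(truth[, j]))
    if (truth[i, j] < 0) truth[, j] <- -truth[, j]
  }
  rownames(truth) <- rownames(L)
  truth
}

# A small symmetric zero-diagonal matrix with distinguishable entries.
labeledSymmetricMatrix <- function(n) {
  M <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) M[i, j] <- M[j, i] <- 10 * i + j
  M
}
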