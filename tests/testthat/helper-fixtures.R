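# Shared fixtures and independent oracle routines. Oracles re-implement
# the math as straight-line code (explicit covariance eigendecomposition,
# literal formula evaluation) so that they never share a code path with
# the package implementation they check.

randomExprMatrix <- function(nGenes, nSamples, seed = 1, sd = 1) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(nGenes * nSamples, sd = sd), nGenes, nSamples)
    dimnames(m) <- list(sprintf("g%03d", seq_len(nGenes)),
                        sprintf("s%03d", seq_len(nSamples)))
    m
  })
}

smallSpec <- function(nPerLeaf = 6, genesPerNode = 12, deltaMu = 4,
                      sigmaE = 1, nBackground = 20, seed = 11)
  simulationSpec(nPerLeaf = nPerLeaf, genesPerNode = genesPerNode,
                 deltaMu = deltaMu, sigmaE = sigmaE,
                 nBackground = nBackground, seed = seed)

# --- straight-line formula oracles -----------------------------------------

oracleWeightedDistance <- function(u, v, w) {
  acc <- 0
  for (i in seq_along(u)) acc <- acc + w[i] * (u[i] - v[i])^2
  sqrt(acc)
}

oracleMembershipProbabilities <- function(d) {
  inv <- numeric(length(d))
  for (i in seq_along(d)) inv[i] <- 1 / d[i]
  tot <- 0
  for (i in seq_along(d)) tot <- tot + inv[i]
  setNames(inv / tot, names(d))
}

oracleRelativeDistance <- function(d, sigma) d / sigma

# Brute-force PCA: eigendecompose the sample covariance matrix directly,
# then apply the package's documented sign convention (largest-|loading|
# positive) so results are comparable without sign ambiguity.
oraclePCA <- function(m, nComponents) {
  X <- t(m)                                  # samples x genes
  Xc <- sweep(X, 2, colMeans(X), "-")
  C <- stats::cov(X)
  eig <- eigen(C, symmetric = TRUE)
  vec <- eig$vectors[, seq_len(nComponents), drop = FALSE]
  for (k in seq_len(ncol(vec))) {
    j <- which.max(abs(vec[, k]))
    if (vec[j, k] < 0) vec[, k] <- -vec[, k]
  }
  scores <- Xc %*% vec
  weights <- eig$values[seq_len(nComponents)] / sum(eig$values)
  list(scores = unname(scores), weights = weights, basis = vec)
}

# Full independent re-derivation of a NodeResult in merge mode: merged
# covariance PCA, per-child centroids and population-sd dispersions,
# literal distance/probability/relative-distance formulas.
oracleClassifyNode <- function(refMatrix, childAssign, childLabels,
                               unknown) {
  merged <- cbind(refMatrix, unknown[rownames(refMatrix)])
  k <- min(nrow(merged), ncol(merged) - 1L)
  p <- oraclePCA(merged, k)
  n <- ncol(refMatrix)
  refScores <- p$scores[seq_len(n), , drop = FALSE]
  uScore <- p$scores[n + 1L, ]
  out <- list(distances = numeric(), sigmas = numeric())
  for (child in childLabels) {
    rows <- refScores[childAssign[colnames(refMatrix)] == child, ,
                      drop = FALSE]
    ctr <- colMeans(rows)
    dd <- apply(rows, 1, oracleWeightedDistance, v = ctr, w = p$weights)
    out$sigmas[child] <- sqrt(mean((dd - mean(dd))^2))
    out$distances[child] <- oracleWeightedDistance(uScore, ctr, p$weights)
  }
  out$probabilities <- oracleMembershipProbabilities(out$distances)
  out$relativeDistances <- out$distances / out$sigmas
  out$assignedChild <- names(which.min(out$distances))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# draw an unknown around a child's empirical mean profile (unit noise)
makeTwoChildUnknown <- function(model, child, seed = 1) {
  cols <- names(modelChildAssign(model))[modelChildAssign(model) == child]
  mu <- rowMeans(model@refMatrix[, cols, drop = FALSE])
  withr::with_seed(seed, mu + rnorm(length(mu)))
}

writeTempGCT <- function(m) {
  path <- withr::local_tempfile(fileext = ".gct",
                                .local_envir = parent.frame())
  writeGCT(m, path)
  path
}

writeTempLines <- function(lines, fileext = ".txt") {
  path <- withr::local_tempfile(fileext = fileext,
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
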