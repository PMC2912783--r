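#' Supervised PCA of classifier-gene expression
#'
#' Fits a principal component analysis with samples as observations and
#' classifier genes as variables (PRINCOMP orientation). Genes are centered
#' by their mean over samples; no scaling to unit variance is applied. The
#' decomposition is computed by SVD of the centered sample x gene matrix.
#' The per-component proportions of total variance form the weight vector
#' later used in distance computations.
#'
#' Component signs are otherwise arbitrary, so each basis column is flipped
#' to make its largest-magnitude loading positive; scores are flipped in
#' step. The fit is deterministic.
#'
#' @param matrix numeric genes x samples expression matrix (already
#'   restricted to one node's classifier genes), with dimnames.
#' @param nComponents integer number of components to retain, or `"all"`
#'   (default) for `min(genes, samples - 1)`.
#' @return A [PCAProjection-class].
#' @examples
#' m <- matrix(rnorm(30), 6, 5,
#'             dimnames = list(paste0("g", 1:6), paste0("s", 1:5)))
#' p <- fitPCA(m)
#' sum(pcaWeights(p))  # 1 when all components are retained
#' @export
fitPCA <- function(matrix, nComponents = "all") {
  .checkExprMatrix(matrix)
  n <- ncol(matrix)
  g <- nrow(matrix)
  if (n < 2L) .stopParameter("PCA needs >= 2 samples, got %d", n)
  kmax <- min(g, n - 1L)
  if (identical(nComponents, "all")) nComponents <- kmax
  nComponents <- as.integer(nComponents)
  if (is.na(nComponents) || nComponents < 1L || nComponents > kmax)
    .stopParameter("nComponents must be in [1, %d], got %s", kmax,
                   as.character(nComponents))
  X <- t(matrix)                       # samples x genes
  center <- colMeans(X)
  Xc <- sweep(X, 2L, center, "-")
  totalVar <- sum(Xc^2) / (n - 1L)
  if (totalVar <= .Machine$double.eps)
    .stopDegenerate("zero-variance input: all %d samples are identical", n)
  sv <- svd(Xc, nu = nComponents, nv = nComponents)
  d <- sv$d
  weights <- (d^2 / (n - 1L)) / totalVar
  weights <- weights[seq_len(nComponents)]
  basis <- sv$v                        # genes x components
  scores <- sv$u %*% diag(d[seq_len(nComponents)], nComponents)
  # deterministic sign convention: largest-|loading| positive per column
  for (k in seq_len(nComponents)) {
    j <- which.max(abs(basis[, k]))
    if (basis[j, k] < 0) {
      basis[, k] <- -basis[, k]
      scores[, k] <- -scores[, k]
    }
  }
  dimnames(basis) <- list(rownames(matrix),
                          paste0("PC", seq_len(nComponents)))
  dimnames(scores) <- list(colnames(matrix),
                           paste0("PC", seq_len(nComponents)))
  names(center) <- rownames(matrix)
  new("PCAProjection", basis = basis, scores = scores,
      center = center, weights = unname(weights),
      nComponents = nComponents)
}

#' @describeIn fitPCA sample x component score matrix.
#' @param object a `PCAProjection`.
#' @export
pcaScores <- function(object) object@scores

#' @describeIn fitPCA gene x component orthonormal basis.
#' @export
pcaBasis <- function(object) object@basis

#' @describeIn fitPCA per-component variance proportions (the weight
#'   vector).
#' @export
pcaWeights <- function(object) object@weights

#' @describeIn fitPCA per-gene centering vector.
#' @export
pcaCenter <- function(object) object@center

#' Merge an unknown profile into a reference and refit the PCA
#'
#' Appends the unknown sample as an extra column of the reference matrix
#' and fits a single PCA on the merged data, so that the unknown
#' participates in the basis exactly as a reference sample would. Gene
#' order is taken from the reference; the unknown must cover every
#' reference gene.
#'
#' @param reference numeric genes x samples reference matrix.
#' @param unknown named numeric vector over (at least) the reference genes.
#' @param sampleId column name given to the unknown in the merged fit.
#' @inheritParams fitPCA
#' @return A [PCAProjection-class] fitted on reference samples plus the
#'   unknown; the unknown's score row is the last one (named `sampleId`).
#' @export
mergeAndProject <- function(reference, unknown, sampleId = "unknown",
                            nComponents = "all") {
  .checkExprMatrix(reference)
  missing <- setdiff(rownames(reference), names(unknown))
  if (length(missing))
    .stopCoverage("unknown sample lacks %d reference gene(s): %s",
                  length(missing), paste(missing, collapse = ", "))
  u <- unknown[rownames(reference)]
  if (!all(is.finite(u)))
    .stopFormat("unknown sample has non-finite values")
  if (sampleId %in% colnames(reference))
    sampleId <- make.unique(c(colnames(reference), sampleId))[
      ncol(reference) + 1L]
  merged <- cbind(reference, u)
  colnames(merged)[ncol(merged)] <- sampleId
  fitPCA(merged, nComponents = nComponents)
}

#' Project samples onto a frozen PCA basis
#'
#' Alternative to merging: the unknown is centered with the reference fit's
#' centering vector and projected onto its basis, leaving the reference
#' scores untouched.
#'
#' @param projection a [PCAProjection-class] fitted on the reference.
#' @param unknown named numeric vector over the fitted genes.
#' @return numeric score vector of length `nComponents`.
#' @export
projectSample <- function(projection, unknown) {
  genes <- rownames(projection@basis)
  missing <- setdiff(genes, names(unknown))
  if (length(missing))
    .stopCoverage("unknown sample lacks %d fitted gene(s): %s",
                  length(missing), paste(missing, collapse = ", "))
  u <- unknown[genes]
  drop((u - projection@center) %*% projection@basis)
}

setMethod("show", "PCAProjection", function(object) {
  cat("PCAProjection:", nrow(object@scores), "samples,",
      nrow(object@basis), "genes,", object@nComponents, "components\n")
  cat("  variance proportions:",
      paste(sprintf("%.3f", head(object@weights, 5L)), collapse = " "),
      if (object@nComponents > 5L) "...\n" else "\n")
})
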