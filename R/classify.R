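#' Weighted Euclidean distance between score vectors
#'
#' `d(u, v) = sqrt(sum_i w_i (u_i - v_i)^2)`, where `w` is the vector of
#' per-component variance proportions from the PCA fit. Components that
#' explain more variance therefore contribute more to the distance.
#'
#' @param u,v numeric vectors of equal length (PC scores).
#' @param w numeric vector of non-negative weights, same length.
#' @return non-negative scalar distance.
#' @examples
#' weightedDistance(c(0, 0), c(3, 4), c(1, 1))      # 5
#' weightedDistance(c(0, 0), c(3, 4), c(0.5, 0.5))  # sqrt(12.5)
#' @export
weightedDistance <- function(u, v, w) {
  if (length(u) != length(v) || length(u) != length(w))
    .stopParameter("u, v and w must have equal length (%d, %d, %d)",
                   length(u), length(v), length(w))
  if (any(w < 0)) .stopParameter("weights must be non-negative")
  sqrt(sum(w * (u - v)^2))
}

#' Inverse-distance membership probabilities
#'
#' Converts the weighted distances of an unknown sample to each child
#' centroid into a confidence share:
#' `p_i = d_i^{-1} / sum_j d_j^{-1}`. Probabilities are in `[0, 1]`, sum
#' to 1, and are order-reversing in the distances. A single zero distance
#' receives probability 1 (the limit of the formula); several zero
#' distances are ill-posed and raise an error.
#'
#' This is an ordinal confidence share, not a calibrated posterior.
#'
#' @param distances named non-negative numeric vector, one entry per child
#'   subtype (>= 2 entries).
#' @return named probability vector over the same children.
#' @examples
#' membershipProbabilities(c(A = 1, B = 3))  # 0.75, 0.25
#' @export
membershipProbabilities <- function(distances) {
  if (length(distances) < 2L)
    .stopParameter("need >= 2 child distances, got %d", length(distances))
  if (any(distances < 0)) .stopParameter("distances must be >= 0")
  zero <- distances == 0
  if (sum(zero) > 1L)
    .stopDegenerate("several zero distances: child centroids coincide")
  if (any(zero)) {
    p <- as.numeric(zero)
  } else {
    inv <- 1 / distances
    p <- inv / sum(inv)
  }
  setNames(p, names(distances))
}

#' Relative distance (outlier score)
#'
#' Distance of the unknown sample to a subtype centroid expressed in units
#' of that subtype's own dispersion: `r_D = d / sigma`, where `sigma` is
#' the standard deviation of the distances of the subtype's reference
#' samples to their centroid. Values far above 1 indicate that the sample
#' sits outside the subtype's cloud even if it is the nearest one.
#'
#' @param d non-negative distance of the unknown to the centroid.
#' @param sigma positive dispersion of the subtype's own sample-to-centroid
#'   distances.
#' @return `d / sigma`, unitless.
#' @examples
#' relativeDistance(2.4, 0.8)  # 3
#' @export
relativeDistance <- function(d, sigma) {
  if (d < 0) .stopParameter("distance must be >= 0")
  if (sigma <= 0)
    .stopDegenerate(paste0(
      "sigma must be > 0 (got %g): the subtype's reference samples ",
      "coincide; add samples or check the reference"), sigma)
  d / sigma
}

#' Classify an unknown sample at one hierarchy node
#'
#' The per-node pipeline: restrict to the node's classifier genes, fit the
#' PCA (merging the unknown into the reference by default), compute each
#' child's centroid and distance dispersion from the reference scores
#' only, then the unknown's weighted distances, membership probabilities
#' and relative distances, and assign the child with minimal distance.
#'
#' In `"merge"` mode the PCA basis is refitted on reference plus unknown
#' (so results depend slightly on the unknown); in `"project"` mode the
#' basis is frozen on the reference and the unknown is projected onto it.
#' Child centroids and dispersions are always computed from reference
#' samples only.
#'
#' @param model a [ReferenceModel-class].
#' @param unknown named numeric expression vector covering the node's
#'   classifier genes (up to the coverage policy).
#' @param mode `"merge"` (default) or `"project"`.
#' @param nComponents components retained in the fit and used in all
#'   distances; `"all"` (default) keeps every available component.
#' @param sigmaDivisor `"n"` (population, default) or `"n-1"` for the
#'   dispersion of child distances.
#' @param coverageThreshold maximum tolerated fraction of classifier genes
#'   absent from the unknown (default 0.05); missing genes below it are
#'   dropped from both sides with a warning.
#' @param sampleId identifier used for the unknown.
#' @return A [NodeResult-class].
#' @seealso [classifyHierarchical()]
#' @export
classifyNode <- function(model, unknown, mode = c("merge", "project"),
                         nComponents = "all", sigmaDivisor = c("n", "n-1"),
                         coverageThreshold = 0.05, sampleId = "unknown") {
  mode <- match.arg(mode)
  sigmaDivisor <- match.arg(sigmaDivisor)
  genes <- .resolveGenes(model@classifierGenes, names(unknown),
                         model@nodeId, coverageThreshold)
  ref <- model@refMatrix[genes, , drop = FALSE]
  u <- unknown[genes]
  if (!all(is.finite(u)))
    .stopFormat("unknown sample has non-finite classifier values")
  if (mode == "merge") {
    proj <- mergeAndProject(ref, u, sampleId = sampleId,
                            nComponents = nComponents)
    sc <- pcaScores(proj)
    refScores <- sc[seq_len(ncol(ref)), , drop = FALSE]
    uScore <- sc[nrow(sc), ]
  } else {
    proj <- fitPCA(ref, nComponents = nComponents)
    refScores <- pcaScores(proj)
    uScore <- projectSample(proj, u)
  }
  w <- pcaWeights(proj)
  assign <- model@childAssign[colnames(ref)]
  dists <- sigmas <- setNames(numeric(length(model@childLabels)),
                              model@childLabels)
  for (child in model@childLabels) {
    rows <- refScores[assign == child, , drop = FALSE]
    ctr <- scoreCentroid(rows)
    dd <- apply(rows, 1L, weightedDistance, v = ctr, w = w)
    sigmas[[child]] <- .sdDiv(dd, sigmaDivisor)
    dists[[child]] <- weightedDistance(uScore, ctr, w)
  }
  probs <- membershipProbabilities(dists)
  rd <- setNames(vapply(model@childLabels, function(child)
    relativeDistance(dists[[child]], sigmas[[child]]), numeric(1)),
    model@childLabels)
  dmin <- min(dists)
  tiedChildren <- names(dists)[dists <= dmin + 1e-12]
  assigned <- tiedChildren[1L]   # first declared child wins a tie
  tied <- length(tiedChildren) > 1L
  if (tied)
    warning(sprintf("node '%s': tied minimum distance between %s; '%s' wins",
                    model@nodeId, paste(tiedChildren, collapse = ", "),
                    assigned), call. = FALSE)
  k3 <- seq_len(min(3L, length(uScore)))
  new("NodeResult", nodeId = model@nodeId, distances = dists,
      probabilities = probs, relativeDistances = rd,
      assignedChild = assigned,
      pc3 = list(unknown = uScore[k3],
                 reference = refScores[, k3, drop = FALSE],
                 labels = unname(assign)),
      tied = tied)
}

#' Hierarchical classification of an unknown sample
#'
#' Descends the subtype hierarchy from the root, classifying the unknown at
#' each node with [classifyNode()] and following the assigned child until a
#' leaf is reached. The sample is flagged as an outlier when the assigned
#' child's relative distance exceeds `outlierThreshold` at any level; the
#' assignment itself is never suppressed.
#'
#' @param bundle a [ReferenceBundle-class].
#' @param unknown named numeric expression vector.
#' @param sampleId identifier reported for the sample.
#' @param outlierThreshold relative-distance cutoff for the outlier flag
#'   (default 3, a three-sigma convention).
#' @inheritParams classifyNode
#' @return A [PredictionResult-class].
#' @examples
#' spec <- simulationSpec(nPerLeaf = 5, genesPerNode = 10, seed = 7)
#' cohort <- simulateCohort(spec)
#' bundle <- buildReference(cohort$reference, spec@hierarchy,
#'                          cohort$classifierSets)
#' u <- makeUnknown(spec, "OA")
#' classifyHierarchical(bundle, u)
#' @export
classifyHierarchical <- function(bundle, unknown, sampleId = "unknown",
                                 mode = c("merge", "project"),
                                 nComponents = "all",
                                 sigmaDivisor = c("n", "n-1"),
                                 outlierThreshold = 3,
                                 coverageThreshold = 0.05) {
  mode <- match.arg(mode)
  sigmaDivisor <- match.arg(sigmaDivisor)
  if (!is.numeric(outlierThreshold) || outlierThreshold <= 0)
    .stopParameter("outlierThreshold must be > 0")
  hierarchy <- bundle@hierarchy
  models <- bundle@models
  results <- list()
  outlier <- FALSE
  id <- hierarchy@rootId
  repeat {
    nr <- classifyNode(models[[id]], unknown, mode = mode,
                       nComponents = nComponents,
                       sigmaDivisor = sigmaDivisor,
                       coverageThreshold = coverageThreshold,
                       sampleId = sampleId)
    results[[id]] <- nr
    if (nr@relativeDistances[[nr@assignedChild]] > outlierThreshold)
      outlier <- TRUE
    nxt <- hierarchy@nodes[[id]]$childNode[[nr@assignedChild]]
    if (is.na(nxt)) {
      final <- nr@assignedChild
      break
    }
    id <- nxt
  }
  new("PredictionResult", sampleId = sampleId, nodeResults = results,
      finalSubtype = final, outlierFlag = outlier,
      outlierRule = sprintf(
        "outlier if relative distance of assigned child > %g at any level",
        outlierThreshold),
      config = list(mode = mode, nComponents = nComponents,
                    sigmaDivisor = sigmaDivisor,
                    outlierThreshold = outlierThreshold,
                    coverageThreshold = coverageThreshold))
}

#' @describeIn classifyHierarchical assigned leaf label of a prediction.
#' @param result a `PredictionResult`.
#' @export
finalSubtype <- function(result) result@finalSubtype

#' @describeIn classifyHierarchical list of per-node results along the
#'   descent path.
#' @export
nodeResults <- function(result) result@nodeResults

#' @describeIn classifyHierarchical outlier flag of a prediction.
#' @export
isOutlier <- function(result) result@outlierFlag

setMethod("show", "NodeResult", function(object) {
  cat("NodeResult '", object@nodeId, "': assigned ", object@assignedChild,
      "\n", sep = "")
  df <- data.frame(distance = object@distances,
                   probability = object@probabilities,
                   relativeDistance = object@relativeDistances)
  print(round(df, 4))
})

setMethod("show", "PredictionResult", function(object) {
  path <- vapply(object@nodeResults, function(nr) nr@assignedChild,
                 character(1))
  cat("PredictionResult for '", object@sampleId, "': ",
      paste(path, collapse = " -> "), "\n", sep = "")
  cat("  final subtype:", object@finalSubtype,
      if (object@outlierFlag) "(OUTLIER)" else "", "\n")
  for (nr in object@nodeResults) {
    p <- nr@probabilities
    cat(sprintf("  %-6s %s\n", nr@nodeId,
                paste(sprintf("p(%s)=%.3f", names(p), p), collapse = ", ")))
  }
})
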