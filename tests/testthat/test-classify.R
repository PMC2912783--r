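test_that("weightedDistance evaluates the formula", {
  expect_equal(weightedDistance(c(1, 2, 3), c(1, 2, 3), c(1, 1, 1)), 0)
  expect_equal(weightedDistance(c(0, 0), c(3, 4), c(1, 1)), 5)
  expect_equal(weightedDistance(c(0, 0), c(3, 4), c(0.5, 0.5)),
               3.535534, tolerance = 1e-6)
  expect_error(weightedDistance(c(1, 2), c(1, 2, 3), c(1, 1, 1)),
               class = "subtypeParameterError")
  expect_error(weightedDistance(c(1, 2), c(0, 0), c(-1, 1)),
               class = "subtypeParameterError")
})

test_that("weightedDistance is a metric on shared weights", {
  withr::with_seed(12, {
    for (i in 1:50) {
      n <- sample(2:8, 1)
      u <- rnorm(n); v <- rnorm(n); x <- rnorm(n)
      w <- runif(n)
      expect_equal(weightedDistance(u, v, w), weightedDistance(v, u, w))
      expect_lte(weightedDistance(u, x, w),
                 weightedDistance(u, v, w) + weightedDistance(v, x, w) +
                   1e-12)
    }
  })
})

test_that("membership probabilities normalize and reverse distance order", {
  expect_equal(unname(membershipProbabilities(c(A = 1, B = 1))),
               c(0.5, 0.5))
  expect_equal(unname(membershipProbabilities(c(A = 1, B = 3))),
               c(0.75, 0.25))
  expect_equal(unname(membershipProbabilities(c(A = 0, B = 2))), c(1, 0))
  expect_error(membershipProbabilities(c(A = 0, B = 0)),
               class = "subtypeDegenerateError")
  expect_error(membershipProbabilities(c(A = 1)),
               class = "subtypeParameterError")
  withr::with_seed(4, {
    for (i in 1:20) {
      d <- setNames(runif(4, 0.1, 5), letters[1:4])
      p <- membershipProbabilities(d)
      expect_equal(sum(p), 1, tolerance = 1e-12)
      expect_identical(order(p), rev(order(d)))
    }
  })
})

test_that("decreasing one distance strictly increases its probability", {
  d <- c(A = 2, B = 3, C = 4)
  p1 <- membershipProbabilities(d)
  d["A"] <- 1
  p2 <- membershipProbabilities(d)
  expect_gt(p2[["A"]], p1[["A"]])
  expect_lt(p2[["B"]], p1[["B"]])
})

test_that("relativeDistance is d/sigma with guarded degeneracy", {
  expect_equal(relativeDistance(0, 1), 0)
  expect_equal(relativeDistance(0.8, 0.8), 1)
  expect_equal(relativeDistance(2.4, 0.8), 3)
  expect_error(relativeDistance(1, 0), class = "subtypeDegenerateError")
  expect_error(relativeDistance(-1, 1), class = "subtypeParameterError")
})

test_that("rescaling all scores leaves p and r_D unchanged", {
  withr::with_seed(8, {
    u <- rnorm(5); v1 <- rnorm(5); v2 <- rnorm(5); w <- runif(5)
    c0 <- 3.7
    d <- c(A = weightedDistance(u, v1, w), B = weightedDistance(u, v2, w))
    dScaled <- c(A = weightedDistance(c0 * u, c0 * v1, w),
                 B = weightedDistance(c0 * u, c0 * v2, w))
    expect_equal(dScaled, c0 * d, tolerance = 1e-12)
    expect_equal(membershipProbabilities(dScaled),
                 membershipProbabilities(d), tolerance = 1e-12)
    sigma <- 0.4
    expect_equal(relativeDistance(dScaled[["A"]], c0 * sigma),
                 relativeDistance(d[["A"]], sigma), tolerance = 1e-12)
  })
})

# a hand-built two-child node model over raw expression
.twoChildModel <- function(seed = 101, n = 20, g = 30, delta = 4,
                           labels = c("A", "B")) {
  withr::with_seed(seed, {
    shift <- c(rep(delta, g / 2), rep(0, g / 2))
    mA <- matrix(rnorm(g * n), g) + shift
    mB <- matrix(rnorm(g * n), g) + rev(shift)
    m <- cbind(mA, mB)
    dimnames(m) <- list(paste0("g", seq_len(g)),
                        paste0("s", seq_len(2 * n)))
    assign <- setNames(rep(labels, each = n), colnames(m))
    new("ReferenceModel", nodeId = "node", classifierGenes = rownames(m),
        refMatrix = m, childLabels = labels, childAssign = assign)
  })
}

test_that("an unknown at a child's mean profile is assigned that child", {
  model <- .twoChildModel()
  isA <- modelChildAssign(model) == "A"
  u <- rowMeans(model@refMatrix[, isA])
  nr <- classifyNode(model, u)
  expect_identical(nr@assignedChild, "A")
  expect_gt(nr@probabilities[["A"]], 0.5)
  # the mean profile projects exactly onto the child centroid
  expect_equal(nr@distances[["A"]], 0, tolerance = 1e-8)
})

test_that("swapping child labels swaps the assignment", {
  model <- .twoChildModel()
  swapped <- new("ReferenceModel", nodeId = "node",
                 classifierGenes = model@classifierGenes,
                 refMatrix = model@refMatrix,
                 childLabels = c("B", "A"),
                 childAssign = setNames(
                   c(B = "A", A = "B")[model@childAssign],
                   names(model@childAssign)))
  u <- makeTwoChildUnknown(model, "A", seed = 9)
  expect_identical(classifyNode(model, u)@assignedChild, "A")
  expect_identical(classifyNode(swapped, u)@assignedChild, "B")
})

test_that("classifyNode reproduces an independent straight-line oracle", {
  model <- .twoChildModel(seed = 202)
  u <- makeTwoChildUnknown(model, "B", seed = 77)
  nr <- classifyNode(model, u)
  o <- oracleClassifyNode(model@refMatrix, modelChildAssign(model),
                          model@childLabels, u)
  expect_identical(nr@assignedChild, o$assignedChild)
  expect_identical(nr@assignedChild, "B")
  expect_equal(nr@distances, o$distances, tolerance = 1e-8)
  expect_equal(nr@probabilities, o$probabilities, tolerance = 1e-8)
  expect_equal(nr@relativeDistances, o$relativeDistances,
               tolerance = 1e-8)
})

test_that("assignment agrees between merge and project modes on clean data", {
  model <- .twoChildModel(seed = 303)
  for (child in c("A", "B")) {
    u <- makeTwoChildUnknown(model, child, seed = 11)
    expect_identical(classifyNode(model, u, mode = "merge")@assignedChild,
                     child)
    expect_identical(classifyNode(model, u, mode = "project")@assignedChild,
                     child)
  }
})

test_that("exact distance ties go to the first declared child with a warning", {
  # mirror-symmetric children around the origin; unknown at the origin
  m <- cbind(A1 = c(1, 1), A2 = c(1, -1), A3 = c(1, 0),
             B1 = c(-1, 1), B2 = c(-1, -1), B3 = c(-1, 0))
  rownames(m) <- c("g1", "g2")
  model <- new("ReferenceModel", nodeId = "node",
               classifierGenes = rownames(m), refMatrix = m,
               childLabels = c("A", "B"),
               childAssign = setNames(rep(c("A", "B"), each = 3),
                                      colnames(m)))
  u <- c(g1 = 0, g2 = 0)
  expect_warning(nr <- classifyNode(model, u), "tied")
  expect_identical(nr@assignedChild, "A")
  expect_true(nr@tied)
  expect_equal(nr@distances[["A"]], nr@distances[["B"]], tolerance = 1e-12)
})

test_that("hierarchical descent follows the assigned child to a leaf", {
  spec <- smallSpec(seed = 41)
  cohort <- simulateCohort(spec)
  bundle <- buildReference(cohort$reference, spec@hierarchy,
                           cohort$classifierSets)
  # an unknown at the OA mean profile descends root -> O and lands on OA
  labels <- subtypeLabels(cohort$reference)
  u <- rowMeans(exprsMatrix(cohort$reference)[, labels == "OA"])
  res <- classifyHierarchical(bundle, u)
  expect_identical(names(nodeResults(res)), c("root", "O"))
  expect_identical(nodeResults(res)$root@assignedChild, "O")
  expect_identical(finalSubtype(res), "OA")
  expect_false(isOutlier(res))
})

test_that("the descent path is internally consistent for random unknowns", {
  spec <- smallSpec(seed = 43)
  cohort <- simulateCohort(spec)
  bundle <- buildReference(cohort$reference, spec@hierarchy,
                           cohort$classifierSets)
  h <- spec@hierarchy
  leaves <- leafLabels(h)
  for (i in 1:20) {
    u <- makeUnknown(spec, leaves[(i %% 6) + 1], seed = 1000 + i)
    res <- classifyHierarchical(bundle, u)
    nrs <- nodeResults(res)
    for (j in seq_along(nrs)) {
      nxt <- h@nodes[[nrs[[j]]@nodeId]]$childNode[[nrs[[j]]@assignedChild]]
      if (j < length(nrs)) expect_identical(nxt, nrs[[j + 1]]@nodeId)
      else expect_true(is.na(nxt))
      # the final leaf nests under every upstream assigned child
      sub <- nrs[[j]]@assignedChild
      under <- if (is.na(nxt)) sub else leafLabels(h, nxt)
      expect_true(finalSubtype(res) %in% under)
    }
    expect_equal(sum(nrs[[1]]@probabilities), 1, tolerance = 1e-9)
  }
})

test_that("a far-displaced probe is flagged as an outlier", {
  spec <- smallSpec(seed = 47)
  cohort <- simulateCohort(spec)
  bundle <- buildReference(cohort$reference, spec@hierarchy,
                           cohort$classifierSets)
  probe <- makeUnknown(spec, "GA1", displacement = 10, seed = 5)
  res <- classifyHierarchical(bundle, probe)
  expect_true(isOutlier(res))
  rdRoot <- nodeResults(res)$root
  expect_gt(rdRoot@relativeDistances[[rdRoot@assignedChild]], 3)
})
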