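test_that("node models contain the nested sample sets", {
  spec <- simulationSpec(nPerLeaf = 10, genesPerNode = 8, nBackground = 10,
                         seed = 2)
  cohort <- simulateCohort(spec)
  bundle <- buildReference(cohort$reference, spec@hierarchy,
                           cohort$classifierSets)
  models <- bundleModels(bundle)
  expect_setequal(names(models), c("root", "O", "G"))
  expect_length(modelSamples(models$root), 60L)
  expect_length(modelSamples(models$O), 20L)
  expect_length(modelSamples(models$G), 40L)
  # nesting: each non-root node holds exactly the parent samples whose
  # parent-level label equals the node's label
  labels <- subtypeLabels(cohort$reference)
  rollup <- leafToChildMap(spec@hierarchy, "root")
  expect_setequal(modelSamples(models$O),
                  names(labels)[rollup[labels] == "O"])
  expect_setequal(modelSamples(models$G),
                  names(labels)[rollup[labels] == "G"])
})

test_that("a child with fewer than 2 samples fails the build by name", {
  m <- randomExprMatrix(6, 5, seed = 1)
  labels <- setNames(c("OA", "OA", "OB", "GA1", "GA2"), colnames(m))
  ref <- LabeledReference(m, labels)
  sets <- list(root = rownames(m)[1:2], O = rownames(m)[3:4],
               G = rownames(m)[5:6])
  expect_error(
    buildReference(ref, defaultHierarchy(), sets),
    "OB", class = "subtypeBuildError")
})

test_that("missing classifier genes follow the coverage policy", {
  spec <- smallSpec()
  cohort <- simulateCohort(spec)
  sets <- cohort$classifierSets
  # one phantom gene in a 12-gene list is 8% missing: over the threshold
  sets$root <- c(sets$root, "not_a_gene")
  expect_error(
    buildReference(cohort$reference, spec@hierarchy, sets),
    "not_a_gene", class = "subtypeCoverageError")
  # a permissive threshold downgrades it to a warning and drops the gene
  expect_warning(
    bundle <- buildReference(cohort$reference, spec@hierarchy, sets,
                             coverageThreshold = 0.2),
    "not_a_gene")
  expect_false("not_a_gene" %in%
                 bundleModels(bundle)$root@classifierGenes)
})

test_that("scoreCentroid is the component-wise mean", {
  expect_equal(scoreCentroid(rbind(c(0, 0), c(2, 2))), c(1, 1))
  expect_equal(scoreCentroid(rbind(c(3, -1))), c(3, -1))
  withr::with_seed(6, {
    rows <- matrix(rnorm(100), 50, 2)
    manual <- c(sum(rows[, 1]) / 50, sum(rows[, 2]) / 50)
    expect_equal(unname(scoreCentroid(rows)), manual, tolerance = 1e-12)
  })
})

test_that("per-child dispersion matches a brute-force recomputation", {
  spec <- smallSpec(seed = 31)
  cohort <- simulateCohort(spec)
  bundle <- buildReference(cohort$reference, spec@hierarchy,
                           cohort$classifierSets)
  model <- bundleModels(bundle)$root
  u <- makeUnknown(spec, "OA", seed = 99)
  nr <- classifyNode(model, u)
  o <- oracleClassifyNode(model@refMatrix, modelChildAssign(model),
                          model@childLabels, u)
  # sigma enters the result only through r_D = d / sigma
  expect_equal(nr@distances / nr@relativeDistances, o$sigmas,
               tolerance = 1e-8)
})

test_that("build is invariant to sample order", {
  spec <- smallSpec(seed = 17)
  cohort <- simulateCohort(spec)
  m <- exprsMatrix(cohort$reference)
  labels <- subtypeLabels(cohort$reference)
  perm <- withr::with_seed(5, sample(ncol(m)))
  refPerm <- LabeledReference(m[, perm], labels[perm])
  u <- makeUnknown(spec, "GB1", seed = 55)
  b1 <- buildReference(cohort$reference, spec@hierarchy,
                       cohort$classifierSets)
  b2 <- buildReference(refPerm, spec@hierarchy, cohort$classifierSets)
  n1 <- classifyNode(bundleModels(b1)$root, u)
  n2 <- classifyNode(bundleModels(b2)$root, u)
  expect_equal(n1@distances, n2@distances, tolerance = 1e-10)
  expect_equal(n1@relativeDistances, n2@relativeDistances,
               tolerance = 1e-10)
})

test_that("reference bundles survive a JSON round trip", {
  spec <- smallSpec(seed = 23)
  cohort <- simulateCohort(spec)
  bundle <- buildReference(cohort$reference, spec@hierarchy,
                           cohort$classifierSets)
  path <- withr::local_tempfile(fileext = ".json")
  writeReferenceBundle(bundle, path)
  back <- readReferenceBundle(path)
  expect_identical(nodeIds(bundleHierarchy(back)),
                   nodeIds(bundleHierarchy(bundle)))
  for (id in names(bundleModels(bundle))) {
    m1 <- bundleModels(bundle)[[id]]
    m2 <- bundleModels(back)[[id]]
    expect_identical(m2@classifierGenes, m1@classifierGenes)
    expect_identical(m2@childAssign, m1@childAssign)
    expect_equal(m2@refMatrix, m1@refMatrix, tolerance = 1e-12)
  }
  # and predictions through the reloaded bundle are identical
  u <- makeUnknown(spec, "OA", seed = 3)
  r1 <- classifyHierarchical(bundle, u)
  r2 <- classifyHierarchical(back, u)
  expect_identical(finalSubtype(r1), finalSubtype(r2))
  expect_equal(nodeResults(r1)$root@probabilities,
               nodeResults(r2)$root@probabilities, tolerance = 1e-12)
})
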