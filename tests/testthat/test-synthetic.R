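test_that("degenerate growth settings force the predicted topology", {
  # no branching: one unbranched chain, length about the drawn branch length
  p <- growthParams(nStems = 1, branchProb = 0, meanBranchLenUm = 100,
                    branchLenCv = 1e-6, stepUm = 10)
  nt <- growNeuron(p, seed = 1)
  expect_identical(terminalCount(nt), 1L)
  expect_equal(totalDendriticLength(nt), 100, tolerance = 1e-3)
  kids <- table(nodeTable(nt)$parent)
  expect_true(all(kids == 1))      # a pure chain

  # certain bifurcation to the order cap: 2^(maxOrder-1) terminals
  p <- growthParams(nStems = 1, branchProb = 1, maxOrder = 3)
  for (seed in 1:5)
    expect_identical(terminalCount(growNeuron(p, seed = seed)), 4L)
})

test_that("growth is deterministic under a seed", {
  p <- growthParams()
  a <- growNeuron(p, seed = 42)
  b <- growNeuron(p, seed = 42)
  expect_identical(nodeTable(a), nodeTable(b))
  c <- growNeuron(p, seed = 43)
  expect_false(identical(nodeTable(a), nodeTable(c)))
})

test_that("every generated tree is valid and survives an SWC round-trip", {
  p <- growthParams()
  for (seed in 1:20) {
    nt <- growNeuron(p, seed = seed)
    expect_identical(validateNeuronTree(nt), character(0))
  }
  nt <- growNeuron(p, seed = 101)
  f <- withr::local_tempfile(fileext = ".swc")
  writeSWC(nt, f)
  expect_identical(totalDendriticLength(readSWC(f)),
                   totalDendriticLength(nt))
})

test_that("cohort mean length matches the branching-process expectation", {
  p <- growthParams()
  ex <- expectedMorphometry(p)
  # closed form: E[branches per stem] = sum over orders of (2p)^(k-1)
  expect_equal(ex$branchesPerStem, 1 + 1.6 + 1.6^2)
  expect_equal(ex$expectedLength, 3 * (1 + 1.6 + 1.6^2) * 47)

  trees <- generateCohort(cohortSpec("AD06", 60, p), seed = 9)
  L <- vapply(trees, totalDendriticLength, 1)
  sem <- sd(L) / sqrt(length(L))
  expect_lt(abs(mean(L) - ex$expectedLength), 3 * sem)

  Tn <- vapply(trees, terminalCount, 1L)
  semT <- sd(Tn) / sqrt(length(Tn))
  expect_lt(abs(mean(Tn) - ex$expectedTerminals), 3 * semT)

  # dispersion and reach of the default process: length CV in the range
  # of traced pyramidal cohorts, arbors spanning a couple hundred um
  expect_gt(sd(L) / mean(L), 0.15)
  expect_lt(sd(L) / mean(L), 0.40)
  rmax <- vapply(trees, function(t) {
    nd <- nodeTable(t)
    max(sqrt(nd$x^2 + nd$y^2 + nd$z^2))
  }, 1.0)
  expect_gt(median(rmax), 120)
  expect_lt(median(rmax), 300)
})

test_that("cohorts are reproducible and carry ordered metadata", {
  spec <- cohortSpec("AD12", 8, region = "CA1")
  a <- generateCohort(spec, seed = 5)
  b <- generateCohort(spec, seed = 5)
  expect_identical(lapply(a, nodeTable), lapply(b, nodeTable))
  metas <- lapply(a, specimenMeta)
  expect_identical(vapply(metas, function(m) m@cohort, ""), rep("AD12", 8))
  expect_identical(vapply(metas, function(m) m@neuronIndex, 1L), 1:8)
})

test_that("a planted length multiplier shifts the cohort mean by that ratio", {
  p <- growthParams()
  ratios <- vapply(1:10, function(r) {
    a <- generateCohort(cohortSpec("A", 40, p), seed = r)
    b <- generateCohort(cohortSpec("B", 40, p, lengthEffect = 1.2),
                        seed = 1000 + r)
    mean(vapply(b, totalDendriticLength, 1)) /
      mean(vapply(a, totalDendriticLength, 1))
  }, 1.0)
  expect_equal(mean(ratios), 1.2, tolerance = 0.05)
})

test_that("centroid fields are Poisson with the requested intensity", {
  ext <- regionExtent(c(300, 300, 300))
  expect_identical(nrow(generateCentroidField(ext, 0, seed = 1)), 0L)

  lambda <- 25 / 300^3
  counts <- vapply(1:200, function(s)
    nrow(generateCentroidField(ext, lambda, seed = s)), 1L)
  expect_equal(mean(counts), 25, tolerance = 0.1)
  # Poisson dispersion: variance close to the mean
  expect_gt(var(counts) / mean(counts), 0.7)
  expect_lt(var(counts) / mean(counts), 1.4)

  f1 <- generateCentroidField(ext, lambda, seed = 7)
  f2 <- generateCentroidField(ext, lambda, seed = 7)
  expect_identical(f1, f2)
  inRange <- f1 >= 0 & f1 <= 300
  expect_true(all(inRange))
})

test_that("cohorts written to disk read back with identical metrics", {
  dir <- withr::local_tempdir()
  trees <- generateCohort(cohortSpec("AD06", 5, region = "PMC"), seed = 2)
  writeCohort(trees, dir)
  expect_true(file.exists(file.path(dir, "metadata.csv")))
  expect_length(list.files(dir, pattern = "\\.swc$"), 5L)
  back <- readCohort(dir)
  expect_length(back, 5L)
  expect_equal(vapply(back, totalDendriticLength, 1),
               vapply(trees, totalDendriticLength, 1))
  expect_identical(vapply(back, function(t) specimenMeta(t)@cohort, ""),
                   rep("AD06", 5))
})
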