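test_that("a minimal soma-dendrite chain is structurally valid", {
  nt <- makeChainTree(3)
  expect_identical(validateNeuronTree(nt), character(0))
  expect_equal(nNodes(nt), 3L)
  expect_identical(somaId(nt), 1L)
  expect_equal(unname(somaPosition(nt)), c(0, 0, 0))
})

test_that("structural violations are diagnosed, not raised", {
  selfLoop <- NeuronTree(data.frame(id = 1:2, parent = c(NA, 2),
                                    x = 0:1, y = 0, z = 0), check = FALSE)
  v <- validateNeuronTree(selfLoop)
  expect_true(any(grepl("cycle", v)))
  expect_true(any(grepl("2", v)))

  twoRoots <- NeuronTree(data.frame(id = 1:2, parent = c(NA, NA),
                                    x = 0:1, y = 0, z = 0), check = FALSE)
  v <- validateNeuronTree(twoRoots)
  expect_true(any(grepl("multiple roots", v)))

  dangling <- NeuronTree(data.frame(id = 1:2, parent = c(NA, 99),
                                    x = 0:1, y = 0, z = 0), check = FALSE)
  expect_true(any(grepl("dangling", validateNeuronTree(dangling))))

  disconnected <- NeuronTree(data.frame(id = 1:4, parent = c(NA, 1, 4, 3),
                                        x = c(0, 1, 5, 6), y = 0, z = 0),
                             check = FALSE, mergeDuplicates = FALSE)
  expect_true(any(grepl("unreachable", validateNeuronTree(disconnected))))

  expect_error(NeuronTree(data.frame(id = 1:2, parent = c(NA, 99),
                                     x = 0:1, y = 0, z = 0)),
               "invalid NeuronTree")
})

test_that("segment extraction yields one segment per parent-child pair", {
  one <- NeuronTree(data.frame(id = 1:2, parent = c(NA, 1),
                               x = c(0, 3), y = c(0, 4), z = 0))
  seg <- extractSegments(one)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$length, 5)
  expect_true(seg$childIsTerminal)

  fork <- NeuronTree(data.frame(id = 1:3, parent = c(NA, 1, 1),
                                x = c(0, 1, -1), y = 0, z = 0))
  seg <- extractSegments(fork)
  expect_equal(nrow(seg), 2L)
  expect_true(all(seg$childIsTerminal))
})

test_that("random trees with N nodes decompose into N - 1 segments", {
  for (seed in 1:10) {
    nt <- makeRandomTree(50, seed)
    seg <- extractSegments(nt)
    expect_equal(nrow(seg), 49L)
    # every node is reachable: total of the oracle edge walk matches
    expect_equal(sum(seg$length), oracleLength(nt))
  }
})

test_that("duplicate tracing points are merged with a warning", {
  nd <- data.frame(id = 1:4, parent = c(NA, 1, 2, 3),
                   x = c(0, 5, 5, 9), y = 0, z = 0)
  expect_warning(nt <- NeuronTree(nd), "duplicate tracing point")
  expect_equal(nNodes(nt), 3L)
  expect_equal(totalDendriticLength(nt), 9)
  expect_equal(nrow(extractSegments(nt)), 2L)
})

test_that("specimen metadata travels with the tree", {
  nt <- makeChainTree(2)
  specimenMeta(nt) <- SpecimenMeta(cohort = "AD06", region = "CA1",
                                   hemisphere = "L", layer = "L1",
                                   neuronIndex = 3L)
  m <- specimenMeta(nt)
  expect_identical(m@cohort, "AD06")
  expect_identical(m@neuronIndex, 3L)
  expect_error(SpecimenMeta(hemisphere = "X"), "hemisphere")
})
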