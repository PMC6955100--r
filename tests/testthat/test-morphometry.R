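test_that("scalar metrics match hand-computed values on tiny trees", {
  tri <- NeuronTree(data.frame(id = 1:2, parent = c(NA, 1),
                               x = c(0, 3), y = c(0, 4), z = 0))
  expect_equal(totalDendriticLength(tri), 5)
  expect_identical(terminalCount(tri), 1L)
  expect_equal(spatialVolume(tri), 0)

  s <- summarizeMorphometry(tri)
  expect_equal(s$length_um, 5)
  expect_equal(s$terminal_count, 1L)
  expect_equal(s$spatial_volume_um3, 0)
  expect_identical(s$volume_mode, "box")

  soma <- NeuronTree(data.frame(id = 1, parent = NA, x = 0, y = 0, z = 0))
  expect_equal(totalDendriticLength(soma), 0)
  expect_warning(tc <- terminalCount(soma), "soma-only")
  expect_identical(tc, 0L)
  expect_warning(s <- summarizeMorphometry(soma), "soma-only")
  expect_equal(s$length_um, 0)
  expect_equal(s$spatial_volume_um3, 0)
})

test_that("terminal count is the number of last-stage branches", {
  expect_identical(terminalCount(makeChainTree(10)), 1L)
  expect_identical(terminalCount(makeBinaryTree(2)), 4L)
  # branching process with certain bifurcation: 2^(maxOrder - 1) leaves
  nt <- growNeuron(growthParams(nStems = 1, branchProb = 1, maxOrder = 3),
                   seed = 5)
  expect_identical(terminalCount(nt), 4L)
})

test_that("spatial volume supports box and strict-cube readings", {
  cube <- NeuronTree(data.frame(
    id = 1:4, parent = c(NA, 1, 1, 1),
    x = c(0, 1, 0, 0), y = c(0, 0, 1, 0), z = c(0, 0, 0, 1)))
  expect_equal(spatialVolume(cube), 1)
  expect_equal(spatialVolume(cube, mode = "cube"), 1)

  slab <- NeuronTree(data.frame(id = 1:3, parent = c(NA, 1, 2),
                                x = c(0, 4, 4), y = c(0, 0, 2), z = 0))
  expect_equal(spatialVolume(slab), 0)        # flat in z
  expect_equal(spatialVolume(slab, mode = "cube"), 64)

  collinear <- makeChainTree(5)
  expect_equal(spatialVolume(collinear), 0)
})

test_that("metrics agree with brute-force node-table oracles", {
  for (seed in 1:8) {
    nt <- makeRandomTree(100, seed)
    expect_equal(totalDendriticLength(nt), oracleLength(nt))
    expect_identical(terminalCount(nt), oracleTerminals(nt))
    expect_equal(spatialVolume(nt), oracleBoxVolume(nt))
  }
})

test_that("full binary depth-2 fixture sums its six edges", {
  nt <- makeBinaryTree(2, edgeLen = 7)
  expect_identical(terminalCount(nt), 4L)
  expect_equal(totalDendriticLength(nt), 6 * 7)
})

test_that("metrics are invariant under translation and relabelling; L and T under rotation", {
  nt <- makeRandomTree(60, 99)
  nd <- nodeTable(nt)

  shifted <- nd
  shifted$x <- nd$x + 100; shifted$y <- nd$y - 40; shifted$z <- nd$z + 7
  ntS <- NeuronTree(shifted)
  expect_equal(totalDendriticLength(ntS), totalDendriticLength(nt))
  expect_identical(terminalCount(ntS), terminalCount(nt))
  expect_equal(spatialVolume(ntS), spatialVolume(nt))

  relabeled <- nd
  relabeled$id <- nd$id * 10L
  relabeled$parent <- nd$parent * 10L
  ntR <- NeuronTree(relabeled)
  expect_equal(totalDendriticLength(ntR), totalDendriticLength(nt))
  expect_identical(terminalCount(ntR), terminalCount(nt))

  rot <- rotateTree(nt)
  expect_equal(totalDendriticLength(rot), totalDendriticLength(nt))
  expect_identical(terminalCount(rot), terminalCount(nt))
  # the axis-aligned box is rotation-variant by construction: documented
  # limitation, asserted so it is never silently relied upon
  expect_false(isTRUE(all.equal(spatialVolume(rot), spatialVolume(nt))))
})

test_that("deleting a leaf edge shortens L by exactly that edge", {
  nt <- makeRandomTree(40, 4)
  seg <- extractSegments(nt)
  leafSeg <- seg[seg$childIsTerminal, ][1, ]
  nd <- nodeTable(nt)
  pruned <- NeuronTree(nd[nd$id != leafSeg$childId, ])
  expect_equal(totalDendriticLength(pruned),
               totalDendriticLength(nt) - leafSeg$length)
  expect_equal(nrow(extractSegments(pruned)), nrow(seg) - 1L)
})
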