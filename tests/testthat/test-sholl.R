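test_that("segment-sphere crossing counts follow the quadratic geometry", {
  o <- c(0, 0, 0)
  # radial ray from the centre crosses once
  expect_identical(segmentSphereCrossings(c(0, 0, 0), c(100, 0, 0), o, 30), 1L)
  # chord entering and leaving: endpoints at sqrt(1025) > 30, closest 25
  expect_identical(segmentSphereCrossings(c(25, -20, 0), c(25, 20, 0), o, 30),
                   2L)
  # tangent: closest approach exactly 30 counts 0 by default
  expect_identical(segmentSphereCrossings(c(30, -10, 0), c(30, 10, 0), o, 30),
                   0L)
  expect_identical(
    segmentSphereCrossings(c(30, -10, 0), c(30, 10, 0), o, 30,
                           tangencyCounts = TRUE), 1L)
  # fully inside and fully outside
  expect_identical(segmentSphereCrossings(c(1, 0, 0), c(2, 0, 0), o, 30), 0L)
  expect_identical(segmentSphereCrossings(c(50, 0, 0), c(60, 0, 0), o, 30), 0L)
  expect_warning(n <- segmentSphereCrossings(c(1, 1, 1), c(1, 1, 1), o, 30),
                 "degenerate")
  expect_identical(n, 0L)
})

test_that("a node exactly on a shell is attributed to exactly one segment", {
  # chain 0 -> 30 -> 60 along x: the shell at r = 30 passes through node 2,
  # shared by both adjoining segments; half-open [0, 1) counts it once
  nt <- makeChainTree(3, step = 30)
  pr <- shollProfile(nt, stepUm = 30)
  expect_identical(intersectionCounts(pr)[shellRadii(pr) == 30], 1L)
  expect_identical(intersectionCounts(pr)[shellRadii(pr) == 60], 0L)
})

test_that("a straight radial dendrite crosses each interior shell once", {
  nt <- makeChainTree(11, step = 10)  # 0..100 um in 10 um steps
  pr <- shollProfile(nt, stepUm = 30, maxRadiusUm = 120)
  expect_equal(shellRadii(pr), c(30, 60, 90, 120))
  expect_identical(intersectionCounts(pr), c(1L, 1L, 1L, 0L))
  expect_true(all(intersectionCounts(pr) %in% 0:1))
})

test_that("a fixture with a known radial layout gives the constructed profile", {
  # one stem to radius 40, bifurcating into two leaves at radius 70
  nodes <- data.frame(
    id = 1:7, parent = c(NA, 1, 2, 3, 3, 4, 5),
    x = c(0, 20, 40, 50, 50, 60, 60),
    y = c(0, 0, 0, 10, -10, 30, -30),
    z = 0)
  nt <- NeuronTree(nodes)
  pr <- shollProfile(nt, stepUm = 30)
  expect_identical(intersectionCounts(pr)[1], 1L)  # stem crossing at 30
  expect_identical(intersectionCounts(pr)[2], 2L)  # both daughters at 60
  expect_identical(intersectionCounts(pr),
                   oracleSholl(nt, shellRadii(pr)))
})

test_that("exact profiles equal the dense-sampling oracle on random trees", {
  for (seed in 1:25) {
    nt <- growNeuron(growthParams(), seed = seed)
    pr <- shollProfile(nt)
    expect_identical(intersectionCounts(pr),
                     oracleSholl(nt, shellRadii(pr), ds = 0.05))
  }
})

test_that("profiles are invariant under rigid rotation about the soma", {
  nt <- growNeuron(growthParams(), seed = 77)
  rot <- rotateTree(nt, axis = c(1, 2, 0.5), angle = 1.1)
  expect_identical(intersectionCounts(shollProfile(nt)),
                   intersectionCounts(shollProfile(rot)))
})

test_that("crossing totals respect the 2-per-segment bound and vanish beyond the arbor", {
  for (seed in c(2, 9)) {
    nt <- growNeuron(growthParams(), seed = seed)
    pr <- shollProfile(nt)
    nSeg <- nrow(extractSegments(nt))
    expect_lte(sum(intersectionCounts(pr)),
               2 * nSeg * length(shellRadii(pr)))
    nd <- nodeTable(nt)
    rmax <- max(sqrt(nd$x^2 + nd$y^2 + nd$z^2))
    beyond <- shellRadii(pr) > rmax
    expect_true(all(intersectionCounts(pr)[beyond] == 0L))
  }
})

test_that("range aggregation sums the selected shells with outward snapping", {
  pr <- new("ShollProfile", radii = c(30, 60, 90),
            intersections = c(1L, 1L, 1L), stepUm = 30,
            meta = SpecimenMeta())
  expect_identical(aggregateRange(pr, 30, 90), 3L)
  expect_identical(aggregateRange(pr, 60, 60), 1L)
  expect_warning(v <- aggregateRange(pr, 45, 75), "snapped outward")
  expect_identical(v, 3L)  # snapped to [30, 90]
  expect_warning(v <- aggregateRange(pr, 120, 150), "empty")
  expect_identical(v, 0L)

  set.seed(31)
  for (i in 1:10) {
    counts <- as.integer(rpois(8, 3))
    p2 <- new("ShollProfile", radii = seq(30, 240, by = 30),
              intersections = counts, stepUm = 30, meta = SpecimenMeta())
    lo <- sample(c(30, 60, 90), 1); hi <- sample(c(120, 180, 240), 1)
    expect_identical(aggregateRange(p2, lo, hi),
                     as.integer(sum(counts[seq(30, 240, 30) >= lo &
                                             seq(30, 240, 30) <= hi])))
  }
})

test_that("profile alignment zero-pads onto the longest shell grid", {
  a <- new("ShollProfile", radii = c(30, 60), intersections = c(2L, 1L),
           stepUm = 30, meta = SpecimenMeta())
  b <- new("ShollProfile", radii = c(30, 60, 90, 120),
           intersections = c(3L, 2L, 2L, 1L), stepUm = 30,
           meta = SpecimenMeta())
  al <- alignShollProfiles(list(a, b))
  expect_equal(al$radii, c(30, 60, 90, 120))
  expect_equal(al$counts[1, ], c(2L, 1L, 0L, 0L))
  expect_equal(al$counts[2, ], c(3L, 2L, 2L, 1L))
  expect_error(alignShollProfiles(list(a, new("ShollProfile",
    radii = 20, intersections = 1L, stepUm = 20, meta = SpecimenMeta()))),
    "differing shell spacing")
})
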