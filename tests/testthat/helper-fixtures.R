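# Fixture builders and independent oracles shared across the suite.
# Everything is generated in code; no binary fixtures.

# unbranched chain from the origin along a given direction
makeChainTree <- function(n, step = 10, dir = c(1, 0, 0)) {
  dir <- dir / sqrt(sum(dir^2))
  d <- (seq_len(n) - 1) * step
  NeuronTree(data.frame(
    id = seq_len(n), parent = c(NA, seq_len(n - 1)),
    x = d * dir[1], y = d * dir[2], z = d * dir[3]))
}

# full binary tree of given depth; each edge has the given length, child
# directions fan out in the xy plane
makeBinaryTree <- function(depth = 2, edgeLen = 10) {
  nodes <- data.frame(id = 1L, parent = NA_integer_, x = 0, y = 0, z = 0)
  frontier <- data.frame(id = 1L, x = 0, y = 0, angle = pi / 2, span = pi / 2)
  nextId <- 2L
  for (d in seq_len(depth)) {
    newFrontier <- NULL
    for (i in seq_len(nrow(frontier))) {
      f <- frontier[i, ]
      for (s in c(-1, 1)) {
        ang <- f$angle + s * f$span / 2
        nodes <- rbind(nodes, data.frame(
          id = nextId, parent = f$id,
          x = f$x + edgeLen * cos(ang), y = f$y + edgeLen * sin(ang), z = 0))
        newFrontier <- rbind(newFrontier, data.frame(
          id = nextId, x = f$x + edgeLen * cos(ang),
          y = f$y + edgeLen * sin(ang), angle = ang, span = f$span / 2))
        nextId <- nextId + 1L
      }
    }
    frontier <- newFrontier
  }
  NeuronTree(nodes)
}

# random tree with guaranteed non-coincident nodes (for counting edges)
makeRandomTree <- function(nNodes, seed) {
  set.seed(seed)
  parent <- c(NA, vapply(2:nNodes, function(i) sample(i - 1L, 1L), 1L))
  pos <- matrix(0, nNodes, 3)
  for (i in 2:nNodes) {
    pos[i, ] <- pos[parent[i], ] + stats::rnorm(3, sd = 8) + 0.5
  }
  NeuronTree(data.frame(id = seq_len(nNodes), parent = parent,
                        x = pos[, 1], y = pos[, 2], z = pos[, 3]))
}

# brute-force morphometry oracles working on the raw node table only
oracleLength <- function(tree) {
  nd <- nodeTable(tree)
  total <- 0
  for (i in seq_len(nrow(nd))) {
    if (is.na(nd$parent[i])) next
    j <- which(nd$id == nd$parent[i])
    total <- total + sqrt(sum((c(nd$x[i], nd$y[i], nd$z[i]) -
                                 c(nd$x[j], nd$y[j], nd$z[j]))^2))
  }
  total
}

oracleTerminals <- function(tree) {
  nd <- nodeTable(tree)
  n <- 0L
  for (i in seq_len(nrow(nd))) {
    if (nd$id[i] == somaId(tree)) next
    if (!any(!is.na(nd$parent) & nd$parent == nd$id[i])) n <- n + 1L
  }
  n
}

oracleBoxVolume <- function(tree) {
  nd <- nodeTable(tree)
  (max(nd$x) - min(nd$x)) * (max(nd$y) - min(nd$y)) * (max(nd$z) - min(nd$z))
}

# dense-sampling Sholl oracle: sample each segment every `ds` micrometres
# and count sign changes of |p| - r along it
oracleSholl <- function(tree, radii, ds = 0.01) {
  seg <- extractSegments(tree)
  center <- somaPosition(tree)
  counts <- integer(length(radii))
  for (s in seq_len(nrow(seg))) {
    a <- c(seg$ax[s], seg$ay[s], seg$az[s])
    b <- c(seg$bx[s], seg$by[s], seg$bz[s])
    n <- max(2L, ceiling(seg$length[s] / ds))
    ts <- seq(0, 1, length.out = n + 1L)
    px <- a[1] + ts * (b[1] - a[1]) - center[1]
    py <- a[2] + ts * (b[2] - a[2]) - center[2]
    pz <- a[3] + ts * (b[3] - a[3]) - center[3]
    dist <- sqrt(px^2 + py^2 + pz^2)
    for (i in seq_along(radii)) {
      counts[i] <- counts[i] + sum(diff(dist > radii[i]) != 0)
    }
  }
  counts
}

# rigid rotation of a tree about its soma (for invariance checks)
rotateTree <- function(tree, axis = c(0, 0, 1), angle = pi / 5) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  nd <- nodeTable(tree)
  cen <- somaPosition(tree)
  xyz <- t(R %*% (t(as.matrix(nd[, c("x", "y", "z")])) - cen) + cen)
  nd$x <- xyz[, 1]; nd$y <- xyz[, 2]; nd$z <- xyz[, 3]
  NeuronTree(nd, meta = specimenMeta(tree))
}
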