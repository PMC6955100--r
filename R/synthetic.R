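#' Growth parameters for the stochastic neuron generator
#'
#' The generator grows a dendritic arbor as a branching process: from a
#' single soma at the origin, \code{nStems} primary dendrites emerge in
#' random directions; each branch is a straight polyline chain of nodes
#' \code{stepUm} apart with a gamma-distributed total length; at a branch
#' end the branch bifurcates with probability \code{branchProb} while its
#' centripetal order is below \code{maxOrder}, otherwise it terminates;
#' child directions are the parent direction perturbed by a random polar
#' angle up to \code{angleSpreadDeg}.
#'
#' Under these rules the expected number of branches per stem is
#' \eqn{\sum_{k=1}^{maxOrder} (2 p)^{k-1}} and the expected total
#' dendritic length is \code{nStems} times that, times
#' \code{meanBranchLenUm}; the expected terminal count follows the same
#' recursion with absorbing leaves. The defaults give a mean total
#' dendritic length near 720 µm, nine to ten terminal dendrites, a
#' bounding-box volume of a few 1e6 µm³ and a per-neuron length CV around
#' 0.27 — the scale and dispersion of traced cortical pyramidal neurons,
#' at which a planted 20\% length contrast is reliably detectable with 60
#' neurons per group.
#'
#' @param nStems number of primary dendrites (default 3).
#' @param meanBranchLenUm mean branch length, µm (default 47).
#' @param branchLenCv coefficient of variation of the gamma branch-length
#'   distribution (default 0.4; right-skewed, strictly positive).
#' @param branchProb bifurcation probability at a branch end (default
#'   0.8).
#' @param maxOrder branch-order cap (default 3; stems are order 1).
#' @param angleSpreadDeg maximal polar deviation of a child direction from
#'   its parent direction, degrees (default 35).
#' @param stepUm inter-node spacing along a branch, µm (default 10).
#' @return list of class \code{"growthParams"}.
#' @export
growthParams <- function(nStems = 3L, meanBranchLenUm = 47,
                         branchLenCv = 0.4, branchProb = 0.8,
                         maxOrder = 3L, angleSpreadDeg = 35,
                         stepUm = 10) {
  stopifnot(nStems >= 1, meanBranchLenUm > 0, branchLenCv > 0,
            branchProb >= 0, branchProb <= 1, maxOrder >= 1,
            angleSpreadDeg >= 0, stepUm > 0)
  structure(list(nStems = as.integer(nStems),
                 meanBranchLenUm = meanBranchLenUm,
                 branchLenCv = branchLenCv, branchProb = branchProb,
                 maxOrder = as.integer(maxOrder),
                 angleSpreadDeg = angleSpreadDeg, stepUm = stepUm),
            class = "growthParams")
}

#' Expected morphometrics of the growth process
#'
#' Closed-form expectations under the branching rules of
#' \code{\link{growthParams}}: expected branch count per stem
#' \eqn{\sum_{k=1}^{m} (2p)^{k-1}}, expected total length
#' \eqn{E[L] = nStems \cdot E[branches] \cdot meanBranchLen}, and expected
#' terminal count from the leaf recursion \eqn{T_m = 1},
#' \eqn{T_k = (1-p) + 2 p T_{k+1}}.
#'
#' @param params a \code{\link{growthParams}}.
#' @return list with \code{branchesPerStem}, \code{expectedLength},
#'   \code{expectedTerminals}.
#' @export
expectedMorphometry <- function(params) {
  p <- params$branchProb
  m <- params$maxOrder
  branches <- sum((2 * p)^(seq_len(m) - 1))
  leaves <- 1
  if (m > 1) for (k in seq.int(m - 1, 1)) leaves <- (1 - p) + 2 * p * leaves
  list(branchesPerStem = branches,
       expectedLength = params$nStems * branches * params$meanBranchLenUm,
       expectedTerminals = params$nStems * leaves)
}

.randomUnit <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-12) return(v / n)
  }
}

## Rotate `dir` by a polar angle drawn from U(0, spread) about a random
## axis perpendicular to it (Rodrigues rotation).
.perturbDirection <- function(dir, spreadDeg) {
  if (spreadDeg <= 0) return(dir)
  theta <- stats::runif(1, 0, spreadDeg * pi / 180)
  r <- .randomUnit()
  axis <- r - sum(r * dir) * dir
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) return(dir)
  axis <- axis / n
  dir * cos(theta) + .crossProduct(axis, dir) * sin(theta) +
    axis * sum(axis * dir) * (1 - cos(theta))
}

.crossProduct <- function(u, v) {
  c(u[2L] * v[3L] - u[3L] * v[2L],
    u[3L] * v[1L] - u[1L] * v[3L],
    u[1L] * v[2L] - u[2L] * v[1L])
}

#' Grow one synthetic neuron
#'
#' Runs the stochastic branching process of \code{\link{growthParams}} and
#' returns a valid rooted tree with the soma at the origin. The same seed
#' always yields the same tree.
#'
#' @param params a \code{\link{growthParams}}.
#' @param seed integer seed; \code{NULL} uses the current RNG state.
#' @param meta a \code{\linkS4class{SpecimenMeta}} to attach.
#' @return A validated \code{\linkS4class{NeuronTree}}.
#' @export
growNeuron <- function(params, seed = NULL, meta = SpecimenMeta()) {
  stopifnot(inherits(params, "growthParams"))
  if (!is.null(seed)) set.seed(seed)
  shape <- 1 / params$branchLenCv^2
  step <- params$stepUm

  capacity <- 256L
  xs <- numeric(capacity); ys <- numeric(capacity); zs <- numeric(capacity)
  parents <- integer(capacity)
  xs[1L] <- 0; ys[1L] <- 0; zs[1L] <- 0; parents[1L] <- NA_integer_
  nNode <- 1L

  queue <- vector("list", 64L)
  qn <- 0L
  push <- function(item) {
    qn <<- qn + 1L
    if (qn > length(queue)) length(queue) <<- 2L * qn
    queue[[qn]] <<- item
  }
  for (s in seq_len(params$nStems))
    push(list(pos = c(0, 0, 0), dir = .randomUnit(), order = 1L,
              parent = 1L))

  while (qn > 0L) {
    br <- queue[[qn]]; qn <- qn - 1L
    len <- stats::rgamma(1, shape = shape,
                         rate = shape / params$meanBranchLenUm)
    len <- max(len, step / 2)
    dists <- seq_len(floor(len / step)) * step
    if (!length(dists) || dists[length(dists)] < len - 1e-9)
      dists <- c(dists, len)
    k <- length(dists)
    while (nNode + k > capacity) {
      capacity <- capacity * 2L
      length(xs) <- capacity; length(ys) <- capacity
      length(zs) <- capacity; length(parents) <- capacity
    }
    idx <- nNode + seq_len(k)
    xs[idx] <- br$pos[1L] + dists * br$dir[1L]
    ys[idx] <- br$pos[2L] + dists * br$dir[2L]
    zs[idx] <- br$pos[3L] + dists * br$dir[3L]
    parents[idx] <- c(br$parent, idx[-k])
    nNode <- nNode + k
    if (br$order < params$maxOrder &&
        stats::runif(1) < params$branchProb) {
      endPos <- c(xs[idx[k]], ys[idx[k]], zs[idx[k]])
      for (j in 1:2)
        push(list(pos = endPos,
                  dir = .perturbDirection(br$dir, params$angleSpreadDeg),
                  order = br$order + 1L, parent = idx[k]))
    }
  }
  sel <- seq_len(nNode)
  nodes <- data.frame(
    id = sel, parent = parents[sel], x = xs[sel], y = ys[sel], z = zs[sel],
    radius = c(5, rep(0.5, nNode - 1L)),
    kind = c("soma", rep("dendrite", nNode - 1L)),
    stringsAsFactors = FALSE
  )
  NeuronTree(nodes, meta = meta, check = FALSE, mergeDuplicates = FALSE)
}

#' Cohort specification
#'
#' A labelled group of neurons grown from shared parameters, with optional
#' planted effects expressed as multipliers on the baseline mean branch
#' length and bifurcation probability (the two dials that move dendritic
#' length and arbor density, respectively).
#'
#' @param label cohort label (e.g. \code{"AD06"}).
#' @param nNeurons number of neurons, >= 1 (default 60, a typical
#'   per-group neuron count in regional morphometry studies).
#' @param params baseline \code{\link{growthParams}}.
#' @param region brain-region label for the metadata.
#' @param hemisphere,layer metadata labels.
#' @param lengthEffect multiplier (> 0) on \code{meanBranchLenUm}.
#' @param branchProbEffect multiplier (> 0) on \code{branchProb} (capped
#'   at 1).
#' @return list of class \code{"cohortSpec"}.
#' @export
cohortSpec <- function(label, nNeurons = 60L, params = growthParams(),
                       region = "PFC", hemisphere = "L", layer = "L3",
                       lengthEffect = 1, branchProbEffect = 1) {
  stopifnot(nNeurons >= 1, lengthEffect > 0, branchProbEffect > 0)
  eff <- params
  eff$meanBranchLenUm <- params$meanBranchLenUm * lengthEffect
  eff$branchProb <- min(1, params$branchProb * branchProbEffect)
  structure(list(label = label, nNeurons = as.integer(nNeurons),
                 params = eff, region = region, hemisphere = hemisphere,
                 layer = layer, lengthEffect = lengthEffect,
                 branchProbEffect = branchProbEffect),
            class = "cohortSpec")
}

## One master seed -> per-neuron child seeds by counter, so cohorts are
## reproducible regardless of generation order. Kept below 2^31.
.deriveSeed <- function(master, counter) {
  as.integer((as.double(master) * 48271 + as.double(counter) * 16807) %%
               2147483647)
}

#' Generate a synthetic cohort
#'
#' Grows \code{nNeurons} trees under the cohort's parameters, attaching
#' metadata (cohort label, region, hemisphere, layer, running index).
#' Per-neuron seeds are derived deterministically from the master seed by
#' counter.
#'
#' @param spec a \code{\link{cohortSpec}}.
#' @param seed master integer seed.
#' @return list of \code{\linkS4class{NeuronTree}}.
#' @export
generateCohort <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cohortSpec"))
  lapply(seq_len(spec$nNeurons), function(i) {
    meta <- SpecimenMeta(cohort = spec$label, region = spec$region,
                         hemisphere = spec$hemisphere, layer = spec$layer,
                         neuronIndex = i)
    growNeuron(spec$params, seed = .deriveSeed(seed, i), meta = meta)
  })
}

#' Homogeneous Poisson centroid field
#'
#' Simulates soma-centroid positions as a homogeneous Poisson point
#' process over a region extent, the null model against which the
#' stereological density estimator is calibrated.
#'
#' @param extent a \code{\link{regionExtent}}.
#' @param intensityPerUm3 point intensity, per µm³ (>= 0).
#' @param seed integer seed.
#' @return matrix with columns x, y, z (µm); zero rows when the draw is
#'   empty.
#' @export
generateCentroidField <- function(extent, intensityPerUm3, seed = NULL) {
  stopifnot(inherits(extent, "regionExtent"), intensityPerUm3 >= 0)
  if (!is.null(seed)) set.seed(seed)
  vol <- prod(extent$size)
  n <- stats::rpois(1, intensityPerUm3 * vol)
  m <- matrix(stats::runif(3 * n), ncol = 3L)
  m <- sweep(m, 2L, extent$size, `*`)
  m <- sweep(m, 2L, extent$origin, `+`)
  colnames(m) <- c("x", "y", "z")
  m
}

#' Write a cohort to disk as SWC files plus metadata CSV
#'
#' File names follow the configured \code{\link{namingConvention}}; a
#' \code{metadata.csv} companion maps each neuron to its grouping.
#'
#' @param trees list of \code{\linkS4class{NeuronTree}} with metadata.
#' @param dir output directory (created if absent).
#' @param convention a \code{\link{namingConvention}}.
#' @return invisibly, the metadata data.frame.
#' @export
writeCohort <- function(trees, dir, convention = namingConvention()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  metas <- lapply(trees, specimenMeta)
  files <- vapply(metas, formatSpecimenFilename, "",
                  convention = convention)
  for (i in seq_along(trees))
    writeSWC(trees[[i]], file.path(dir, files[i]))
  writeCohortMetadata(metas, files, file.path(dir, "metadata.csv"))
}

#' Read a directory of tracing files as a cohort
#'
#' Metadata comes from \code{metadata.csv} when present, otherwise from
#' the file names via \code{\link{parseSpecimenMetadata}}. Unreadable
#' files are skipped with a per-file message; the skip count is returned
#' as an attribute.
#'
#' @param dir directory of \code{.swc} or \code{.am} files.
#' @param format \code{"swc"} or \code{"amira"}.
#' @param convention a \code{\link{namingConvention}}.
#' @return list of \code{\linkS4class{NeuronTree}}, with attribute
#'   \code{"skipped"} (character vector of per-file failure reasons).
#' @export
readCohort <- function(dir, format = c("swc", "amira"),
                       convention = namingConvention()) {
  format <- match.arg(format)
  ext <- if (format == "swc") "\\.swc$" else "\\.am$"
  metaFile <- file.path(dir, "metadata.csv")
  reader <- if (format == "swc") readSWC else readAmiraSpatialGraph
  if (file.exists(metaFile)) {
    md <- readCohortMetadata(metaFile)
    files <- md$path
    metas <- lapply(seq_len(nrow(md)), function(i)
      SpecimenMeta(cohort = md$cohort[i], region = md$region[i],
                   hemisphere = md$hemisphere[i], layer = md$layer[i],
                   neuronIndex = md$index[i]))
  } else {
    files <- sort(list.files(dir, pattern = ext))
    metas <- NULL
  }
  trees <- list()
  skipped <- character()
  for (i in seq_along(files)) {
    res <- tryCatch({
      meta <- if (is.null(metas))
        parseSpecimenMetadata(files[i], convention) else metas[[i]]
      reader(file.path(dir, files[i]), meta = meta)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      msg <- sprintf("%s: %s", files[i], conditionMessage(res))
      message("skipping ", msg)
      skipped <- c(skipped, msg)
    } else {
      trees[[length(trees) + 1L]] <- res
    }
  }
  attr(trees, "skipped") <- skipped
  trees
}
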