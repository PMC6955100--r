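#' Crossings of a line segment with a sphere
#'
#' Counts the transversal crossings of the sphere of radius \code{r}
#' centred at \code{center} by the segment from \code{a} to \code{b}.
#' Counting classifies the endpoints (a point is inside iff its distance
#' to the centre is at most \code{r}; a point exactly on the sphere
#' classifies as inside): one endpoint inside and one outside is one
#' crossing; both outside is two crossings iff the closest approach falls
#' strictly inside the sphere at an interior parameter (the chord case,
#' from the quadratic \eqn{|a + t(b-a) - c|^2 = r^2}); both inside is
#' none. Because a node shared by two consecutive segments classifies
#' identically in both, a crossing exactly at a node is attributed to
#' exactly one adjoining segment and never double-counted — equivalent to
#' counting quadratic roots on a half-open parameter interval, but robust
#' to roundoff when a node lies exactly on a shell; a dendrite that only
#' reaches a shell at its tip does not cross it. A tangential touch
#' (closest approach exactly \code{r}) counts 0 by default: it is a
#' measure-zero event and the convention matches a sign-change count
#' along the path.
#'
#' @param a,b numeric xyz endpoints of the segment (µm).
#' @param center numeric xyz of the sphere centre (µm).
#' @param r sphere radius, > 0 (µm).
#' @param tangencyCounts logical; count a tangential touch as one crossing.
#' @return integer in \code{0:2}.
#' @examples
#' segmentSphereCrossings(c(0, 0, 0), c(100, 0, 0), c(0, 0, 0), 30)   # 1
#' segmentSphereCrossings(c(25, -20, 0), c(25, 20, 0), c(0, 0, 0), 30) # 2
#' @export
segmentSphereCrossings <- function(a, b, center, r, tangencyCounts = FALSE) {
  stopifnot(length(a) == 3L, length(b) == 3L, length(center) == 3L, r > 0)
  d <- b - a
  if (all(d == 0)) {
    warning("degenerate segment (a == b): 0 crossings", call. = FALSE)
    return(0L)
  }
  p <- a - center
  q <- b - center
  r2 <- r * r
  aIn <- sum(p * p) <= r2
  bIn <- sum(q * q) <= r2
  if (aIn != bIn) return(1L)
  if (aIn) return(0L)
  ## both endpoints outside: chord iff the interior closest approach dips
  ## strictly inside the sphere
  A <- sum(d * d)
  B <- 2 * sum(p * d)
  tmin <- -B / (2 * A)
  if (tmin <= 0 || tmin >= 1) return(0L)
  dmin2 <- sum((p + tmin * d)^2)
  if (dmin2 < r2) return(2L)
  if (dmin2 == r2 && tangencyCounts) return(1L)
  0L
}

#' 3D Sholl intersection profile
#'
#' Counts, for each concentric sphere of radius \eqn{k \cdot \Delta r}
#' centred at the soma, the exact number of transversal crossings by the
#' dendritic segments of the tree. Spheres (not planar circles) are used
#' because the reconstructions are three-dimensional. The crossing count
#' per segment is the number of real roots of the quadratic
#' \eqn{|a + t(b-a) - c|^2 = r^2} on \eqn{t \in [0, 1)}, summed over all
#' segments.
#'
#' @param x a valid \code{\linkS4class{NeuronTree}}.
#' @param stepUm shell spacing \eqn{\Delta r} in µm (default 30, the
#'   conventional spacing for pyramidal-neuron profiles).
#' @param maxRadiusUm outermost shell radius; default: the smallest
#'   multiple of \code{stepUm} at or beyond the most distant node, so the
#'   profile always ends in the shell just past the arbor.
#' @param tangencyCounts see \code{\link{segmentSphereCrossings}}.
#' @return A \code{\linkS4class{ShollProfile}}.
#' @aliases shollProfile
#' @export
setMethod("shollProfile", "NeuronTree",
          function(x, stepUm = 30, maxRadiusUm = NULL,
                   tangencyCounts = FALSE, ...) {
  stopifnot(stepUm > 0)
  .assertValidTree(x)
  center <- somaPosition(x)
  nodes <- x@nodes
  maxDist <- max(sqrt((nodes$x - center[1L])^2 + (nodes$y - center[2L])^2 +
                        (nodes$z - center[3L])^2))
  if (is.null(maxRadiusUm))
    maxRadiusUm <- stepUm * max(1, ceiling(maxDist / stepUm))
  stopifnot(maxRadiusUm >= stepUm)
  radii <- seq(stepUm, maxRadiusUm, by = stepUm)

  seg <- extractSegments(x)
  counts <- integer(length(radii))
  if (nrow(seg)) {
    px <- seg$ax - center[1L]; py <- seg$ay - center[2L]
    pz <- seg$az - center[3L]
    dx <- seg$bx - seg$ax; dy <- seg$by - seg$ay; dz <- seg$bz - seg$az
    A <- dx^2 + dy^2 + dz^2
    B <- 2 * (px * dx + py * dy + pz * dz)
    P2 <- px^2 + py^2 + pz^2
    Q2 <- (px + dx)^2 + (py + dy)^2 + (pz + dz)^2
    tmin <- -B / (2 * A)
    interior <- tmin > 0 & tmin < 1
    dmin2 <- ifelse(interior,
                    (px + tmin * dx)^2 + (py + tmin * dy)^2 +
                      (pz + tmin * dz)^2, Inf)
    for (i in seq_along(radii)) {
      r2 <- radii[i]^2
      aIn <- P2 <= r2
      bIn <- Q2 <= r2
      n <- as.integer(aIn != bIn) +
        2L * as.integer(!aIn & !bIn & dmin2 < r2)
      if (tangencyCounts)
        n <- n + as.integer(!aIn & !bIn & dmin2 == r2)
      counts[i] <- sum(n)
    }
  }
  new("ShollProfile", radii = radii, intersections = as.integer(counts),
      stepUm = as.numeric(stepUm), meta = x@meta)
})

#' Accessors for ShollProfile
#'
#' @param x a \code{\linkS4class{ShollProfile}}.
#' @return \code{shellRadii}: the shell radii (µm);
#'   \code{intersectionCounts}: the crossing counts.
#' @name shollProfile-accessors
#' @aliases shellRadii intersectionCounts
NULL

#' @rdname shollProfile-accessors
#' @export
setMethod("shellRadii", "ShollProfile", function(x) x@radii)

#' @rdname shollProfile-accessors
#' @export
setMethod("intersectionCounts", "ShollProfile", function(x) x@intersections)

#' Sum a Sholl profile over a radius range
#'
#' Adds up the intersection counts of all shells with
#' \code{lo <= radius <= hi}. Bounds not aligned to the shell spacing are
#' snapped outward (lo down, hi up) with a warning.
#'
#' @param profile a \code{\linkS4class{ShollProfile}}.
#' @param loUm,hiUm range bounds in µm, \code{loUm <= hiUm}.
#' @return integer(1), summed crossings over the range.
#' @export
aggregateRange <- function(profile, loUm, hiUm) {
  stopifnot(is(profile, "ShollProfile"), loUm <= hiUm)
  step <- profile@stepUm
  lo <- floor(loUm / step) * step
  hi <- ceiling(hiUm / step) * step
  if (lo != loUm || hi != hiUm)
    warning(sprintf("range [%g, %g] snapped outward to [%g, %g] (step %g)",
                    loUm, hiUm, lo, hi, step), call. = FALSE)
  sel <- profile@radii >= lo & profile@radii <= hi
  if (!any(sel)) {
    warning("empty radius range: 0 crossings", call. = FALSE)
    return(0L)
  }
  as.integer(sum(profile@intersections[sel]))
}

#' Align Sholl profiles onto a common shell grid
#'
#' Pads shorter profiles with zero counts up to the longest profile's
#' outermost shell so cohorts can be compared shell by shell. All profiles
#' must share the same shell spacing.
#'
#' @param profiles list of \code{\linkS4class{ShollProfile}}.
#' @return list with \code{radii} (common grid) and \code{counts} (matrix,
#'   one row per profile).
#' @export
alignShollProfiles <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  steps <- vapply(profiles, function(p) p@stepUm, 1.0)
  if (length(unique(steps)) != 1L)
    stop("profiles have differing shell spacing: ",
         paste(unique(steps), collapse = ", "))
  step <- steps[1L]
  nShell <- max(vapply(profiles, function(p) length(p@radii), 1L))
  radii <- seq(step, step * nShell, by = step)
  counts <- do.call(rbind, lapply(profiles, function(p) {
    c(p@intersections, rep(0L, nShell - length(p@intersections)))
  }))
  list(radii = radii, counts = counts)
}

#' Long-format Sholl table for a cohort
#'
#' @param profiles list of \code{\linkS4class{ShollProfile}}.
#' @return data.frame with columns \code{cohort}, \code{region},
#'   \code{neuron_index}, \code{radius_um}, \code{intersections}.
#' @export
shollTable <- function(profiles) {
  do.call(rbind, lapply(profiles, function(p) {
    data.frame(cohort = p@meta@cohort, region = p@meta@region,
               neuron_index = p@meta@neuronIndex,
               radius_um = p@radii, intersections = p@intersections,
               stringsAsFactors = FALSE)
  }))
}
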