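#' Total dendritic length
#'
#' The sum of the Euclidean lengths of all dendritic branches, i.e. of all
#' parent-to-child segments of the tree, in micrometres. A soma-only tree
#' has length 0.
#'
#' @param x a valid \code{\linkS4class{NeuronTree}}.
#' @return numeric(1), total length in µm.
#' @aliases totalDendriticLength
#' @export
setMethod("totalDendriticLength", "NeuronTree", function(x, ...) {
  .assertValidTree(x)
  nodes <- x@nodes
  pidx <- match(nodes$parent, nodes$id)
  ok <- !is.na(pidx)
  sum(sqrt((nodes$x[ok] - nodes$x[pidx[ok]])^2 +
             (nodes$y[ok] - nodes$y[pidx[ok]])^2 +
             (nodes$z[ok] - nodes$z[pidx[ok]])^2))
})

#' Terminal-dendrite count
#'
#' The number of branches of the last stage, counted as the number of leaf
#' nodes (nodes with no children). The soma is excluded even when it is
#' childless: a soma-only tree has 0 terminals (with a warning, since a
#' traced neuron is expected to carry dendrites).
#'
#' @param x a valid \code{\linkS4class{NeuronTree}}.
#' @return integer(1), terminal count.
#' @aliases terminalCount
#' @export
setMethod("terminalCount", "NeuronTree", function(x, ...) {
  .assertValidTree(x)
  nodes <- x@nodes
  if (nrow(nodes) == 1L) {
    warning("soma-only tree: terminal count is 0", call. = FALSE)
    return(0L)
  }
  isLeaf <- !(nodes$id %in% nodes$parent)
  sum(isLeaf & nodes$id != x@somaId)
})

#' Spatial volume of a neuron
#'
#' The smallest cubic volume that accommodates the entire neuron. Two
#' readings of "cubic volume" are supported and the mode is always
#' reported alongside any number derived from it:
#' \describe{
#'   \item{\code{"box"} (default)}{volume of the axis-aligned bounding box
#'     of all node positions, \eqn{\Delta x \cdot \Delta y \cdot \Delta z}.}
#'   \item{\code{"cube"}}{the literal cube: the largest coordinate extent,
#'     cubed.}
#' }
#' The soma position participates in the extent. Degenerate (coplanar or
#' collinear) trees have volume 0 in box mode.
#'
#' @param x a valid \code{\linkS4class{NeuronTree}}.
#' @param mode \code{"box"} or \code{"cube"}.
#' @return numeric(1), volume in µm³.
#' @aliases spatialVolume
#' @export
setMethod("spatialVolume", "NeuronTree", function(x, mode = c("box", "cube"),
                                                  ...) {
  mode <- match.arg(mode)
  .assertValidTree(x)
  nodes <- x@nodes
  ext <- c(diff(range(nodes$x)), diff(range(nodes$y)), diff(range(nodes$z)))
  switch(mode, box = prod(ext), cube = max(ext)^3)
})

#' Per-neuron morphometry summary
#'
#' Computes the three scalar complexity indicators of one neuron — total
#' dendritic length L (µm), terminal-dendrite count T, and spatial volume
#' V (µm³) — together with the node count and the attached specimen
#' metadata.
#'
#' @param x a valid \code{\linkS4class{NeuronTree}}.
#' @param volumeMode volume reading passed to \code{\link{spatialVolume}}.
#' @return A one-row data.frame with columns \code{cohort}, \code{region},
#'   \code{hemisphere}, \code{neuron_index}, \code{length_um},
#'   \code{terminal_count}, \code{spatial_volume_um3}, \code{node_count},
#'   \code{volume_mode}.
#' @aliases summarizeMorphometry
#' @export
setMethod("summarizeMorphometry", "NeuronTree",
          function(x, volumeMode = c("box", "cube"), ...) {
  volumeMode <- match.arg(volumeMode)
  .assertValidTree(x)
  m <- x@meta
  tc <- if (nrow(x@nodes) == 1L) {
    warning("soma-only tree: terminal count is 0", call. = FALSE)
    0L
  } else suppressWarnings(terminalCount(x))
  data.frame(
    cohort = m@cohort, region = m@region, hemisphere = m@hemisphere,
    neuron_index = m@neuronIndex,
    length_um = totalDendriticLength(x),
    terminal_count = tc,
    spatial_volume_um3 = spatialVolume(x, mode = volumeMode),
    node_count = nrow(x@nodes),
    volume_mode = volumeMode,
    stringsAsFactors = FALSE
  )
})

#' Morphometry table for a cohort of neurons
#'
#' @param trees list of \code{\linkS4class{NeuronTree}}.
#' @param volumeMode volume reading passed to \code{\link{spatialVolume}}.
#' @return data.frame with one row per neuron (see
#'   \code{\link{summarizeMorphometry}}).
#' @export
morphometryTable <- function(trees, volumeMode = c("box", "cube")) {
  volumeMode <- match.arg(volumeMode)
  do.call(rbind, lapply(trees, summarizeMorphometry, volumeMode = volumeMode))
}
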