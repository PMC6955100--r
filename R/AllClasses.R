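#' @import methods
NULL

#' Specimen metadata for a traced neuron
#'
#' Carries the grouping information attached to one reconstruction: cohort
#' (e.g. an age group such as \code{"AD06"} / \code{"AD12"}, or \code{"WT"}),
#' brain region (\code{"PFC"}, \code{"PMC"}, \code{"EC"}, \code{"CA1"}),
#' hemisphere, cortical layer label and a running neuron index.
#'
#' @slot cohort character(1), cohort label (NA when unknown).
#' @slot region character(1), brain-region abbreviation.
#' @slot hemisphere character(1), one of \code{"L"}, \code{"R"},
#'   \code{"unknown"}.
#' @slot layer character(1), free-form layer label.
#' @slot neuronIndex integer(1), running index of the neuron.
#' @export
setClass("SpecimenMeta",
  representation(
    cohort = "character",
    region = "character",
    hemisphere = "character",
    layer = "character",
    neuronIndex = "integer"
  ),
  prototype(
    cohort = NA_character_,
    region = NA_character_,
    hemisphere = "unknown",
    layer = NA_character_,
    neuronIndex = NA_integer_
  )
)

setValidity("SpecimenMeta", function(object) {
  msg <- character()
  for (sl in c("cohort", "region", "hemisphere", "layer")) {
    if (length(slot(object, sl)) != 1L)
      msg <- c(msg, sprintf("slot '%s' must have length 1", sl))
  }
  if (length(object@neuronIndex) != 1L)
    msg <- c(msg, "slot 'neuronIndex' must have length 1")
  hemi <- object@hemisphere
  if (!is.na(hemi) && !hemi %in% c("L", "R", "unknown"))
    msg <- c(msg, "hemisphere must be 'L', 'R' or 'unknown'")
  if (length(msg)) msg else TRUE
})

#' Rooted tree of 3D points representing a traced neuron
#'
#' The substrate of every metric in the package: a soma root node plus
#' dendrite nodes connected by parent links, with positions in micrometres.
#' The node table has columns \code{id}, \code{parent} (NA for the root),
#' \code{x}, \code{y}, \code{z}, \code{radius}, \code{kind} (one of
#' \code{"soma"}, \code{"dendrite"}, \code{"undefined"}).
#'
#' Class validity only enforces the table shape; full structural validation
#' (single root, acyclicity, connectivity) is a diagnostic operation, see
#' \code{\link{validateNeuronTree}}, so that malformed inputs can be
#' inspected rather than merely rejected.
#'
#' @slot nodes data.frame of nodes, one row per tracing point.
#' @slot somaId integer(1), the node id of the root (soma centroid).
#' @slot meta a \code{\linkS4class{SpecimenMeta}}.
#' @export
setClass("NeuronTree",
  representation(
    nodes = "data.frame",
    somaId = "integer",
    meta = "SpecimenMeta"
  )
)

.NODE_COLS <- c("id", "parent", "x", "y", "z", "radius", "kind")

setValidity("NeuronTree", function(object) {
  msg <- character()
  missing <- setdiff(.NODE_COLS, names(object@nodes))
  if (length(missing))
    msg <- c(msg, paste("node table lacks columns:",
                        paste(missing, collapse = ", ")))
  if (length(object@somaId) != 1L)
    msg <- c(msg, "somaId must have length 1")
  if (length(msg)) msg else TRUE
})

#' Sholl intersection profile of one neuron
#'
#' Counts of transversal dendrite crossings of concentric spheres centred at
#' the soma, one count per shell radius.
#'
#' @slot radii numeric, ordered shell radii in micrometres.
#' @slot intersections integer, crossing count per shell.
#' @slot stepUm numeric(1), shell spacing in micrometres.
#' @slot meta a \code{\linkS4class{SpecimenMeta}}.
#' @export
setClass("ShollProfile",
  representation(
    radii = "numeric",
    intersections = "integer",
    stepUm = "numeric",
    meta = "SpecimenMeta"
  )
)

setValidity("ShollProfile", function(object) {
  msg <- character()
  if (length(object@radii) != length(object@intersections))
    msg <- c(msg, "radii and intersections must have equal length")
  if (any(object@intersections < 0L))
    msg <- c(msg, "intersection counts must be non-negative")
  if (length(object@stepUm) != 1L || object@stepUm <= 0)
    msg <- c(msg, "stepUm must be a single positive number")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SpecimenMeta", function(object) {
  cat(sprintf("SpecimenMeta: cohort=%s region=%s hemisphere=%s layer=%s index=%s\n",
              object@cohort, object@region, object@hemisphere,
              object@layer, object@neuronIndex))
})

setMethod("show", "NeuronTree", function(object) {
  nd <- nrow(object@nodes)
  cat(sprintf("NeuronTree with %d node%s (soma id %d)\n",
              nd, if (nd == 1L) "" else "s", object@somaId))
  if (!is.na(object@meta@cohort) || !is.na(object@meta@region))
    show(object@meta)
})

setMethod("show", "ShollProfile", function(object) {
  cat(sprintf("ShollProfile: %d shells, step %g um, total crossings %d\n",
              length(object@radii), object@stepUm,
              sum(object@intersections)))
})
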