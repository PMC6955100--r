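#' Construct a NeuronTree
#'
#' Builds the rooted-tree container from a node table. Duplicate tracing
#' points (a child coinciding exactly with its parent position) are merged
#' into the parent with a warning, since they carry no geometric
#' information; downstream metrics are unaffected by the merge.
#'
#' @param nodes data.frame with columns \code{id}, \code{parent} (NA or
#'   negative for the root), \code{x}, \code{y}, \code{z} (micrometres),
#'   and optionally \code{radius} (micrometres, default 1) and \code{kind}
#'   (default: root is \code{"soma"}, everything else \code{"dendrite"}).
#' @param meta a \code{\linkS4class{SpecimenMeta}} (optional).
#' @param check logical; validate the structure and stop on violations
#'   (default TRUE). With \code{check = FALSE} a structurally invalid tree
#'   can be built for inspection with \code{\link{validateNeuronTree}}.
#' @param mergeDuplicates logical; merge zero-length parent/child pairs
#'   (default TRUE).
#' @return A \code{\linkS4class{NeuronTree}}.
#' @examples
#' nt <- NeuronTree(data.frame(id = 1:2, parent = c(NA, 1),
#'                             x = c(0, 3), y = c(0, 4), z = c(0, 0)))
#' totalDendriticLength(nt)
#' @export
NeuronTree <- function(nodes, meta = SpecimenMeta(), check = TRUE,
                       mergeDuplicates = TRUE) {
  stopifnot(is.data.frame(nodes), nrow(nodes) >= 1L)
  nodes$id <- as.integer(nodes$id)
  nodes$parent <- suppressWarnings(as.integer(nodes$parent))
  nodes$parent[!is.na(nodes$parent) & nodes$parent < 0L] <- NA_integer_
  for (cc in c("x", "y", "z")) nodes[[cc]] <- as.numeric(nodes[[cc]])
  if (is.null(nodes$radius)) nodes$radius <- 1.0
  nodes$radius <- as.numeric(nodes$radius)
  if (is.null(nodes$kind))
    nodes$kind <- ifelse(is.na(nodes$parent), "soma", "dendrite")
  nodes$kind <- as.character(nodes$kind)
  nodes <- nodes[, .NODE_COLS]
  rownames(nodes) <- NULL

  rootRows <- which(is.na(nodes$parent))
  sid <- if (length(rootRows) == 1L) nodes$id[rootRows] else NA_integer_

  if (mergeDuplicates && !anyNA(sid)) {
    nodes <- .mergeZeroLengthPairs(nodes)
  }
  obj <- new("NeuronTree", nodes = nodes, somaId = as.integer(sid)[1L],
             meta = meta)
  if (check) {
    viol <- validateNeuronTree(obj)
    if (length(viol))
      stop("invalid NeuronTree: ", paste(viol, collapse = "; "))
  }
  obj
}

## Contract zero-length parent->child edges: the child node is removed and
## its children re-parented, preserving all metrics.
.mergeZeroLengthPairs <- function(nodes) {
  repeat {
    idx <- match(nodes$parent, nodes$id)
    idx[!is.na(idx) & idx == seq_len(nrow(nodes))] <- NA  # self-loops: not ours to fix
    dup <- which(!is.na(idx) &
                   nodes$x == nodes$x[idx] &
                   nodes$y == nodes$y[idx] &
                   nodes$z == nodes$z[idx])
    if (!length(dup)) return(nodes)
    d <- dup[1L]
    warning(sprintf(
      "merging duplicate tracing point: node %d coincides with its parent %d",
      nodes$id[d], nodes$parent[d]), call. = FALSE)
    nodes$parent[!is.na(nodes$parent) & nodes$parent == nodes$id[d]] <-
      nodes$parent[d]
    nodes <- nodes[-d, , drop = FALSE]
  }
}

#' Construct specimen metadata
#'
#' @param cohort,region,hemisphere,layer character(1) labels; NA when
#'   unknown.
#' @param neuronIndex integer(1) running neuron index.
#' @return A \code{\linkS4class{SpecimenMeta}}.
#' @export
SpecimenMeta <- function(cohort = NA_character_, region = NA_character_,
                         hemisphere = "unknown", layer = NA_character_,
                         neuronIndex = NA_integer_) {
  new("SpecimenMeta",
      cohort = as.character(cohort), region = as.character(region),
      hemisphere = as.character(hemisphere), layer = as.character(layer),
      neuronIndex = as.integer(neuronIndex))
}

#' Structural validation of a neuron tree
#'
#' Diagnostic check of the rooted-tree invariants: unique node ids, exactly
#' one root, the root is the soma, every parent reference resolves, no
#' cycles, and every node is reachable from the soma. Never raises on bad
#' structure; returns a description of each violation instead.
#'
#' @param tree a \code{\linkS4class{NeuronTree}} (possibly built with
#'   \code{check = FALSE}).
#' @return character vector of violation descriptions; empty iff the tree
#'   is valid. Each message names the offending node id(s) and the rule
#'   broken.
#' @examples
#' bad <- NeuronTree(data.frame(id = 1:2, parent = c(NA, 2),
#'                              x = 0:1, y = 0, z = 0), check = FALSE)
#' validateNeuronTree(bad)
#' @export
validateNeuronTree <- function(tree) {
  stopifnot(is(tree, "NeuronTree"))
  nodes <- tree@nodes
  out <- character()
  if (nrow(nodes) < 1L) return("tree has no nodes")

  dupIds <- unique(nodes$id[duplicated(nodes$id)])
  if (length(dupIds))
    out <- c(out, sprintf("duplicate node id(s): %s",
                          paste(dupIds, collapse = ", ")))

  rootRows <- which(is.na(nodes$parent))
  if (length(rootRows) == 0L) {
    out <- c(out, "no root: every node has a parent")
  } else if (length(rootRows) > 1L) {
    out <- c(out, sprintf("multiple roots: nodes %s all lack a parent",
                          paste(nodes$id[rootRows], collapse = ", ")))
  } else {
    rid <- nodes$id[rootRows]
    if (!identical(as.integer(rid), tree@somaId))
      out <- c(out, sprintf("somaId (%d) is not the root node (%d)",
                            tree@somaId, rid))
    if (nodes$kind[rootRows] != "soma")
      out <- c(out, sprintf("root node %d has kind '%s', expected 'soma'",
                            rid, nodes$kind[rootRows]))
  }

  selfLoop <- which(!is.na(nodes$parent) & nodes$parent == nodes$id)
  if (length(selfLoop))
    out <- c(out, sprintf("cycle: node(s) %s are their own parent",
                          paste(nodes$id[selfLoop], collapse = ", ")))

  dangling <- which(!is.na(nodes$parent) & !(nodes$parent %in% nodes$id))
  if (length(dangling))
    out <- c(out, sprintf("dangling parent reference(s): node(s) %s point to absent id(s) %s",
                          paste(nodes$id[dangling], collapse = ", "),
                          paste(unique(nodes$parent[dangling]), collapse = ", ")))

  badKind <- which(!nodes$kind %in% c("soma", "dendrite", "undefined"))
  if (length(badKind))
    out <- c(out, sprintf("unknown kind for node(s) %s",
                          paste(nodes$id[badKind], collapse = ", ")))

  ## Reachability from the root detects both disconnection and cycles not
  ## caught by the self-loop check.
  if (length(rootRows) == 1L && !length(dupIds) && !length(dangling)) {
    reach <- .reachableFromRoot(nodes, nodes$id[rootRows])
    unreached <- setdiff(nodes$id, reach)
    if (length(unreached))
      out <- c(out, sprintf("node(s) %s unreachable from soma (disconnected or in a cycle)",
                            paste(unreached, collapse = ", ")))
  }
  out
}

## Wave-by-wave reachability; the returned order is breadth-first, so
## parents always precede their children.
.reachableFromRoot <- function(nodes, rootId) {
  pidx <- match(nodes$parent, nodes$id)
  reached <- nodes$id == rootId
  out <- nodes$id[reached]
  repeat {
    newly <- !reached & !is.na(pidx) & reached[pidx]
    if (!any(newly)) break
    reached[newly] <- TRUE
    out <- c(out, nodes$id[newly])
  }
  out
}

.assertValidTree <- function(tree) {
  viol <- validateNeuronTree(tree)
  if (length(viol))
    stop("invalid NeuronTree: ", paste(viol, collapse = "; "), call. = FALSE)
  invisible(tree)
}

#' Extract parent-to-child segments
#'
#' Decomposes a valid tree into straight segments, one per parent/child node
#' pair; these are the units over which dendritic length is summed and
#' sphere crossings are counted. Zero-length pairs have already been merged
#' at construction, so the segment count equals node count minus one.
#'
#' @param x a valid \code{\linkS4class{NeuronTree}}.
#' @return data.frame with one row per segment: \code{ax,ay,az} (parent
#'   position), \code{bx,by,bz} (child position), \code{length} (µm),
#'   \code{childId}, and \code{childIsTerminal} (TRUE iff the child has no
#'   children).
#' @export
#' @aliases extractSegments
setMethod("extractSegments", "NeuronTree", function(x, ...) {
  .assertValidTree(x)
  nodes <- x@nodes
  child <- which(!is.na(nodes$parent))
  if (!length(child)) {
    return(data.frame(ax = numeric(), ay = numeric(), az = numeric(),
                      bx = numeric(), by = numeric(), bz = numeric(),
                      length = numeric(), childId = integer(),
                      childIsTerminal = logical()))
  }
  pidx <- match(nodes$parent[child], nodes$id)
  ax <- nodes$x[pidx]; ay <- nodes$y[pidx]; az <- nodes$z[pidx]
  bx <- nodes$x[child]; by <- nodes$y[child]; bz <- nodes$z[child]
  childId <- nodes$id[child]
  structure(list(
    ax = ax, ay = ay, az = az, bx = bx, by = by, bz = bz,
    length = sqrt((bx - ax)^2 + (by - ay)^2 + (bz - az)^2),
    childId = childId,
    childIsTerminal = !(childId %in% nodes$parent)
  ), class = "data.frame", row.names = c(NA_integer_, -length(child)))
})

#' Accessors for NeuronTree
#'
#' @param x a \code{\linkS4class{NeuronTree}}.
#' @param value a \code{\linkS4class{SpecimenMeta}} (for the replacement
#'   method).
#' @return \code{nodeTable}: the node data.frame; \code{somaId}: the root
#'   id; \code{somaPosition}: numeric xyz of the soma; \code{nNodes}: node
#'   count; \code{specimenMeta}: the attached metadata.
#' @name neuronTree-accessors
#' @aliases nodeTable somaId somaPosition nNodes specimenMeta specimenMeta<-
NULL

#' @rdname neuronTree-accessors
#' @export
setMethod("nodeTable", "NeuronTree", function(x) x@nodes)

#' @rdname neuronTree-accessors
#' @export
setMethod("somaId", "NeuronTree", function(x) x@somaId)

#' @rdname neuronTree-accessors
#' @export
setMethod("somaPosition", "NeuronTree", function(x) {
  i <- match(x@somaId, x@nodes$id)
  c(x = x@nodes$x[i], y = x@nodes$y[i], z = x@nodes$z[i])
})

#' @rdname neuronTree-accessors
#' @export
setMethod("nNodes", "NeuronTree", function(x) nrow(x@nodes))

#' @rdname neuronTree-accessors
#' @export
setMethod("specimenMeta", "NeuronTree", function(x) x@meta)

#' @rdname neuronTree-accessors
#' @export
setReplaceMethod("specimenMeta", "NeuronTree", function(x, value) {
  stopifnot(is(value, "SpecimenMeta"))
  x@meta <- value
  x
})
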