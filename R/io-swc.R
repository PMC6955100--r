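#' Read an SWC morphology file
#'
#' Parses the standard 7-column SWC format (id, type, x, y, z, radius,
#' parent; '#' comments) into a \code{\linkS4class{NeuronTree}}. SWC type
#' code 1 maps to kind \code{"soma"}, all other codes to \code{"dendrite"}
#' (the metrics here are skeleton-based and do not distinguish neurite
#' types further). Multi-point soma contours are collapsed to their
#' centroid, which becomes the single root node.
#'
#' @param file path to an SWC file, or a character vector of SWC lines
#'   (via \code{text}).
#' @param text optional character vector of lines, used instead of
#'   \code{file}.
#' @param meta a \code{\linkS4class{SpecimenMeta}} to attach.
#' @return A validated \code{\linkS4class{NeuronTree}}.
#' @seealso \code{\link{writeSWC}}
#' @export
readSWC <- function(file, text = NULL, meta = SpecimenMeta()) {
  lines <- if (!is.null(text)) text else readLines(file, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  keep <- grepl("\\S", lines)
  lineNo <- which(keep)
  lines <- trimws(lines[keep])
  if (!length(lines)) stop("SWC parse error: no records found")

  fields <- strsplit(lines, "\\s+")
  nf <- lengths(fields)
  bad <- which(nf != 7L)
  if (length(bad))
    stop(sprintf("SWC parse error at line %d: expected 7 fields, found %d",
                 lineNo[bad[1L]], nf[bad[1L]]))
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))),
              ncol = 7L, byrow = TRUE)
  nonNum <- which(apply(is.na(m), 1L, any))
  if (length(nonNum))
    stop(sprintf("SWC parse error at line %d: non-numeric field",
                 lineNo[nonNum[1L]]))

  rec <- data.frame(id = as.integer(m[, 1L]), type = as.integer(m[, 2L]),
                    x = m[, 3L], y = m[, 4L], z = m[, 5L],
                    radius = m[, 6L], parent = as.integer(m[, 7L]))
  if (any(rec$id <= 0L))
    stop("SWC parse error: node ids must be positive")
  if (anyDuplicated(rec$id))
    stop("SWC structural error: duplicate node id ",
         rec$id[duplicated(rec$id)][1L])

  roots <- which(rec$parent == -1L)
  if (length(roots) == 0L)
    stop("SWC structural error: no root record (parent -1)")
  if (length(roots) > 1L && !all(rec$type[roots] == 1L))
    stop("SWC structural error: multiple roots (ids ",
         paste(rec$id[roots], collapse = ", "), ")")

  missingParent <- !(rec$parent %in% c(-1L, rec$id))
  if (any(missingParent))
    stop("SWC structural error: node ", rec$id[which(missingParent)[1L]],
         " references absent parent ", rec$parent[which(missingParent)[1L]])

  rec <- .collapseSomaContour(rec)

  nodes <- data.frame(
    id = rec$id,
    parent = ifelse(rec$parent == -1L, NA_integer_, rec$parent),
    x = rec$x, y = rec$y, z = rec$z, radius = rec$radius,
    kind = ifelse(rec$type == 1L, "soma", "dendrite"),
    stringsAsFactors = FALSE
  )
  ## Non-root rows typed soma (contour remnants) become the root itself
  ## after collapsing; any leftover soma-typed child is treated as dendrite.
  isRoot <- is.na(nodes$parent)
  nodes$kind[!isRoot & nodes$kind == "soma"] <- "dendrite"
  nodes$kind[isRoot] <- "soma"
  NeuronTree(nodes, meta = meta)
}

## Multi-point soma (several type-1 records forming a contour around the
## root) is replaced by a single node at the contour centroid.
.collapseSomaContour <- function(rec) {
  soma <- which(rec$type == 1L)
  if (length(soma) <= 1L) return(rec)
  rootRow <- which(rec$parent == -1L)[1L]
  ## soma points: the root plus any type-1 node whose parent is a soma node
  somaIds <- rec$id[rootRow]
  repeat {
    more <- rec$id[rec$type == 1L & rec$parent %in% somaIds &
                     !(rec$id %in% somaIds)]
    if (!length(more)) break
    somaIds <- c(somaIds, more)
  }
  if (length(somaIds) <= 1L) return(rec)
  inSoma <- rec$id %in% somaIds
  cen <- c(mean(rec$x[inSoma]), mean(rec$y[inSoma]), mean(rec$z[inSoma]))
  rootId <- rec$id[rootRow]
  rec$x[rootRow] <- cen[1L]; rec$y[rootRow] <- cen[2L]
  rec$z[rootRow] <- cen[3L]
  rec$radius[rootRow] <- max(rec$radius[inSoma])
  ## re-parent children of removed contour points onto the root
  rec$parent[rec$parent %in% setdiff(somaIds, rootId)] <- rootId
  rec <- rec[!(inSoma & rec$id != rootId), , drop = FALSE]
  rec
}

#' Write a neuron tree as SWC
#'
#' Records are written topologically ordered (every parent before its
#' children) so the file is re-readable by any conforming SWC reader. Node
#' ids are relabelled 1..N in that order. Kind \code{"soma"} is written as
#' type 1, \code{"dendrite"} as type 3, \code{"undefined"} as type 0; an
#' unset radius is written as 1.0.
#'
#' @param tree a valid \code{\linkS4class{NeuronTree}}.
#' @param file path to write to, or \code{NULL} to return the lines.
#' @return Invisibly, the character vector of SWC lines.
#' @export
writeSWC <- function(tree, file = NULL) {
  .assertValidTree(tree)
  nodes <- tree@nodes
  order <- .reachableFromRoot(nodes, tree@somaId)
  idx <- match(order, nodes$id)
  newId <- seq_along(order)
  names(newId) <- as.character(order)
  parent <- nodes$parent[idx]
  parentOut <- ifelse(is.na(parent), -1L, newId[as.character(parent)])
  typeOut <- c(soma = 1L, dendrite = 3L, undefined = 0L)[nodes$kind[idx]]
  radius <- nodes$radius[idx]
  radius[is.na(radius)] <- 1.0
  ## %.17g keeps doubles exact, so a round-trip preserves metrics bit-for-bit
  lines <- sprintf("%d %d %.17g %.17g %.17g %.17g %d",
                   newId, typeOut, nodes$x[idx], nodes$y[idx], nodes$z[idx],
                   radius, parentOut)
  lines <- c("# SWC written by neuroarbor", lines)
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}
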