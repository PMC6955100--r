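#' Spatial extent of a brain region
#'
#' An axis-aligned box, in µm, spanning the region over which counting
#' blocks are placed and centroid fields are simulated.
#'
#' @param size numeric(3), extents along x, y, z (µm), all > 0.
#' @param origin numeric(3), lower corner (µm).
#' @param label region label.
#' @return A list of class \code{"regionExtent"}.
#' @export
regionExtent <- function(size, origin = c(0, 0, 0), label = NA_character_) {
  stopifnot(length(size) == 3L, all(size > 0), length(origin) == 3L)
  structure(list(origin = as.numeric(origin), size = as.numeric(size),
                 label = as.character(label)),
            class = "regionExtent")
}

#' Place stereological counting blocks
#'
#' Systematically random placement of cubic counting blocks along the
#' longest axis of a region: the first block starts at a uniformly random
#' offset (seeded) within one spacing interval, subsequent blocks repeat
#' at the spacing; every block lies fully inside the extent. Defaults
#' follow the conventional unbiased design of five 300 µm cubes at 3 mm
#' intervals along the whole length of the region.
#'
#' @param extent a \code{\link{regionExtent}}.
#' @param blockEdgeUm block edge length (µm), default 300.
#' @param nBlocks number of blocks, default 5.
#' @param spacingUm interval between successive block origins (µm),
#'   default 3000. Shrunk with a warning when the region's long axis
#'   cannot accommodate all blocks at this spacing.
#' @param randomStart logical; draw the starting offset uniformly at
#'   random (TRUE, the unbiased design) or start at the region origin.
#' @param seed optional integer seed for the random start.
#' @return data.frame with one row per block: \code{block_index},
#'   \code{origin_x}, \code{origin_y}, \code{origin_z}, \code{edge_um}.
#' @export
placeCountingBlocks <- function(extent, blockEdgeUm = 300, nBlocks = 5,
                                spacingUm = 3000, randomStart = TRUE,
                                seed = NULL) {
  stopifnot(inherits(extent, "regionExtent"), blockEdgeUm > 0, nBlocks >= 1,
            spacingUm >= blockEdgeUm)
  axis <- which.max(extent$size)
  L <- extent$size[axis]
  if (any(extent$size < blockEdgeUm))
    stop("configuration error: extent (",
         paste(extent$size, collapse = " x "),
         ") cannot accommodate a single block of edge ", blockEdgeUm)
  span <- (nBlocks - 1) * spacingUm + blockEdgeUm
  if (span > L) {
    spacingUm <- if (nBlocks > 1) (L - blockEdgeUm) / (nBlocks - 1) else spacingUm
    warning(sprintf(
      "long axis (%g um) cannot hold %d blocks at %g um spacing; spacing shrunk to %g um",
      L, nBlocks, span - blockEdgeUm + spacingUm, spacingUm), call. = FALSE)
    span <- (nBlocks - 1) * spacingUm + blockEdgeUm
  }
  slack <- L - span
  offset <- 0
  if (randomStart && slack > 0) {
    if (!is.null(seed)) set.seed(seed)
    offset <- stats::runif(1, 0, min(spacingUm, slack))
  }
  origins <- matrix(extent$origin, nBlocks, 3L, byrow = TRUE)
  origins[, axis] <- origins[, axis] + offset +
    (seq_len(nBlocks) - 1) * spacingUm
  data.frame(block_index = seq_len(nBlocks),
             origin_x = origins[, 1L], origin_y = origins[, 2L],
             origin_z = origins[, 3L], edge_um = blockEdgeUm)
}

#' Count marker centroids in blocks and estimate density
#'
#' A marker falls in a block iff \code{origin <= coordinate < origin +
#' edge} on every axis; the half-open convention means a centroid exactly
#' on the shared face of two adjacent blocks is counted once, in the
#' higher block, never twice. The density estimate is the total count
#' divided by the total block volume.
#'
#' @param blocks data.frame from \code{\link{placeCountingBlocks}}.
#' @param centroids data.frame or matrix with columns/cols
#'   \code{x_um}, \code{y_um}, \code{z_um} (or unnamed xyz), in the same
#'   coordinate frame as the blocks.
#' @return list with \code{blocks} (the input plus a \code{count} column),
#'   \code{totalCount}, and \code{densityPerUm3}.
#' @export
countMarkers <- function(blocks, centroids) {
  xyz <- .asCentroidMatrix(centroids)
  counts <- integer(nrow(blocks))
  for (i in seq_len(nrow(blocks))) {
    o <- c(blocks$origin_x[i], blocks$origin_y[i], blocks$origin_z[i])
    e <- blocks$edge_um[i]
    inBlock <- xyz[, 1L] >= o[1L] & xyz[, 1L] < o[1L] + e &
      xyz[, 2L] >= o[2L] & xyz[, 2L] < o[2L] + e &
      xyz[, 3L] >= o[3L] & xyz[, 3L] < o[3L] + e
    counts[i] <- sum(inBlock)
  }
  blocks$count <- counts
  totalVol <- sum(blocks$edge_um^3)
  list(blocks = blocks, totalCount = sum(counts),
       densityPerUm3 = sum(counts) / totalVol)
}

.asCentroidMatrix <- function(centroids) {
  if (is.matrix(centroids)) {
    stopifnot(ncol(centroids) >= 3L)
    return(centroids[, 1:3, drop = FALSE])
  }
  stopifnot(is.data.frame(centroids))
  cols <- if (all(c("x_um", "y_um", "z_um") %in% names(centroids)))
    c("x_um", "y_um", "z_um") else names(centroids)[1:3]
  as.matrix(centroids[, cols])
}

#' Read / write a centroid list
#'
#' Plain tabular centroid coordinates in µm, CSV columns
#' \code{x_um,y_um,z_um} plus an optional \code{label}.
#'
#' @param file CSV path.
#' @param centroids matrix or data.frame of centroids.
#' @return \code{readCentroids}: data.frame; \code{writeCentroids}: the
#'   data.frame written, invisibly.
#' @export
readCentroids <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("x_um", "y_um", "z_um") %in% names(df)))
    stop("centroid CSV must have columns x_um,y_um,z_um")
  df
}

#' @rdname readCentroids
#' @export
writeCentroids <- function(centroids, file) {
  xyz <- .asCentroidMatrix(centroids)
  df <- data.frame(x_um = xyz[, 1L], y_um = xyz[, 2L], z_um = xyz[, 3L])
  utils::write.csv(df, file, row.names = FALSE)
  invisible(df)
}

#' Stereological density estimate for a region
#'
#' Convenience wrapper: place blocks, count centroids, report per-block
#' counts and the pooled density. With \code{perMouse} grouping the
#' per-mouse mean block count is also emitted, mirroring a design where
#' each animal contributes one systematic series of blocks.
#'
#' @param extent a \code{\link{regionExtent}}.
#' @param centroids centroid list (see \code{\link{countMarkers}}).
#' @param ... passed to \code{\link{placeCountingBlocks}}.
#' @return list with \code{blocks}, \code{totalCount},
#'   \code{densityPerUm3}, and \code{meanBlockCount}.
#' @export
estimateDensity <- function(extent, centroids, ...) {
  blocks <- placeCountingBlocks(extent, ...)
  res <- countMarkers(blocks, centroids)
  res$meanBlockCount <- mean(res$blocks$count)
  res
}
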