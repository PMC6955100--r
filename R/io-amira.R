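#' Read an Amira SpatialGraph ASCII file
#'
#' Parses the HxSpatialGraph ASCII dialect (AmiraMesh 3D ASCII with
#' \code{VERTEX}/\code{EDGE}/\code{POINT} arrays referenced by \code{@}
#' data blocks) into a \code{\linkS4class{NeuronTree}}. Edge point lists
#' conventionally repeat the endpoint vertex coordinates; those duplicates
#' are dropped so each interior point becomes one chain node. The first
#' vertex of the file is taken as the soma unless \code{rootVertex}
#' designates another one.
#'
#' @param file path to a \code{.am} file, or lines via \code{text}.
#' @param text optional character vector of file lines.
#' @param rootVertex 1-based index of the vertex to use as soma root
#'   (default 1, the file's first vertex).
#' @param meta a \code{\linkS4class{SpecimenMeta}} to attach.
#' @return A validated \code{\linkS4class{NeuronTree}}.
#' @export
readAmiraSpatialGraph <- function(file, text = NULL, rootVertex = 1L,
                                  meta = SpecimenMeta()) {
  lines <- if (!is.null(text)) text else readLines(file, warn = FALSE)
  if (!length(lines) || !grepl("AmiraMesh", lines[1L]))
    stop("not an AmiraMesh file (missing '# AmiraMesh' header)")
  if (grepl("BINARY", lines[1L], ignore.case = TRUE))
    stop("unsupported dialect: detected binary AmiraMesh ('",
         trimws(lines[1L]), "'); only the 3D ASCII SpatialGraph dialect is supported")

  getDefine <- function(what) {
    m <- regmatches(lines, regexpr(sprintf("^\\s*define\\s+%s\\s+(\\d+)", what),
                                   lines))
    if (!length(m)) stop("Amira parse error: missing 'define ", what, "'")
    as.integer(sub(".*\\s", "", m[1L]))
  }
  nV <- getDefine("VERTEX")
  nE <- getDefine("EDGE")
  nP <- getDefine("POINT")

  ## which @block holds which named array
  decl <- regmatches(lines,
    regexpr("^\\s*(VERTEX|EDGE|POINT)\\s*\\{[^}]*\\b(\\w+)\\s*\\}\\s*@(\\d+)",
            lines))
  blockOf <- list()
  for (d in decl) {
    nm <- sub(".*\\b(\\w+)\\s*\\}.*", "\\1", d)
    id <- sub(".*@(\\d+).*", "\\1", d)
    blockOf[[nm]] <- id
  }
  need <- c("VertexCoordinates", "EdgeConnectivity", "NumEdgePoints",
            "EdgePointCoordinates")
  miss <- setdiff(need, names(blockOf))
  if (length(miss))
    stop("Amira parse error: missing array declaration(s): ",
         paste(miss, collapse = ", "))

  readBlock <- function(id, nRows, nCols) {
    start <- grep(sprintf("^@%s\\s*$", id), lines)
    if (!length(start))
      stop("Amira parse error: data block @", id, " not found")
    body <- lines[seq.int(start[1L] + 1L, length(lines))]
    stopAt <- grep("^@\\d+\\s*$", body)
    if (length(stopAt)) body <- body[seq_len(stopAt[1L] - 1L)]
    body <- trimws(body[grepl("\\S", body)])
    vals <- suppressWarnings(as.numeric(unlist(strsplit(body, "\\s+"))))
    if (anyNA(vals) || length(vals) != nRows * nCols)
      stop(sprintf("Amira parse error: block @%s should hold %d x %d numbers",
                   id, nRows, nCols))
    matrix(vals, ncol = nCols, byrow = TRUE)
  }
  verts <- readBlock(blockOf$VertexCoordinates, nV, 3L)
  conn <- readBlock(blockOf$EdgeConnectivity, nE, 2L)
  npts <- as.integer(readBlock(blockOf$NumEdgePoints, nE, 1L))
  pts <- readBlock(blockOf$EdgePointCoordinates, nP, 3L)
  if (sum(npts) != nP)
    stop("Amira parse error: NumEdgePoints sums to ", sum(npts),
         " but POINT defines ", nP)
  conn <- conn + 1L  # file is 0-based

  ## connectivity check over the vertex graph
  comp <- .graphComponents(nV, conn)
  if (max(comp) > 1L) {
    byComp <- split(seq_len(nV), comp)
    stop("Amira structural error: graph has ", max(comp),
         " disconnected components: ",
         paste(vapply(byComp, function(v)
           paste0("{", paste(v, collapse = ","), "}"), ""), collapse = " "))
  }
  if (rootVertex < 1L || rootVertex > nV)
    stop("rootVertex out of range 1..", nV)

  ptStart <- c(0L, cumsum(npts))[seq_len(nE)]
  edgePts <- lapply(seq_len(nE), function(e) {
    if (npts[e] == 0L) return(matrix(numeric(), 0L, 3L))
    pts[ptStart[e] + seq_len(npts[e]), , drop = FALSE]
  })

  ## BFS from the root vertex, emitting chain nodes for interior points
  ids <- integer(); parents <- integer()
  xs <- numeric(); ys <- numeric(); zs <- numeric()
  addNode <- function(pos, parent) {
    id <- length(ids) + 1L
    ids[id] <<- id; parents[id] <<- parent
    xs[id] <<- pos[1L]; ys[id] <<- pos[2L]; zs[id] <<- pos[3L]
    id
  }
  vertNode <- rep(NA_integer_, nV)
  vertNode[rootVertex] <- addNode(verts[rootVertex, ], NA_integer_)
  edgeDone <- rep(FALSE, nE)
  frontier <- rootVertex
  while (length(frontier)) {
    v <- frontier[1L]; frontier <- frontier[-1L]
    for (e in which(!edgeDone & (conn[, 1L] == v | conn[, 2L] == v))) {
      edgeDone[e] <- TRUE
      w <- if (conn[e, 1L] == v) conn[e, 2L] else conn[e, 1L]
      p <- edgePts[[e]]
      if (conn[e, 1L] != v && nrow(p)) p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
      ## drop repeated endpoint coordinates
      if (nrow(p) && all(p[1L, ] == verts[v, ])) p <- p[-1L, , drop = FALSE]
      if (nrow(p) && all(p[nrow(p), ] == verts[w, ])) p <- p[-nrow(p), , drop = FALSE]
      cur <- vertNode[v]
      if (nrow(p)) for (k in seq_len(nrow(p))) cur <- addNode(p[k, ], cur)
      if (is.na(vertNode[w])) {
        vertNode[w] <- addNode(verts[w, ], cur)
        frontier <- c(frontier, w)
      }
      ## an already-visited w would mean a cycle; leave it for validation
    }
  }
  nodes <- data.frame(id = ids, parent = parents, x = xs, y = ys, z = zs,
                      radius = 1.0,
                      kind = ifelse(is.na(parents), "soma", "dendrite"),
                      stringsAsFactors = FALSE)
  NeuronTree(nodes, meta = meta)
}

.graphComponents <- function(nV, conn) {
  comp <- rep(0L, nV)
  cur <- 0L
  for (s in seq_len(nV)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    frontier <- s
    while (length(frontier)) {
      comp[frontier] <- cur
      nb <- c(conn[conn[, 1L] %in% frontier, 2L],
              conn[conn[, 2L] %in% frontier, 1L])
      frontier <- unique(nb[comp[nb] == 0L])
    }
  }
  comp
}

#' Write a neuron tree as an Amira SpatialGraph ASCII file
#'
#' The inverse of \code{\link{readAmiraSpatialGraph}}: branch points, the
#' soma and terminals become graph vertices; each unbranched path becomes
#' one edge whose point list includes both endpoints (the usual Amira
#' layout). The soma is written as the first vertex.
#'
#' @param tree a valid \code{\linkS4class{NeuronTree}}.
#' @param file path to write to, or \code{NULL} to return the lines.
#' @return Invisibly, the character vector of file lines.
#' @export
writeAmiraSpatialGraph <- function(tree, file = NULL) {
  .assertValidTree(tree)
  nodes <- tree@nodes
  nKids <- table(factor(nodes$parent, levels = nodes$id))
  isVertex <- nodes$id == tree@somaId | nKids[as.character(nodes$id)] != 1L
  vertIds <- c(tree@somaId, setdiff(nodes$id[isVertex], tree@somaId))
  vertIdx <- seq_along(vertIds) - 1L  # 0-based in file
  names(vertIdx) <- as.character(vertIds)

  kids <- split(nodes$id, factor(nodes$parent, levels = nodes$id))
  pos <- function(id) {
    i <- match(id, nodes$id)
    c(nodes$x[i], nodes$y[i], nodes$z[i])
  }
  edges <- list()
  for (v in vertIds) {
    for (child in kids[[as.character(v)]]) {
      path <- c(v, child)
      while (!(child %in% vertIds)) {
        child <- kids[[as.character(child)]][1L]
        path <- c(path, child)
      }
      edges[[length(edges) + 1L]] <- path
    }
  }
  nE <- length(edges)
  connLines <- vapply(edges, function(p)
    sprintf("%d %d", vertIdx[as.character(p[1L])],
            vertIdx[as.character(p[length(p)])]), "")
  nptsLines <- vapply(edges, function(p) sprintf("%d", length(p)), "")
  fmt3 <- function(p) sprintf("%.17g %.17g %.17g", p[1L], p[2L], p[3L])
  ptLines <- unlist(lapply(edges, function(p) vapply(p, function(id)
    fmt3(pos(id)), "")))
  vertLines <- vapply(vertIds, function(id) fmt3(pos(id)), "")

  lines <- c(
    "# AmiraMesh 3D ASCII 2.0",
    "",
    sprintf("define VERTEX %d", length(vertIds)),
    sprintf("define EDGE %d", nE),
    sprintf("define POINT %d", length(ptLines)),
    "",
    "Parameters {",
    "    ContentType \"HxSpatialGraph\"",
    "}",
    "",
    "VERTEX { float[3] VertexCoordinates } @1",
    "EDGE { int[2] EdgeConnectivity } @2",
    "EDGE { int NumEdgePoints } @3",
    "POINT { float[3] EdgePointCoordinates } @4",
    "",
    "@1", vertLines, "",
    "@2", connLines, "",
    "@3", nptsLines, "",
    "@4", ptLines, "")
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}
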