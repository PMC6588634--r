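#' @include AllClasses.R geometry-utils.R
NULL

#' Read / write geometry in standard formats
#'
#' \code{readGeometry}/\code{writeGeometry} dispatch on \code{format}
#' (or the file extension): \code{"ply"}/\code{"obj"} for meshes,
#' \code{"swc"} for skeletons, \code{"edgelist"}/\code{"graphml"} for
#' supervoxel graphs. Round trips preserve topology exactly and coordinates
#' to the written precision. Graph formats serialize ids, edges, volumes and
#' labels; meshes and sample locations are not embedded.
#'
#' @param path file path.
#' @param format one of \code{"ply"}, \code{"obj"}, \code{"swc"},
#'   \code{"edgelist"}, \code{"graphml"}; guessed from the extension when
#'   missing.
#' @return \code{readGeometry}: a \linkS4class{TriangleMesh},
#'   \linkS4class{Skeleton} or \linkS4class{SupervoxelGraph}.
#' @export
readGeometry <- function(path, format = NULL) {
  format <- .geomFormat(path, format)
  switch(format,
         ply = readPLY(path), obj = readOBJ(path), swc = readSWC(path),
         edgelist = readSVEdgeList(path), graphml = readSVGraphML(path))
}

#' @rdname readGeometry
#' @param x object to write.
#' @export
writeGeometry <- function(x, path, format = NULL) {
  format <- .geomFormat(path, format)
  switch(format,
         ply = writePLY(x, path), obj = writeOBJ(x, path),
         swc = writeSWC(x, path), edgelist = writeSVEdgeList(x, path),
         graphml = writeSVGraphML(x, path))
  invisible(path)
}

.geomFormat <- function(path, format) {
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  format <- match.arg(tolower(format),
                      c("ply", "obj", "swc", "edgelist", "graphml"))
  format
}

## ---- PLY (ASCII) -----------------------------------------------------------

#' @rdname readGeometry
#' @export
readPLY <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || trimws(lines[1]) != "ply")
    stop("PLY parse error at line 1: missing 'ply' magic in ", path)
  endHdr <- which(trimws(lines) == "end_header")[1]
  if (is.na(endHdr)) stop("PLY parse error: no end_header in ", path)
  hdr <- lines[seq_len(endHdr)]
  nV <- nF <- 0L
  props <- character(0)
  cur <- ""
  for (i in seq_along(hdr)) {
    tok <- strsplit(trimws(hdr[i]), "\\s+")[[1]]
    if (!length(tok)) next
    if (tok[1] == "element") {
      cur <- tok[2]
      if (cur == "vertex") nV <- as.integer(tok[3])
      if (cur == "face") nF <- as.integer(tok[3])
    } else if (tok[1] == "property" && cur == "vertex" &&
               tok[2] != "list") {
      props <- c(props, tok[length(tok)])
    }
  }
  body <- lines[-seq_len(endHdr)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < nV + nF)
    stop("PLY parse error: expected ", nV + nF, " records, found ",
         length(body), " in ", path)
  vrec <- strsplit(trimws(body[seq_len(nV)]), "\\s+")
  vmat <- do.call(rbind, lapply(seq_along(vrec), function(i) {
    v <- suppressWarnings(as.numeric(vrec[[i]]))
    if (anyNA(v) || length(v) < 3L)
      stop("PLY parse error at vertex record ", i, " in ", path)
    v
  }))
  lab <- integer(0)
  li <- match("label", props)
  if (!is.na(li) && ncol(vmat) >= li) lab <- as.integer(vmat[, li])
  frec <- strsplit(trimws(body[nV + seq_len(nF)]), "\\s+")
  fmat <- if (nF) do.call(rbind, lapply(seq_len(nF), function(i) {
    v <- suppressWarnings(as.integer(frec[[i]]))
    if (anyNA(v) || v[1] != 3L || length(v) < 4L)
      stop("PLY parse error at face record ", i,
           ": only triangles supported, in ", path)
    v[2:4] + 1L
  })) else matrix(integer(0), 0, 3)
  TriangleMesh(vmat[, 1:3, drop = FALSE], fmat, lab)
}

#' @rdname readGeometry
#' @export
writePLY <- function(x, path) {
  stopifnot(is(x, "TriangleMesh"))
  lab <- x@vertexLabels
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nVertices(x)),
           "property double x", "property double y", "property double z",
           if (length(lab)) "property int label",
           sprintf("element face %d", nFaces(x)),
           "property list uchar int vertex_indices", "end_header")
  vfmt <- cbind(format(x@vertices[, 1], digits = 17, trim = TRUE, scientific = FALSE),
                format(x@vertices[, 2], digits = 17, trim = TRUE, scientific = FALSE),
                format(x@vertices[, 3], digits = 17, trim = TRUE, scientific = FALSE))
  vlines <- if (nVertices(x)) {
    if (length(lab)) paste(vfmt[, 1], vfmt[, 2], vfmt[, 3], lab)
    else paste(vfmt[, 1], vfmt[, 2], vfmt[, 3])
  } else character(0)
  flines <- if (nFaces(x))
    paste(3L, x@faces[, 1] - 1L, x@faces[, 2] - 1L, x@faces[, 3] - 1L)
  else character(0)
  writeLines(c(hdr, vlines, flines), path)
  invisible(path)
}

## ---- OBJ -------------------------------------------------------------------

#' @rdname readGeometry
#' @export
readOBJ <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vs <- list(); fs <- list()
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (!length(tok) || tok[1] %in% c("#", "")) next
    if (tok[1] == "v") {
      v <- suppressWarnings(as.numeric(tok[2:4]))
      if (anyNA(v)) stop("OBJ parse error at line ", i, " in ", path)
      vs[[length(vs) + 1L]] <- v
    } else if (tok[1] == "f") {
      idx <- suppressWarnings(as.integer(sub("/.*", "", tok[-1])))
      if (anyNA(idx) || length(idx) != 3L)
        stop("OBJ parse error at line ", i,
             ": only triangular faces supported, in ", path)
      fs[[length(fs) + 1L]] <- idx
    }
  }
  TriangleMesh(do.call(rbind, vs),
               if (length(fs)) do.call(rbind, fs) else matrix(integer(0), 0, 3))
}

#' @rdname readGeometry
#' @export
writeOBJ <- function(x, path) {
  stopifnot(is(x, "TriangleMesh"))
  vl <- sprintf("v %.9g %.9g %.9g", x@vertices[, 1], x@vertices[, 2],
                x@vertices[, 3])
  fl <- if (nFaces(x)) sprintf("f %d %d %d", x@faces[, 1], x@faces[, 2],
                               x@faces[, 3]) else character(0)
  writeLines(c(vl, fl), path)
  invisible(path)
}

## ---- SWC -------------------------------------------------------------------

#' @rdname readGeometry
#' @export
readSWC <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  recs <- strsplit(trimws(lines[keep]), "\\s+")
  lineNo <- which(keep)
  n <- length(recs)
  if (!n) return(Skeleton(matrix(numeric(0), 0, 3)))
  m <- matrix(NA_real_, n, 7)
  for (i in seq_len(n)) {
    v <- suppressWarnings(as.numeric(recs[[i]]))
    if (length(v) != 7L || anyNA(v))
      stop("SWC parse error at line ", lineNo[i], ": expected 7 fields, in ",
           path)
    m[i, ] <- v
  }
  ids <- as.integer(m[, 1])
  parent <- as.integer(m[, 7])
  bad <- parent != -1L & !(parent %in% ids)
  if (any(bad))
    stop("SWC parse error at line ", lineNo[which(bad)[1]],
         ": node references missing parent ", parent[which(bad)[1]],
         ", in ", path)
  ord <- match(ids, ids)  # keep file order; indices by id lookup
  e <- cbind(match(parent[parent != -1L], ids), which(parent != -1L))
  Skeleton(m[, 3:5, drop = FALSE], e, radii = m[, 6],
           nodeLabels = as.integer(m[, 2]))
}

#' @rdname readGeometry
#' @export
writeSWC <- function(x, path) {
  stopifnot(is(x, "Skeleton"))
  n <- nrow(x@nodes)
  ## root every connected component at its lowest-index node, parents via BFS
  parent <- rep(-1L, n)
  adj <- .adjList(n, x@edges)
  visited <- logical(n)
  for (r in seq_len(n)) {
    if (visited[r]) next
    queue <- r; visited[r] <- TRUE
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (v in adj[[u]]) if (!visited[v]) {
        visited[v] <- TRUE; parent[v] <- u; queue <- c(queue, v)
      }
    }
  }
  lab <- if (length(x@nodeLabels)) ifelse(is.na(x@nodeLabels), 0L,
                                          x@nodeLabels) else rep(0L, n)
  lines <- sprintf("%d %d %.9g %.9g %.9g %.9g %d", seq_len(n), lab,
                   x@nodes[, 1], x@nodes[, 2], x@nodes[, 3], x@radii, parent)
  writeLines(c("# SWC export (coordinates nm, radius nm)", lines), path)
  invisible(path)
}

.adjList <- function(n, e) {
  adj <- rep(list(integer(0)), n)
  if (nrow(e)) {
    for (k in seq_len(nrow(e))) {
      adj[[e[k, 1]]] <- c(adj[[e[k, 1]]], e[k, 2])
      adj[[e[k, 2]]] <- c(adj[[e[k, 2]]], e[k, 1])
    }
  }
  adj
}

## ---- SV graph: TSV edge list & GraphML ------------------------------------

#' @rdname readGeometry
#' @export
readSVEdgeList <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  nodeIds <- character(0); e <- list()
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) == 1L) nodeIds <- c(nodeIds, tok)
    else if (length(tok) == 2L) e[[length(e) + 1L]] <- tok
    else stop("edge-list parse error at record ", i, " in ", path)
  }
  em <- if (length(e)) do.call(rbind, e) else matrix(character(0), 0, 2)
  ids <- unique(c(nodeIds, as.vector(em)))
  meshes <- rep(list(TriangleMesh(matrix(numeric(0), 0, 3))), length(ids))
  g <- SupervoxelGraph(ids, meshes,
                       locations = rep(list(matrix(numeric(0), 0, 3)),
                                       length(ids)),
                       edges = em)
  g
}

#' @rdname readGeometry
#' @export
writeSVEdgeList <- function(x, path) {
  stopifnot(is(x, "SupervoxelGraph"))
  iso <- setdiff(x@ids, unique(as.vector(x@edges)))
  lines <- c("# supervoxel adjacency: one 'a<TAB>b' edge or isolated id per line",
             if (nrow(x@edges)) paste(x@edges[, 1], x@edges[, 2], sep = "\t"),
             iso)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname readGeometry
#' @export
readSVGraphML <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  ids <- igraph::V(g)$name
  att <- igraph::vertex_attr_names(g)
  vol <- if ("volume" %in% att) igraph::V(g)$volume else numeric(length(ids))
  lab <- if ("label" %in% att) {
    l <- igraph::V(g)$label
    suppressWarnings(as.integer(l))
  } else rep(NA_integer_, length(ids))
  locs <- if (all(c("x", "y", "z") %in% att)) {
    lapply(seq_along(ids), function(i)
      matrix(c(igraph::V(g)$x[i], igraph::V(g)$y[i], igraph::V(g)$z[i]),
             1, 3))
  } else rep(list(matrix(numeric(0), 0, 3)), length(ids))
  em <- igraph::as_edgelist(g)
  meshes <- rep(list(TriangleMesh(matrix(numeric(0), 0, 3))), length(ids))
  SupervoxelGraph(ids, meshes, volumes = vol, locations = locs,
                  labels = lab, edges = em)
}

#' @rdname readGeometry
#' @export
writeSVGraphML <- function(x, path) {
  stopifnot(is(x, "SupervoxelGraph"))
  ## one representative coordinate per SV (mesh centroid, else first
  ## sample location) so geometry-free readers keep a usable position
  ctr <- t(vapply(x@ids, function(i) {
    V <- x@meshes[[i]]@vertices
    if (nrow(V)) colMeans(V)
    else if (nrow(x@locations[[i]])) x@locations[[i]][1, ]
    else c(NA_real_, NA_real_, NA_real_)
  }, numeric(3)))
  g <- igraph::graph_from_data_frame(
    d = as.data.frame(x@edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = x@ids, volume = x@volumes,
                          label = ifelse(is.na(x@labels), "", x@labels),
                          x = ctr[, 1], y = ctr[, 2], z = ctr[, 3],
                          stringsAsFactors = FALSE))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
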