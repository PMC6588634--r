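#' @include AllClasses.R AllGenerics.R
NULL

NM_PER_UM <- 1e3

#' @describeIn bbd diagonal of a point matrix (rows = points, nm)
#' @export
setMethod("bbd", "matrix", function(x, ...) {
  if (nrow(x) == 0L) stop("bbd: empty point set")
  rng <- apply(x, 2L, range)
  sqrt(sum((rng[2L, ] - rng[1L, ])^2)) / NM_PER_UM
})

#' @describeIn bbd diagonal over the mesh vertices
#' @export
setMethod("bbd", "TriangleMesh", function(x, ...) bbd(x@vertices))

#' @describeIn bbd diagonal over the pooled mesh vertices of a set of SVs
#' @param ids optional subset of SV ids (default: all).
#' @export
setMethod("bbd", "SupervoxelGraph", function(x, ids = svIds(x), ...) {
  vs <- do.call(rbind, lapply(x@meshes[ids], function(m) m@vertices))
  bbd(vs)
})

#' Connected components of a supervoxel graph
#'
#' Components are maximal under adjacency restricted to the nodes kept by
#' \code{nodeFilter}; isolated kept nodes are singleton components.
#'
#' @param graph a \linkS4class{SupervoxelGraph}.
#' @param nodeFilter optional predicate taking an SV id and returning
#'   TRUE/FALSE, or a character vector of ids to keep.
#' @return list of character vectors (SV-id sets), a partition of the kept
#'   node set. Empty list for an empty graph.
#' @export
connectedComponents <- function(graph, nodeFilter = NULL) {
  ids <- svIds(graph)
  keep <- if (is.null(nodeFilter)) ids
          else if (is.character(nodeFilter)) intersect(ids, nodeFilter)
          else ids[vapply(ids, nodeFilter, logical(1))]
  if (!length(keep)) return(list())
  e <- graph@edges
  e <- e[e[, 1] %in% keep & e[, 2] %in% keep, , drop = FALSE]
  comp <- .componentsUF(keep, e)
  unname(split(keep, comp))
}

## union-find components over arbitrary node ids; returns component index
## per node (in order of `ids`)
.componentsUF <- function(ids, edgeMat) {
  n <- length(ids)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(edgeMat)) {
    a <- match(edgeMat[, 1], ids)
    b <- match(edgeMat[, 2], ids)
    for (k in seq_along(a)) {
      ra <- find(a[k]); rb <- find(b[k])
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Euler characteristic of a mesh
#'
#' V - E + F with E counted from the undirected edge set of the faces.
#' A closed genus-0 surface has Euler characteristic 2.
#'
#' @param mesh a \linkS4class{TriangleMesh}.
#' @return integer scalar.
#' @export
eulerCharacteristic <- function(mesh) {
  f <- mesh@faces
  if (!nrow(f)) return(nVertices(mesh))
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(1, 3)])
  e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  nVertices(mesh) - nrow(e) + nrow(f)
}

#' Merge meshes into one
#'
#' Concatenates vertex and face lists (face indices re-offset); labels are
#' kept when every part carries them.
#'
#' @param meshes list of \linkS4class{TriangleMesh}.
#' @return a single \linkS4class{TriangleMesh}.
#' @export
mergeMeshes <- function(meshes) {
  meshes <- meshes[vapply(meshes, nVertices, integer(1)) > 0L]
  if (!length(meshes)) return(TriangleMesh(matrix(numeric(0), 0, 3)))
  off <- cumsum(c(0L, vapply(meshes, nVertices, integer(1))))
  vs <- do.call(rbind, lapply(meshes, vertices))
  fs <- do.call(rbind, Map(function(m, o) m@faces + o, meshes,
                           off[seq_along(meshes)]))
  lbs <- lapply(meshes, function(m) m@vertexLabels)
  lab <- if (all(lengths(lbs) > 0L)) unlist(lbs, use.names = FALSE) else integer(0)
  TriangleMesh(vs, fs, lab)
}

## k nearest neighbours by Euclidean distance, brute force in blocks.
## Returns list(index = n_query x k matrix, dist = matrix).
.knn <- function(train, query, k) {
  train <- as.matrix(train); query <- as.matrix(query)
  k <- min(k, nrow(train))
  nq <- nrow(query)
  idx <- matrix(0L, nq, k); dst <- matrix(0, nq, k)
  tr2 <- rowSums(train^2)
  block <- max(1L, floor(2e7 / nrow(train)))
  for (s in seq(1L, nq, by = block)) {
    e <- min(nq, s + block - 1L)
    q <- query[s:e, , drop = FALSE]
    d2 <- outer(rowSums(q^2), tr2, "+") - 2 * q %*% t(train)
    d2[d2 < 0] <- 0
    for (i in seq_len(e - s + 1L)) {
      o <- order(d2[i, ])[seq_len(k)]
      idx[s + i - 1L, ] <- o
      dst[s + i - 1L, ] <- sqrt(d2[i, o])
    }
  }
  list(index = idx, dist = dst)
}

## majority vote among k nearest labeled points; ties -> lowest class code
.knnVote <- function(train, labels, query, k) {
  nn <- .knn(train, query, k)
  apply(nn$index, 1L, function(ix) {
    tb <- table(labels[ix])
    cls <- as.integer(names(tb))
    min(cls[tb == max(tb)])
  })
}

## rotation matrix about a unit axis by angle (radians)
.rotationAboutAxis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle)
  ux <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  c_ * diag(3) + s_ * ux + (1 - c_) * (u %o% u)
}
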