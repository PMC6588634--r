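#' @include AllGenerics.R
NULL

#' TriangleMesh: triangle surface mesh in nanometer coordinates
#'
#' The universal geometry carrier of the package. Vertices are 3D positions
#' in nanometers; faces are 1-based triplets of vertex indices. Per-vertex
#' integer class labels are optional (length 0 when absent).
#'
#' @slot vertices numeric matrix, n x 3 (nm).
#' @slot faces integer matrix, m x 3, 1-based vertex indices.
#' @slot vertexLabels integer vector of length n or 0.
#' @export
setClass("TriangleMesh",
  representation(vertices = "matrix", faces = "matrix",
                 vertexLabels = "integer"),
  prototype(vertices = matrix(numeric(0), 0, 3),
            faces = matrix(integer(0), 0, 3),
            vertexLabels = integer(0)))

setValidity("TriangleMesh", function(object) {
  v <- object@vertices; f <- object@faces
  if (ncol(v) != 3L) return("vertices must have 3 columns")
  if (ncol(f) != 3L) return("faces must have 3 columns")
  if (length(v) && !all(is.finite(v))) return("vertex coordinates must be finite")
  if (nrow(f)) {
    if (nrow(v) == 0L) return("faces present but no vertices")
    if (min(f) < 1L || max(f) > nrow(v))
      return("face indices out of range [1, nVertices]")
  }
  lb <- object@vertexLabels
  if (length(lb) && length(lb) != nrow(v))
    return("vertexLabels must be empty or one per vertex")
  TRUE
})

#' Construct a TriangleMesh
#'
#' @param vertices numeric matrix n x 3, coordinates in nm.
#' @param faces integer matrix m x 3 of 1-based vertex indices (may have 0
#'   rows for a bare point cloud carrier).
#' @param vertexLabels optional integer vector, one small-integer class code
#'   per vertex.
#' @return a \linkS4class{TriangleMesh}.
#' @examples
#' m <- TriangleMesh(rbind(c(0, 0, 0), c(1000, 0, 0), c(0, 1000, 0)),
#'                   rbind(c(1L, 2L, 3L)))
#' nFaces(m)
#' @export
TriangleMesh <- function(vertices, faces = matrix(integer(0), 0, 3),
                         vertexLabels = integer(0)) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(faces) == 0L) faces <- matrix(integer(0), 0, 3)
  dimnames(vertices) <- NULL; dimnames(faces) <- NULL
  new("TriangleMesh", vertices = vertices, faces = faces,
      vertexLabels = as.integer(vertexLabels))
}

#' Skeleton: node-and-edge centerline representation
#'
#' Undirected skeleton with node positions in nm, per-node radii in nm and
#' optional integer node labels (e.g. compartment classes).
#'
#' @slot nodes numeric matrix n x 3 (nm).
#' @slot radii numeric vector length n (nm, >= 0).
#' @slot nodeLabels integer vector length n (NA allowed) or length 0.
#' @slot edges integer matrix m x 2 of node indices; no self loops.
#' @export
setClass("Skeleton",
  representation(nodes = "matrix", radii = "numeric",
                 nodeLabels = "integer", edges = "matrix"),
  prototype(nodes = matrix(numeric(0), 0, 3), radii = numeric(0),
            nodeLabels = integer(0), edges = matrix(integer(0), 0, 2)))

setValidity("Skeleton", function(object) {
  n <- nrow(object@nodes)
  if (ncol(object@nodes) != 3L) return("nodes must have 3 columns")
  if (length(object@radii) != n) return("one radius per node required")
  if (length(object@radii) && any(object@radii < 0, na.rm = TRUE))
    return("radii must be >= 0")
  lb <- object@nodeLabels
  if (length(lb) && length(lb) != n)
    return("nodeLabels must be empty or one per node")
  e <- object@edges
  if (ncol(e) != 2L) return("edges must have 2 columns")
  if (nrow(e)) {
    if (min(e) < 1L || max(e) > n) return("edge endpoints out of range")
    if (any(e[, 1] == e[, 2])) return("self-loop edges not allowed")
  }
  TRUE
})

#' Construct a Skeleton
#'
#' Edges are stored undirected and deduplicated (the pair \{i, j\} appears
#' once, with i < j).
#'
#' @param nodes numeric matrix n x 3 (nm).
#' @param edges integer matrix m x 2 of node indices.
#' @param radii numeric vector of node radii (nm); defaults to 0.
#' @param nodeLabels optional integer labels.
#' @return a \linkS4class{Skeleton}.
#' @export
Skeleton <- function(nodes, edges = matrix(integer(0), 0, 2),
                     radii = numeric(nrow(as.matrix(nodes))),
                     nodeLabels = integer(0)) {
  nodes <- as.matrix(nodes); storage.mode(nodes) <- "double"
  dimnames(nodes) <- NULL
  edges <- as.matrix(edges); storage.mode(edges) <- "integer"
  if (ncol(edges) == 0L) edges <- matrix(integer(0), 0, 2)
  if (nrow(edges)) {
    edges <- t(apply(edges, 1L, sort))
    edges <- unique(edges)
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
  }
  dimnames(edges) <- NULL
  new("Skeleton", nodes = nodes, radii = as.numeric(radii),
      nodeLabels = as.integer(nodeLabels), edges = edges)
}

#' SupervoxelGraph: adjacency graph of supervoxels
#'
#' Nodes are supervoxels (SVs), each carrying a mesh, a voxel-derived volume
#' in µm³, sample locations (nm) and an optional class label/probability.
#' Edges are unordered SV-id pairs encoding spatial adjacency; connected
#' components define cells/cell fragments (SSVs). Isolated SVs are singleton
#' SSVs.
#'
#' @slot ids character vector of SV identifiers.
#' @slot meshes named list of \linkS4class{TriangleMesh}.
#' @slot volumes named numeric vector (µm³, >= 0).
#' @slot locations named list of numeric matrices (sample locations, nm).
#' @slot labels named integer vector (0 = neuron, 1 = glia, NA = unknown).
#' @slot probs named numeric vector (glia probability, NA = unknown).
#' @slot edges character matrix m x 2 of SV-id pairs.
#' @export
setClass("SupervoxelGraph",
  representation(ids = "character", meshes = "list", volumes = "numeric",
                 locations = "list", labels = "integer", probs = "numeric",
                 edges = "matrix"))

setValidity("SupervoxelGraph", function(object) {
  ids <- object@ids
  if (anyDuplicated(ids)) return("duplicate SV ids")
  n <- length(ids)
  if (length(object@meshes) != n || length(object@volumes) != n ||
      length(object@locations) != n || length(object@labels) != n ||
      length(object@probs) != n)
    return("per-SV slots must all have one entry per id")
  if (any(object@volumes < 0, na.rm = TRUE)) return("volumes must be >= 0")
  e <- object@edges
  if (ncol(e) != 2L) return("edges must have 2 columns")
  if (nrow(e)) {
    if (!all(e %in% ids)) return("every edge endpoint must be a node")
    if (any(e[, 1] == e[, 2])) return("self-loop edges not allowed")
  }
  TRUE
})

#' Construct a SupervoxelGraph
#'
#' @param ids SV identifiers (coerced to character).
#' @param meshes list of \linkS4class{TriangleMesh}, one per id.
#' @param volumes numeric voxel volumes in µm³ (default 0).
#' @param locations list of k x 3 matrices of sample locations in nm
#'   (default: one location per SV, the mesh vertex centroid).
#' @param labels integer class labels (0 neuron, 1 glia; NA unknown).
#' @param probs numeric glia probabilities (NA unknown).
#' @param edges two-column matrix of SV-id pairs; deduplicated, self loops
#'   dropped.
#' @return a \linkS4class{SupervoxelGraph}.
#' @export
SupervoxelGraph <- function(ids, meshes, volumes = NULL, locations = NULL,
                            labels = NULL, probs = NULL,
                            edges = matrix(character(0), 0, 2)) {
  ids <- as.character(ids)
  n <- length(ids)
  stopifnot(length(meshes) == n)
  names(meshes) <- ids
  if (is.null(volumes)) volumes <- numeric(n)
  volumes <- as.numeric(volumes); names(volumes) <- ids
  if (is.null(locations))
    locations <- lapply(meshes, function(m)
      matrix(colMeans(m@vertices), 1, 3))
  names(locations) <- ids
  if (is.null(labels)) labels <- rep(NA_integer_, n)
  labels <- as.integer(labels); names(labels) <- ids
  if (is.null(probs)) probs <- rep(NA_real_, n)
  probs <- as.numeric(probs); names(probs) <- ids
  edges <- as.matrix(edges)
  if (ncol(edges) == 0L) edges <- matrix(character(0), 0, 2)
  storage.mode(edges) <- "character"
  if (nrow(edges)) {
    edges <- t(apply(edges, 1L, sort))
    edges <- unique(edges)
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
  }
  dimnames(edges) <- NULL
  new("SupervoxelGraph", ids = ids, meshes = meshes, volumes = volumes,
      locations = locations, labels = labels, probs = probs, edges = edges)
}

#' LabeledVolume: dense 3D label grid with anisotropic voxel size
#'
#' @slot data integer 3D array.
#' @slot voxelSize numeric length-3, voxel edge lengths in nm (> 0).
#' @slot offset numeric length-3, global position of the (1,1,1) voxel's
#'   lower corner in nm.
#' @export
setClass("LabeledVolume",
  representation(data = "array", voxelSize = "numeric", offset = "numeric"))

setValidity("LabeledVolume", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L) return("data must be a 3D array")
  if (any(d <= 0L)) return("grid shape must be > 0 in all axes")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    return("voxelSize must be 3 positive values (nm)")
  if (length(object@offset) != 3L) return("offset must have length 3")
  TRUE
})

#' Construct a LabeledVolume
#'
#' @param data integer 3D array of labels.
#' @param voxelSize voxel edge lengths in nm, e.g. \code{c(9, 9, 20)}.
#' @param offset global nm position of the grid origin (lower corner of the
#'   first voxel).
#' @return a \linkS4class{LabeledVolume}.
#' @export
LabeledVolume <- function(data, voxelSize, offset = c(0, 0, 0)) {
  storage.mode(data) <- "integer"
  new("LabeledVolume", data = data, voxelSize = as.numeric(voxelSize),
      offset = as.numeric(offset))
}

#' LocalFrame: PCA-derived orthonormal rendering frame
#'
#' Axes are the first/second/third principal components of the clipped
#' vertex subset around a rendering location, stored as the columns of a
#' right-handed orthonormal 3 x 3 matrix.
#'
#' @slot origin numeric length-3 rendering location (nm).
#' @slot axes numeric 3 x 3 matrix, columns = x, y, z axes.
#' @slot degenerate logical; TRUE when the covariance was rank deficient and
#'   global axes were substituted.
#' @export
setClass("LocalFrame",
  representation(origin = "numeric", axes = "matrix",
                 degenerate = "logical"))

setValidity("LocalFrame", function(object) {
  if (length(object@origin) != 3L) return("origin must have length 3")
  A <- object@axes
  if (!all(dim(A) == c(3L, 3L))) return("axes must be 3 x 3")
  G <- crossprod(A)
  if (max(abs(G - diag(3))) > 1e-6) return("axes must be orthonormal")
  if (det(A) < 0) return("axes must be right-handed")
  TRUE
})

#' ViewSet: multi-channel 8-bit orthographic depth-map views
#'
#' Stack of 8-bit orthographic depth maps rendered at one location; array
#' dimensions are (x, y, perspective, channel). Background pixels are 0;
#' surface pixels map depth linearly to 255 (near clip) .. 1 (far clip).
#'
#' @slot data integer array (nx, ny, nPersp, nChannels), values in 0..255.
#' @slot location numeric length-3 rendering location (nm).
#' @slot channels character vector of channel names.
#' @export
setClass("ViewSet",
  representation(data = "array", location = "numeric",
                 channels = "character"))

setValidity("ViewSet", function(object) {
  d <- dim(object@data)
  if (length(d) != 4L) return("data must be a 4D array (x, y, persp, channel)")
  if (length(object@channels) != d[4])
    return("one channel name per channel required")
  r <- range(object@data)
  if (r[1] < 0L || r[2] > 255L) return("values must be in [0, 255]")
  TRUE
})

## ---- accessors & show ------------------------------------------------------

#' @describeIn nVertices vertex count of a mesh
#' @export
setMethod("nVertices", "TriangleMesh", function(x) nrow(x@vertices))

#' @describeIn nVertices face count of a mesh
#' @export
setMethod("nFaces", "TriangleMesh", function(x) nrow(x@faces))

#' @describeIn vertices mesh vertices
#' @export
setMethod("vertices", "TriangleMesh", function(x) x@vertices)

#' @describeIn faces mesh faces
#' @export
setMethod("faces", "TriangleMesh", function(x) x@faces)

#' @describeIn vertexLabels mesh vertex labels (NULL when absent)
#' @export
setMethod("vertexLabels", "TriangleMesh",
          function(x) if (length(x@vertexLabels)) x@vertexLabels else NULL)

#' @describeIn vertexLabels set mesh vertex labels
#' @export
setMethod("vertexLabels<-", "TriangleMesh", function(x, value) {
  x@vertexLabels <- as.integer(value)
  validObject(x)
  x
})

setMethod("show", "TriangleMesh", function(object) {
  cat(sprintf("TriangleMesh: %d vertices, %d faces%s\n",
              nVertices(object), nFaces(object),
              if (length(object@vertexLabels)) ", labeled" else ""))
  if (nVertices(object))
    cat(sprintf("  bbd: %.3f um\n", bbd(object)))
})

#' @describeIn vertices skeleton node positions
#' @export
setMethod("vertices", "Skeleton", function(x) x@nodes)

#' @describeIn nodes node positions of a skeleton
#' @export
setMethod("nodes", "Skeleton", function(x) x@nodes)

#' @describeIn nodes node radii
#' @export
setMethod("radii", "Skeleton", function(x) x@radii)

#' @describeIn nodes node labels (NULL when absent)
#' @export
setMethod("nodeLabels", "Skeleton",
          function(x) if (length(x@nodeLabels)) x@nodeLabels else NULL)

#' @describeIn nodes set node labels
#' @export
setMethod("nodeLabels<-", "Skeleton", function(x, value) {
  x@nodeLabels <- as.integer(value)
  validObject(x)
  x
})

#' @describeIn edges skeleton edges (node indices)
#' @export
setMethod("edges", "Skeleton", function(x) x@edges)

#' @describeIn pathLength sum of skeleton edge lengths in nm
#' @export
setMethod("pathLength", "Skeleton", function(x) {
  if (!nrow(x@edges)) return(0)
  d <- x@nodes[x@edges[, 1], , drop = FALSE] -
       x@nodes[x@edges[, 2], , drop = FALSE]
  sum(sqrt(rowSums(d^2)))
})

setMethod("show", "Skeleton", function(object) {
  cat(sprintf("Skeleton: %d nodes, %d edges, path length %.2f um\n",
              nrow(object@nodes), nrow(object@edges),
              pathLength(object) / 1e3))
})

#' @describeIn svIds SV identifiers
#' @export
setMethod("svIds", "SupervoxelGraph", function(x) x@ids)

#' @describeIn svVolumes SV volumes in µm³
#' @export
setMethod("svVolumes", "SupervoxelGraph", function(x) x@volumes)

#' @describeIn svLabels SV class labels
#' @export
setMethod("svLabels", "SupervoxelGraph", function(x) x@labels)

#' @describeIn svLabels set SV class labels
#' @export
setMethod("svLabels<-", "SupervoxelGraph", function(x, value) {
  value <- as.integer(value)
  if (is.null(names(value))) names(value) <- x@ids
  x@labels <- value[x@ids]
  names(x@labels) <- x@ids
  validObject(x)
  x
})

#' @describeIn svMeshes SV meshes
#' @export
setMethod("svMeshes", "SupervoxelGraph", function(x) x@meshes)

#' @describeIn edges SV adjacency edges (id pairs)
#' @export
setMethod("edges", "SupervoxelGraph", function(x) x@edges)

setMethod("show", "SupervoxelGraph", function(object) {
  nl <- sum(!is.na(object@labels))
  cat(sprintf("SupervoxelGraph: %d SVs, %d edges, %d labeled\n",
              length(object@ids), nrow(object@edges), nl))
})

setMethod("show", "LabeledVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("LabeledVolume: %d x %d x %d voxels @ (%g, %g, %g) nm, %d foreground\n",
              d[1], d[2], d[3], object@voxelSize[1], object@voxelSize[2],
              object@voxelSize[3], sum(object@data != 0L)))
})

setMethod("show", "LocalFrame", function(object) {
  cat(sprintf("LocalFrame at (%.0f, %.0f, %.0f) nm%s\n", object@origin[1],
              object@origin[2], object@origin[3],
              if (object@degenerate) " [degenerate: global axes]" else ""))
})

#' @describeIn viewArray the raw 8-bit view array
#' @export
setMethod("viewArray", "ViewSet", function(x) x@data)

setMethod("show", "ViewSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("ViewSet: %d x %d px, %d perspective(s), channels: %s\n",
              d[1], d[2], d[3], paste(object@channels, collapse = ", ")))
})
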