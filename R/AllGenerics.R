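#' Number of vertices / faces
#'
#' @param x a \linkS4class{TriangleMesh}.
#' @return integer scalar.
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))

#' @rdname nVertices
#' @export
setGeneric("nFaces", function(x) standardGeneric("nFaces"))

#' Vertex coordinates (nm)
#'
#' @param x an object carrying vertices.
#' @return numeric matrix with one row per vertex and columns x, y, z (nm).
#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))

#' Triangle faces
#'
#' @param x a \linkS4class{TriangleMesh}.
#' @return integer matrix with one row per face (1-based vertex indices).
#' @export
setGeneric("faces", function(x) standardGeneric("faces"))

#' Per-vertex labels
#'
#' @param x an object with per-vertex labels.
#' @return integer vector (length \code{nVertices(x)}) or \code{NULL}.
#' @export
setGeneric("vertexLabels", function(x) standardGeneric("vertexLabels"))

#' @rdname vertexLabels
#' @param value replacement labels.
#' @export
setGeneric("vertexLabels<-", function(x, value) standardGeneric("vertexLabels<-"))

#' Bounding-box diagonal in micrometers
#'
#' Euclidean length of the diagonal of the axis-aligned bounding box of a
#' point set given in nanometers, reported in micrometers. A single point has
#' a diagonal of 0.
#'
#' @param x a numeric matrix of 3D positions (nm), a
#'   \linkS4class{TriangleMesh}, or a \linkS4class{SupervoxelGraph}.
#' @param ... unused.
#' @return numeric scalar, micrometers.
#' @export
setGeneric("bbd", function(x, ...) standardGeneric("bbd"))

#' Supervoxel ids
#'
#' @param x a \linkS4class{SupervoxelGraph}.
#' @return character vector of SV identifiers.
#' @export
setGeneric("svIds", function(x) standardGeneric("svIds"))

#' Supervoxel volumes (µm³)
#'
#' @param x a \linkS4class{SupervoxelGraph}.
#' @return named numeric vector.
#' @export
setGeneric("svVolumes", function(x) standardGeneric("svVolumes"))

#' Per-supervoxel labels
#'
#' @param x a \linkS4class{SupervoxelGraph}.
#' @return named integer vector (NA where unlabeled).
#' @export
setGeneric("svLabels", function(x) standardGeneric("svLabels"))

#' @rdname svLabels
#' @param value replacement labels.
#' @export
setGeneric("svLabels<-", function(x, value) standardGeneric("svLabels<-"))

#' Supervoxel meshes
#'
#' @param x a \linkS4class{SupervoxelGraph}.
#' @return named list of \linkS4class{TriangleMesh} objects.
#' @export
setGeneric("svMeshes", function(x) standardGeneric("svMeshes"))

#' Graph edges
#'
#' @param x a \linkS4class{SupervoxelGraph} or \linkS4class{Skeleton}.
#' @return two-column matrix of endpoints.
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' Skeleton nodes, radii, labels
#'
#' @param x a \linkS4class{Skeleton}.
#' @return \code{nodes}: numeric matrix (nm); \code{radii}: numeric vector
#'   (nm); \code{nodeLabels}: integer vector (NA allowed).
#' @export
setGeneric("nodes", function(x) standardGeneric("nodes"))

#' @rdname nodes
#' @export
setGeneric("radii", function(x) standardGeneric("radii"))

#' @rdname nodes
#' @export
setGeneric("nodeLabels", function(x) standardGeneric("nodeLabels"))

#' @rdname nodes
#' @param value replacement labels.
#' @export
setGeneric("nodeLabels<-", function(x, value) standardGeneric("nodeLabels<-"))

#' Total path length of a skeleton (nm)
#'
#' Sum of the Euclidean lengths of all edges.
#'
#' @param x a \linkS4class{Skeleton}.
#' @return numeric scalar (nm).
#' @export
setGeneric("pathLength", function(x) standardGeneric("pathLength"))

#' View array of a ViewSet
#'
#' @param x a \linkS4class{ViewSet}.
#' @return integer array with dimensions (x, y, perspective, channel),
#'   values in 0..255.
#' @export
setGeneric("viewArray", function(x) standardGeneric("viewArray"))
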