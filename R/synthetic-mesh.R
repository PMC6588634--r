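#' @include AllClasses.R geometry-utils.R
NULL

#' GroundTruthBundle: one synthetic cell with full ground truth
#'
#' Holds everything the generators know about a synthetic cell: the surface
#' mesh with per-vertex spine-class labels (1 = neck, 2 = head, 3 = shaft,
#' 4 = other), the skeleton with per-node compartment labels (1 = soma,
#' 2 = axon, 3 = dendrite), the supervoxel decomposition with per-SV
#' neuron/glia labels (0/1), the organelle objects (sparse voxel sets on the
#' configured grid) and any planted merge-error edges.
#'
#' @slot mesh a \linkS4class{TriangleMesh} with vertex labels.
#' @slot skeleton a \linkS4class{Skeleton} with node labels.
#' @slot svGraph a \linkS4class{SupervoxelGraph}.
#' @slot organelles list of organelle objects (see
#'   \code{\link{makeNeuron}}).
#' @slot plantedEdges character matrix of planted merge-error edges.
#' @slot config the \code{\link{synthesisConfig}} used.
#' @export
setClass("GroundTruthBundle",
  representation(mesh = "TriangleMesh", skeleton = "Skeleton",
                 svGraph = "SupervoxelGraph", organelles = "list",
                 plantedEdges = "matrix", config = "list"))

setValidity("GroundTruthBundle", function(object) {
  if (nVertices(object@mesh) && !length(object@mesh@vertexLabels))
    return("mesh vertex labels must cover all vertices")
  n <- nrow(object@skeleton@nodes)
  if (n && length(object@skeleton@nodeLabels) != n)
    return("skeleton node labels must cover all nodes")
  pe <- object@plantedEdges
  if (nrow(pe)) {
    key <- function(m) paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
    if (!all(key(pe) %in% key(object@svGraph@edges)))
      return("planted edges must exist in the SV graph")
  }
  TRUE
})

setMethod("show", "GroundTruthBundle", function(object) {
  cat(sprintf(
    "GroundTruthBundle: %d vertices, %d skeleton nodes, %d SVs, %d organelles\n",
    nVertices(object@mesh), nrow(object@skeleton@nodes),
    length(object@svGraph@ids), length(object@organelles)))
})

## run expr under a fixed seed without disturbing the caller's RNG stream
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

## unit vector perpendicular to v
.anyPerp <- function(v) {
  a <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  p <- a - sum(a * v) * v
  p / sqrt(sum(p^2))
}

## UV sphere mesh; radius/center in nm
.sphereMesh <- function(center, radius, nLat = 8L, nLon = 12L, label = 4L) {
  lat <- seq(0, pi, length.out = nLat + 1L)
  vs <- list(center + c(0, 0, radius))
  for (i in seq_len(nLat - 1L)) {
    th <- lat[i + 1L]
    for (j in seq_len(nLon)) {
      ph <- 2 * pi * (j - 1L) / nLon
      vs[[length(vs) + 1L]] <- center +
        radius * c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
    }
  }
  vs[[length(vs) + 1L]] <- center - c(0, 0, radius)
  V <- do.call(rbind, vs)
  idx <- function(i, j) 1L + (i - 1L) * nLon + ((j - 1L) %% nLon) + 1L
  fs <- list()
  for (j in seq_len(nLon))  # top cap
    fs[[length(fs) + 1L]] <- c(1L, idx(1L, j), idx(1L, j + 1L))
  for (i in seq_len(nLat - 2L)) for (j in seq_len(nLon)) {
    a <- idx(i, j); b <- idx(i, j + 1L)
    c_ <- idx(i + 1L, j); d <- idx(i + 1L, j + 1L)
    fs[[length(fs) + 1L]] <- c(a, c_, b)
    fs[[length(fs) + 1L]] <- c(b, c_, d)
  }
  bot <- nrow(V)
  for (j in seq_len(nLon))  # bottom cap
    fs[[length(fs) + 1L]] <- c(bot, idx(nLat - 1L, j + 1L), idx(nLat - 1L, j))
  TriangleMesh(V, do.call(rbind, fs), rep(as.integer(label), nrow(V)))
}

## ellipsoid mesh: unit sphere scaled by semiAxes (nm) and rotated by R
.ellipsoidMesh <- function(center, semiAxes, R = diag(3), nLat = 6L,
                           nLon = 8L, label = 4L) {
  m <- .sphereMesh(c(0, 0, 0), 1, nLat, nLon, label)
  V <- sweep(m@vertices, 2L, semiAxes, `*`) %*% t(R)
  TriangleMesh(sweep(V, 2L, center, `+`), m@faces, m@vertexLabels)
}

## tube along a polyline of ring centers (k x 3 nm) with per-ring radii;
## rings use parallel-transported normals to avoid twist. Returns mesh plus
## the ring index of every vertex (attr "ring"); ends optionally capped.
.tubeMesh <- function(centers, ringRadii, nSeg = 10L, label = 3L,
                      cap = TRUE) {
  k <- nrow(centers)
  stopifnot(k >= 2L, length(ringRadii) == k)
  tang <- centers[c(2:k, k), , drop = FALSE] - centers[c(1, 1:(k - 1)), , drop = FALSE]
  tang <- tang / sqrt(rowSums(tang^2))
  nrm <- matrix(0, k, 3)
  nrm[1, ] <- .anyPerp(tang[1, ])
  for (i in 2:k) {
    p <- nrm[i - 1, ] - sum(nrm[i - 1, ] * tang[i, ]) * tang[i, ]
    if (sum(p^2) < 1e-12) p <- .anyPerp(tang[i, ])
    nrm[i, ] <- p / sqrt(sum(p^2))
  }
  theta <- 2 * pi * (seq_len(nSeg) - 1L) / nSeg
  vs <- matrix(0, k * nSeg, 3)
  ring <- integer(k * nSeg)
  for (i in seq_len(k)) {
    b <- .cross3(tang[i, ], nrm[i, ])
    circ <- outer(cos(theta), nrm[i, ]) + outer(sin(theta), b)
    vs[(i - 1L) * nSeg + seq_len(nSeg), ] <-
      sweep(circ * ringRadii[i], 2L, centers[i, ], `+`)
    ring[(i - 1L) * nSeg + seq_len(nSeg)] <- i
  }
  fs <- list()
  for (i in seq_len(k - 1L)) for (j in seq_len(nSeg)) {
    a <- (i - 1L) * nSeg + j
    b <- (i - 1L) * nSeg + (j %% nSeg) + 1L
    c_ <- i * nSeg + j
    d <- i * nSeg + (j %% nSeg) + 1L
    fs[[length(fs) + 1L]] <- c(a, c_, b)
    fs[[length(fs) + 1L]] <- c(b, c_, d)
  }
  if (cap) {
    vs <- rbind(vs, centers[1, ], centers[k, ])
    ring <- c(ring, 1L, k)
    s1 <- nrow(vs) - 1L; s2 <- nrow(vs)
    for (j in seq_len(nSeg)) {
      fs[[length(fs) + 1L]] <- c(s1, j, (j %% nSeg) + 1L)
      fs[[length(fs) + 1L]] <- c(s2, (k - 1L) * nSeg + (j %% nSeg) + 1L,
                                 (k - 1L) * nSeg + j)
    }
  }
  m <- TriangleMesh(vs, do.call(rbind, fs), rep(as.integer(label), nrow(vs)))
  attr(m, "ring") <- ring
  m
}

.cross3 <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
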