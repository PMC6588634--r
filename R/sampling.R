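#' @include AllClasses.R geometry-utils.R
NULL

#' Sampling configuration for rendering locations
#'
#' @param gridEdge edge length of the density grid voxels, nm (default
#'   2 µm).
#' @param radius averaging radius around occupied voxel centers, nm
#'   (default 1 µm).
#' @return a list with class \code{"samplingConfig"}.
#' @export
samplingConfig <- function(gridEdge = 2000, radius = 1000) {
  stopifnot(gridEdge > 0, radius > 0)
  structure(list(gridEdge = gridEdge, radius = radius),
            class = "samplingConfig")
}

#' Sample rendering locations that homogeneously probe a cell
#'
#' The mesh's vertex density is evaluated in a grid of voxels (default
#' 2 x 2 x 2 µm³, anchored at the global coordinate origin). For every
#' occupied voxel the location is the mean of all mesh vertices within the
#' averaging radius (default 1 µm) of the voxel center, so dense surface
#' regions are not oversampled. If no vertex lies within the radius of an
#' occupied voxel's center, the mean of the vertices inside that voxel is
#' used instead, guaranteeing one location per occupied voxel. Locations
#' closer than 1 nm are deduplicated.
#'
#' @param mesh a non-empty \linkS4class{TriangleMesh} (or numeric vertex
#'   matrix, nm).
#' @param config a \code{\link{samplingConfig}}.
#' @return numeric matrix (k x 3) of rendering locations in nm, one per
#'   occupied grid voxel (before deduplication).
#' @export
sampleRenderingLocations <- function(mesh, config = samplingConfig()) {
  V <- if (is(mesh, "TriangleMesh")) mesh@vertices else as.matrix(mesh)
  if (!nrow(V)) stop("sampleRenderingLocations: empty mesh")
  g <- config$gridEdge; r <- config$radius
  cell <- floor(V / g)                       # grid voxel of each vertex
  key <- paste(cell[, 1], cell[, 2], cell[, 3])
  occ <- !duplicated(key)
  centers <- (cell[occ, , drop = FALSE] + 0.5) * g
  occKey <- key[occ]
  ## candidate vertices for each center: those in the 27-voxel neighborhood
  ## (radius <= gridEdge/2 guarantees coverage; general case uses the full
  ## vertex set when the radius exceeds the neighborhood)
  useNbr <- r <= 1.5 * g
  locs <- matrix(0, nrow(centers), 3)
  byKey <- split(seq_len(nrow(V)), key)
  for (q in seq_len(nrow(centers))) {
    ctr <- centers[q, ]
    cand <- if (useNbr) {
      base <- cell[match(occKey[q], key), ]
      nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
      keys <- paste(base[1] + nb[, 1], base[2] + nb[, 2], base[3] + nb[, 3])
      unlist(byKey[keys], use.names = FALSE)
    } else seq_len(nrow(V))
    P <- V[cand, , drop = FALSE]
    d2 <- (P[, 1] - ctr[1])^2 + (P[, 2] - ctr[2])^2 + (P[, 3] - ctr[3])^2
    sel <- d2 <= r^2
    locs[q, ] <- if (any(sel)) colMeans(P[sel, , drop = FALSE])
    else colMeans(V[byKey[[occKey[q]]], , drop = FALSE])
  }
  ## deduplicate within 1 nm (keep the first of any close pair)
  keep <- rep(TRUE, nrow(locs))
  for (q in seq_len(nrow(locs))[-1]) {
    prev <- which(keep[seq_len(q - 1L)])
    d2 <- rowSums(sweep(locs[prev, , drop = FALSE], 2L, locs[q, ], `-`)^2)
    if (any(d2 < 1)) keep[q] <- FALSE
  }
  locs[keep, , drop = FALSE]
}

#' Pool rendering locations over the SVs of a cell
#'
#' Locations are computed per SV and pooled, mirroring per-SV storage of
#' rendering locations in large reconstructions.
#'
#' @param graph a \linkS4class{SupervoxelGraph}.
#' @param ids SV subset (default all).
#' @param config a \code{\link{samplingConfig}}.
#' @return numeric matrix of pooled locations (nm).
#' @export
sampleLocationsSSV <- function(graph, ids = svIds(graph),
                               config = samplingConfig()) {
  do.call(rbind, lapply(ids, function(i)
    sampleRenderingLocations(graph@meshes[[i]], config)))
}
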