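#' @include synthetic-neuron.R
NULL

#' Voxelize a closed mesh
#'
#' Parity-count voxelization: for every voxel-row along x, ray crossings
#' with the mesh surface are collected and voxel centers between successive
#' crossing pairs are labeled 1 (inside). The grid is anchored one voxel
#' below the mesh bounding box at whole-voxel coordinates, so translating
#' the mesh by whole voxels leaves the inside count unchanged.
#'
#' @param mesh a watertight (or near-watertight) \linkS4class{TriangleMesh}.
#' @param voxelSize length-3 voxel edges in nm (anisotropy allowed) or a
#'   scalar.
#' @return a \linkS4class{LabeledVolume} (1 = inside, 0 = outside).
#' @examples
#' sph <- cellmorph:::.sphereMesh(c(0, 0, 0), 1000, nLat = 16L, nLon = 24L)
#' v <- voxelize(sph, 100)
#' sum(v@data) * prod(v@voxelSize) / (4 / 3 * pi * 1000^3)  # ~1
#' @export
voxelize <- function(mesh, voxelSize) {
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  stopifnot(all(voxelSize > 0))
  if (nFaces(mesh) == 0L) stop("voxelize: degenerate mesh (no faces)")
  V <- mesh@vertices; F <- mesh@faces
  lo <- apply(V, 2, min); hi <- apply(V, 2, max)
  o <- (floor(lo / voxelSize) - 1) * voxelSize
  d <- pmax(1L, as.integer(ceiling((hi - o) / voxelSize) + 1L))
  s <- voxelSize
  ## ray centers in y, z; tiny irrational offset avoids edge-on hits
  eps <- c(0, s[2] * 1.23456789e-7, s[3] * 2.3456789e-7)
  yc <- o[2] + (seq_len(d[2]) - 0.5) * s[2] + eps[2]
  zc <- o[3] + (seq_len(d[3]) - 0.5) * s[3] + eps[3]
  rayI <- vector("list", nrow(F)); rayX <- vector("list", nrow(F))
  for (f in seq_len(nrow(F))) {
    tri <- V[F[f, ], , drop = FALSE]
    jr <- range(tri[, 2]); kr <- range(tri[, 3])
    js <- which(yc >= jr[1] & yc <= jr[2])
    ks <- which(zc >= kr[1] & zc <= kr[2])
    if (!length(js) || !length(ks)) next
    py <- rep(yc[js], times = length(ks))
    pz <- rep(zc[ks], each = length(js))
    ## barycentric in the (y, z) projection
    v0 <- tri[2, 2:3] - tri[1, 2:3]; v1 <- tri[3, 2:3] - tri[1, 2:3]
    den <- v0[1] * v1[2] - v1[1] * v0[2]
    if (abs(den) < 1e-12) next
    wy <- py - tri[1, 2]; wz <- pz - tri[1, 3]
    a <- (wy * v1[2] - v1[1] * wz) / den
    b <- (v0[1] * wz - wy * v0[2]) / den
    inside <- a >= 0 & b >= 0 & (a + b) <= 1
    if (!any(inside)) next
    xi <- tri[1, 1] + a[inside] * (tri[2, 1] - tri[1, 1]) +
      b[inside] * (tri[3, 1] - tri[1, 1])
    jj <- js[((which(inside) - 1L) %% length(js)) + 1L]
    kk <- ks[((which(inside) - 1L) %/% length(js)) + 1L]
    rayI[[f]] <- jj + (kk - 1L) * d[2]
    rayX[[f]] <- xi
  }
  ray <- unlist(rayI); xs <- unlist(rayX)
  arr <- array(0L, dim = d)
  if (length(ray)) {
    xc0 <- o[1] + 0.5 * s[1]
    ord <- order(ray, xs)
    ray <- ray[ord]; xs <- xs[ord]
    bounds <- c(which(diff(ray) > 0), length(ray))
    start <- c(1L, head(bounds, -1L) + 1L)
    for (q in seq_along(bounds)) {
      rx <- xs[start[q]:bounds[q]]
      r <- ray[start[q]]
      j <- ((r - 1L) %% d[2]) + 1L
      k <- ((r - 1L) %/% d[2]) + 1L
      np <- length(rx) %/% 2L
      for (p in seq_len(np)) {
        aX <- rx[2L * p - 1L]; bX <- rx[2L * p]
        i0 <- ceiling((aX - xc0) / s[1] + 1e-12) + 1L
        i1 <- floor((bX - xc0) / s[1] - 1e-12) + 1L
        if (i1 >= i0)
          arr[i0:i1, j, k] <- 1L
      }
    }
  }
  LabeledVolume(arr, voxelSize = s, offset = o)
}

## voxel indices (global grid anchored at 0) whose centers fall inside the
## rotated ellipsoid
.ellipsoidVoxels <- function(center, semiAxes, R, voxelSize) {
  s <- voxelSize
  rad <- max(semiAxes)
  lo <- floor((center - rad) / s); hi <- ceiling((center + rad) / s)
  ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
  ctr <- as.matrix(expand.grid(i = ii, j = jj, k = kk))
  p <- sweep((ctr + 0.5) %*% diag(s), 2L, center, `-`)
  q <- p %*% R                       # into ellipsoid frame (R columns = axes)
  keep <- rowSums(sweep(q, 2L, semiAxes, `/`)^2) <= 1
  m <- ctr[keep, , drop = FALSE]
  storage.mode(m) <- "integer"
  dimnames(m) <- NULL
  m
}

#' Rasterize organelle objects into a dense class volume
#'
#' Builds a binary \linkS4class{LabeledVolume} over the joint bounding box
#' of the given objects' voxel sets (which live on the global grid anchored
#' at the origin with the generator's voxel size).
#'
#' @param objects list of organelle objects (see \code{\link{makeNeuron}}).
#' @param voxelSize length-3 nm voxel size of the objects' grid.
#' @param class optional class filter ("MI", "SJ" or "VC").
#' @return a \linkS4class{LabeledVolume} (1 = object voxel), or NULL when no
#'   object matches.
#' @export
rasterizeObjects <- function(objects, voxelSize, class = NULL) {
  if (!is.null(class))
    objects <- Filter(function(o) o$class == class, objects)
  if (!length(objects)) return(NULL)
  vox <- do.call(rbind, lapply(objects, `[[`, "voxels"))
  lo <- apply(vox, 2, min); hi <- apply(vox, 2, max)
  d <- hi - lo + 1L
  arr <- array(0L, dim = d)
  idx <- (vox[, 1] - lo[1] + 1L) +
    (vox[, 2] - lo[2]) * d[1] +
    (vox[, 3] - lo[3]) * d[1] * d[2]
  arr[idx] <- 1L
  LabeledVolume(arr, voxelSize = voxelSize, offset = lo * voxelSize)
}
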