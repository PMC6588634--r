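#' @include AllClasses.R synthetic-voxel.R
NULL

#' Organelle-to-cell mapping thresholds
#'
#' Candidate organelle objects are mapped to a cell when their relative
#' voxel overlap with the cell satisfies the class rule and their voxel
#' count reaches the class minimum. Defaults: mitochondria (MI) and vesicle
#' clouds (VC) require overlap > 0.5; synaptic junctions (SJ), which are
#' shared between two cells, require overlap within [0.2, 0.8] (closed
#' interval). Minimum sizes: SJ 498, VC 1584, MI 2786 voxels.
#'
#' @param miMin,vcMin strict lower overlap bounds for MI / VC.
#' @param sjRange inclusive overlap interval for SJ.
#' @param minSize named integer vector of minimum voxel counts.
#' @return a list with class \code{"mappingThresholds"}.
#' @export
mappingThresholds <- function(miMin = 0.5, vcMin = 0.5,
                              sjRange = c(0.2, 0.8),
                              minSize = c(SJ = 498L, VC = 1584L,
                                          MI = 2786L)) {
  stopifnot(miMin >= 0, miMin <= 1, vcMin >= 0, vcMin <= 1,
            all(sjRange >= 0), all(sjRange <= 1), all(minSize > 0))
  structure(list(miMin = miMin, vcMin = vcMin, sjRange = sjRange,
                 minSize = minSize),
            class = "mappingThresholds")
}

#' Map organelle objects to a cell by relative overlap
#'
#' The overlap fraction of an object is |object voxels inside the cell
#' mask| / |object voxels| (object-normalized). An object is mapped iff its
#' size reaches the class minimum and the fraction satisfies the class rule
#' (MI/VC: strictly above the bound; SJ: inside the closed interval).
#'
#' @param objects list of organelle objects, each a list with fields
#'   \code{class} ("MI"/"SJ"/"VC") and \code{voxels} (integer matrix of
#'   global grid coordinates on the mask's grid).
#' @param cellMask a \linkS4class{LabeledVolume} (nonzero = cell); its
#'   offset must be a whole number of voxels.
#' @param thresholds a \code{\link{mappingThresholds}}.
#' @return data.frame with one row per object: \code{id}, \code{class},
#'   \code{size}, \code{overlap} (reported to 1e-6), \code{mapped}.
#' @export
mapObjects <- function(objects, cellMask,
                       thresholds = mappingThresholds()) {
  stopifnot(is(cellMask, "LabeledVolume"))
  s <- cellMask@voxelSize
  o <- cellMask@offset / s
  if (max(abs(o - round(o))) > 1e-6)
    stop("mapObjects: cell mask grid mismatch (offset not a whole voxel)")
  o <- round(o)
  d <- dim(cellMask@data)
  rows <- lapply(seq_along(objects), function(i) {
    ob <- objects[[i]]
    vx <- ob$voxels
    if (!is.null(ob$voxelSize) && max(abs(ob$voxelSize - s)) > 1e-9)
      stop("mapObjects: object ", i, " voxel size mismatch")
    n <- nrow(vx)
    if (n == 0L) stop("mapObjects: object ", i, " has no voxels")
    li <- vx[, 1] - o[1] + 1L; lj <- vx[, 2] - o[2] + 1L
    lk <- vx[, 3] - o[3] + 1L
    inb <- li >= 1L & li <= d[1] & lj >= 1L & lj <= d[2] &
           lk >= 1L & lk <= d[3]
    hit <- logical(n)
    if (any(inb))
      hit[inb] <- cellMask@data[cbind(li[inb], lj[inb], lk[inb])] != 0L
    frac <- sum(hit) / n
    ok <- switch(ob$class,
                 MI = frac > thresholds$miMin,
                 VC = frac > thresholds$vcMin,
                 SJ = frac >= thresholds$sjRange[1] &&
                      frac <= thresholds$sjRange[2],
                 stop("mapObjects: unknown class ", ob$class))
    mapped <- ok && n >= thresholds$minSize[[ob$class]]
    data.frame(id = i, class = ob$class, size = n,
               overlap = round(frac, 6L), mapped = mapped)
  })
  do.call(rbind, rows)
}

## ---- signed distance field + isosurface -----------------------------------

## 1D squared distance transform (Felzenszwalb & Huttenlocher), spacing s
.dt1d <- function(f, s) {
  n <- length(f)
  src <- which(is.finite(f))
  if (!length(src)) return(f)
  x <- seq_len(n) * s
  v <- integer(length(src)); z <- numeric(length(src) + 1L)
  k <- 1L; v[1] <- src[1]; z[1] <- -Inf; z[2] <- Inf
  for (q in src[-1]) {
    repeat {
      p <- v[k]
      si <- ((f[q] + x[q]^2) - (f[p] + x[p]^2)) / (2 * (x[q] - x[p]))
      if (k > 1L && si <= z[k]) k <- k - 1L else break
    }
    k <- k + 1L; v[k] <- q; z[k] <- si; z[k + 1L] <- Inf
  }
  d <- numeric(n); k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1L] < x[q]) k <- k + 1L
    d[q] <- (x[q] - x[v[k]])^2 + f[v[k]]
  }
  d
}

## squared Euclidean distance (nm^2) of every voxel to the nearest TRUE
## voxel center, with anisotropic spacing (nm)
.edt2 <- function(fg, spacing) {
  d <- dim(fg)
  D <- array(ifelse(fg, 0, Inf), dim = d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2]))
    D[, j, k] <- .dt1d(D[, j, k], spacing[1])
  for (k in seq_len(d[3])) for (i in seq_len(d[1]))
    D[i, , k] <- .dt1d(D[i, , k], spacing[2])
  for (j in seq_len(d[2])) for (i in seq_len(d[1]))
    D[i, j, ] <- .dt1d(D[i, j, ], spacing[3])
  D
}

## separable Gaussian smoothing, sigma in voxels
.gauss3 <- function(A, sigma = 1) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2)); k <- k / sum(k)
  d <- dim(A)
  pad <- function(v) c(rep(v[1], r), v, rep(v[length(v)], r))
  sm <- function(v) stats::filter(pad(v), k, sides = 2)[(r + 1L):(r + length(v))]
  for (kk in seq_len(d[3])) for (j in seq_len(d[2])) A[, j, kk] <- sm(A[, j, kk])
  for (kk in seq_len(d[3])) for (i in seq_len(d[1])) A[i, , kk] <- sm(A[i, , kk])
  for (j in seq_len(d[2])) for (i in seq_len(d[1])) A[i, j, ] <- sm(A[i, j, ])
  A
}

#' Extract a closed surface mesh from a binary mask
#'
#' The binary mask is converted to a signed distance field (positive
#' inside, anisotropic voxel size respected), Gaussian smoothed with
#' sigma = 1 voxel, and the zero level set is extracted with a
#' marching-tetrahedra isosurface (6 tetrahedra per cube, linear edge
#' interpolation). Vertices are returned in nm (grid offset applied).
#'
#' @param mask a \linkS4class{LabeledVolume}; nonzero voxels are inside.
#' @param sigma Gaussian smoothing width in voxels.
#' @return a closed \linkS4class{TriangleMesh}.
#' @export
objectMesh <- function(mask, sigma = 1) {
  stopifnot(is(mask, "LabeledVolume"))
  fg <- mask@data != 0L
  if (!any(fg)) stop("objectMesh: empty mask")
  ## pad with outside so the surface closes at the boundary
  d0 <- dim(fg)
  p <- 2L
  fgp <- array(FALSE, d0 + 2L * p)
  fgp[p + seq_len(d0[1]), p + seq_len(d0[2]), p + seq_len(d0[3])] <- fg
  s <- mask@voxelSize
  din <- .edt2(!fgp, s)   # distance to nearest outside voxel (inside depth)
  dout <- .edt2(fgp, s)   # distance to nearest inside voxel
  f <- sqrt(din) - sqrt(dout)          # signed: positive inside
  fs <- .gauss3(f, sigma)
  ## tiny objects can be smoothed below the contour; keep them meshable
  if (!any(fs > 0)) fs <- f
  tris <- .marchingTetrahedra(fs, s)
  if (!nrow(tris)) stop("objectMesh: no surface found")
  ## positions: voxel centers; account for padding and grid offset
  shift <- mask@offset - (p + 0.5) * s
  P <- sweep(tris, 2L, shift, `+`)
  ## weld vertices shared between triangles
  keyP <- paste(round(P[, 1], 3), round(P[, 2], 3), round(P[, 3], 3))
  uk <- !duplicated(keyP)
  vmap <- match(keyP, keyP[uk])
  Vm <- P[uk, , drop = FALSE]
  Fm <- matrix(vmap, ncol = 3L, byrow = TRUE)
  Fm <- Fm[Fm[, 1] != Fm[, 2] & Fm[, 2] != Fm[, 3] & Fm[, 1] != Fm[, 3], ,
           drop = FALSE]
  TriangleMesh(Vm, Fm)
}

## marching tetrahedra on scalar field A (> 0 inside); returns a matrix of
## triangle corner positions in voxel units (3 rows per triangle)
.marchingTetrahedra <- function(A, s) {
  d <- dim(A)
  ## cubes with a sign change among their 8 corners
  sub <- function(di, dj, dk)
    A[di + seq_len(d[1] - 1L), dj + seq_len(d[2] - 1L),
      dk + seq_len(d[3] - 1L)]
  mx <- mn <- sub(0L, 0L, 0L)
  for (off in list(c(1L,0L,0L), c(0L,1L,0L), c(1L,1L,0L), c(0L,0L,1L),
                   c(1L,0L,1L), c(0L,1L,1L), c(1L,1L,1L))) {
    B <- sub(off[1], off[2], off[3])
    mx <- pmax(mx, B); mn <- pmin(mn, B)
  }
  act <- which(mx > 0 & mn <= 0, arr.ind = TRUE)
  if (!nrow(act)) return(matrix(numeric(0), 0, 3))
  corner <- rbind(c(0,0,0), c(1,0,0), c(1,1,0), c(0,1,0),
                  c(0,0,1), c(1,0,1), c(1,1,1), c(0,1,1))
  tets <- rbind(c(1,2,3,7), c(1,3,4,7), c(1,4,8,7),
                c(1,8,5,7), c(1,5,6,7), c(1,6,2,7))
  out <- vector("list", nrow(act))
  interp <- function(pa, pb, va, vb) pa + (va / (va - vb)) * (pb - pa)
  for (q in seq_len(nrow(act))) {
    base <- as.numeric(act[q, ])
    pos <- sweep(corner, 2L, base, `+`)
    val <- A[cbind(pos[, 1], pos[, 2], pos[, 3])]
    posNm <- sweep(pos, 2L, s, `*`)
    triList <- list()
    for (t in seq_len(6L)) {
      vt <- val[tets[t, ]]; pt <- posNm[tets[t, ], , drop = FALSE]
      inside <- vt > 0
      ni <- sum(inside)
      if (ni == 0L || ni == 4L) next
      iIn <- which(inside); iOut <- which(!inside)
      ## orient every triangle with its normal pointing outside (away from
      ## the positive corners) so downstream signed volumes are consistent
      insideCentroid <- colMeans(pt[iIn, , drop = FALSE])
      orient <- function(tri) {
        nrm <- .cross3(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])
        if (sum(nrm * (colMeans(tri) - insideCentroid)) < 0)
          tri[c(1, 3, 2), ] else tri
      }
      if (ni == 1L || ni == 3L) {
        a <- if (ni == 1L) iIn else iOut
        others <- setdiff(1:4, a)
        tri <- do.call(rbind, lapply(others, function(b)
          interp(pt[a, ], pt[b, ], vt[a], vt[b])))
        triList[[length(triList) + 1L]] <- orient(tri)
      } else {
        e <- list(c(iIn[1], iOut[1]), c(iIn[1], iOut[2]),
                  c(iIn[2], iOut[2]), c(iIn[2], iOut[1]))
        pq <- do.call(rbind, lapply(e, function(ab)
          interp(pt[ab[1], ], pt[ab[2], ], vt[ab[1]], vt[ab[2]])))
        triList[[length(triList) + 1L]] <- orient(pq[c(1, 2, 3), ])
        triList[[length(triList) + 1L]] <- orient(pq[c(1, 3, 4), ])
      }
    }
    out[[q]] <- do.call(rbind, triList)
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Enclosed volume of a closed mesh
#'
#' Signed-tetrahedron (divergence) volume; orientation-independent absolute
#' value, reported in µm³.
#'
#' @param mesh a closed \linkS4class{TriangleMesh}.
#' @return numeric scalar (µm³).
#' @export
meshVolume <- function(mesh) {
  V <- mesh@vertices; F <- mesh@faces
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c_ <- V[F[, 3], , drop = FALSE]
  det6 <- a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
          a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
          a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  abs(sum(det6)) / 6 / 1e9
}
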