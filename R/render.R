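#' @include AllClasses.R geometry-utils.R
NULL

#' Rendering configuration
#'
#' Orthographic multi-view rendering parameters. The clip extent is given in
#' µm as (x, y, z) of the local frame; the default 8 x 4 x 4 µm³ with a
#' 256 x 128 pixel image yields a 31.25 nm pixel pitch. Perspective k
#' (k = 0, 1, ...) is the frame rotated about its first principal component
#' by k * phi degrees; the camera looks along the rotated -z axis.
#'
#' @param extent clip extent in µm, length 3 (default \code{c(8, 4, 4)};
#'   triplet-embedding rendering uses \code{c(8, 4, 8)}).
#' @param resolution image size in pixels, (x, y).
#' @param phi rotation angle between perspectives, degrees (default 90;
#'   triplet training uses 50).
#' @param nPersp number of perspectives (2 default; 5 for surface
#'   segmentation training). For nPersp > 2 the angles are
#'   k * (180 / nPersp) degrees.
#' @param pcaFraction fraction of clipped vertices used for the local PCA
#'   (every \code{1/pcaFraction}-th vertex by index).
#' @param channels channel names rendered, subset of
#'   \code{c("cell", "mi", "sj", "vc")}.
#' @return a list with class \code{"renderConfig"}.
#' @export
renderConfig <- function(extent = c(8, 4, 4), resolution = c(256L, 128L),
                         phi = 90, nPersp = 2L, pcaFraction = 0.125,
                         channels = "cell") {
  stopifnot(length(extent) == 3L, all(extent > 0), length(resolution) == 2L,
            all(resolution > 0), nPersp >= 1L, pcaFraction > 0,
            pcaFraction <= 1)
  structure(list(extent = extent, resolution = as.integer(resolution),
                 phi = phi, nPersp = as.integer(nPersp),
                 pcaFraction = pcaFraction, channels = channels),
            class = "renderConfig")
}

## perspective angles in degrees: k * phi for the 2-view default, evenly
## spread over 180 degrees for more perspectives
.perspAngles <- function(config) {
  if (config$nPersp <= 2L) (seq_len(config$nPersp) - 1L) * config$phi
  else (seq_len(config$nPersp) - 1L) * (180 / config$nPersp)
}

#' Local PCA frame at a rendering location
#'
#' Principal-component frame of the vertex subset around \code{location}:
#' the x axis is the first principal component (highest variance), y the
#' second, z the third. A deterministic subset (every
#' \code{1/pcaFraction}-th vertex by index) of the vertices within the clip
#' region (infinity-norm radius \code{max(extent)/2}) enters the PCA. Each
#' axis is flipped so that its largest-magnitude component is positive
#' (ties toward the lower component index), and the z axis is replaced by
#' x cross y so the frame is right-handed. With fewer than 3 usable
#' vertices or a rank-deficient covariance the frame is flagged degenerate
#' and global axes are used.
#'
#' @param mesh a \linkS4class{TriangleMesh} (or vertex matrix, nm).
#' @param location length-3 rendering location (nm).
#' @param config a \code{\link{renderConfig}}.
#' @return a \linkS4class{LocalFrame}.
#' @export
localFrame <- function(mesh, location, config = renderConfig()) {
  V <- if (is(mesh, "TriangleMesh")) mesh@vertices else as.matrix(mesh)
  location <- as.numeric(location)
  half <- max(config$extent) * 1e3 / 2
  sel <- abs(V[, 1] - location[1]) <= half &
         abs(V[, 2] - location[2]) <= half &
         abs(V[, 3] - location[3]) <= half
  P <- V[sel, , drop = FALSE]
  stride <- max(1L, round(1 / config$pcaFraction))
  P <- P[seq(1L, nrow(P), by = stride), , drop = FALSE]
  degen <- FALSE
  axesM <- diag(3)
  if (nrow(P) >= 3L) {
    cv <- stats::cov(P)
    eg <- eigen(cv, symmetric = TRUE)
    ## rank/tie check: collapse to global axes when variance is gone or the
    ## point cloud is isotropic to numerical precision
    if (eg$values[1] <= 1e-12 ||
        (eg$values[1] - eg$values[3]) / eg$values[1] < 0.02) {
      degen <- TRUE
    } else {
      A <- eg$vectors
      for (j in 1:2) {
        v <- A[, j]
        i0 <- which.max(abs(v) - 1e-15 * seq_along(v))  # ties: lower index
        if (v[i0] < 0) A[, j] <- -v
      }
      A[, 3] <- .cross3(A[, 1], A[, 2])
      axesM <- A
    }
  } else degen <- TRUE
  new("LocalFrame", origin = location, axes = axesM, degenerate = degen)
}

## axes of perspective k: frame rotated about its x axis by angle (deg)
.perspAxes <- function(frame, angleDeg) {
  R <- .rotationAboutAxis(frame@axes[, 1], angleDeg * pi / 180)
  A <- frame@axes
  cbind(A[, 1], R %*% A[, 2], R %*% A[, 3])
}

## Rasterize triangles in camera coordinates.
## Vloc: vertices in the perspective frame (x right, y up, z toward camera);
## visible depth range is [-ez/2, ez/2], camera at +z looking along -z.
## Returns depth (nx x ny, -Inf = background) and 0-based face ids (-1L).
.rasterize <- function(Vloc, F, nx, ny, ext) {
  ex <- ext[1]; ey <- ext[2]; ez <- ext[3]
  px <- -ex / 2 + (seq_len(nx) - 0.5) * ex / nx
  py <- -ey / 2 + (seq_len(ny) - 0.5) * ey / ny
  zbuf <- matrix(-Inf, nx, ny)
  fbuf <- matrix(-1L, nx, ny)
  if (!nrow(F)) return(list(depth = zbuf, face = fbuf))
  x1 <- Vloc[F[, 1], 1]; y1 <- Vloc[F[, 1], 2]; z1 <- Vloc[F[, 1], 3]
  x2 <- Vloc[F[, 2], 1]; y2 <- Vloc[F[, 2], 2]; z2 <- Vloc[F[, 2], 3]
  x3 <- Vloc[F[, 3], 1]; y3 <- Vloc[F[, 3], 2]; z3 <- Vloc[F[, 3], 3]
  den <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
  xmin <- pmin(x1, x2, x3); xmax <- pmax(x1, x2, x3)
  ymin <- pmin(y1, y2, y3); ymax <- pmax(y1, y2, y3)
  zmax <- pmax(z1, z2, z3); zmin <- pmin(z1, z2, z3)
  keep <- which(abs(den) > 1e-12 & xmax >= px[1] & xmin <= px[nx] &
                ymax >= py[1] & ymin <= py[ny] &
                zmax >= -ez / 2 & zmin <= ez / 2)
  sx <- nx / ex
  for (f in keep) {
    i0 <- max(1L, ceiling((xmin[f] + ex / 2) * sx + 0.5 - 1))
    i1 <- min(nx, floor((xmax[f] + ex / 2) * sx + 0.5))
    j0 <- max(1L, ceiling((ymin[f] + ey / 2) * (ny / ey) + 0.5 - 1))
    j1 <- min(ny, floor((ymax[f] + ey / 2) * (ny / ey) + 0.5))
    if (i1 < i0 || j1 < j0) next
    gx <- px[i0:i1] - x3[f]; gy <- py[j0:j1] - y3[f]
    d <- den[f]
    ## barycentric coordinates (affine in pixel position)
    a <- (outer(gx * (y2[f] - y3[f]), gy * (x3[f] - x2[f]), `+`)) / d
    b <- (outer(gx * (y3[f] - y1[f]), gy * (x1[f] - x3[f]), `+`)) / d
    cc <- 1 - a - b
    z <- a * z1[f] + b * z2[f] + cc * z3[f]
    ins <- a >= 0 & b >= 0 & cc >= 0 & z >= -ez / 2 & z <= ez / 2
    if (!any(ins)) next
    sub <- zbuf[i0:i1, j0:j1, drop = FALSE]
    upd <- ins & z > sub
    if (any(upd)) {
      sub[upd] <- z[upd]
      zbuf[i0:i1, j0:j1] <- sub
      fsub <- fbuf[i0:i1, j0:j1, drop = FALSE]
      fsub[upd] <- f - 1L
      fbuf[i0:i1, j0:j1] <- fsub
    }
  }
  list(depth = zbuf, face = fbuf)
}

## 8-bit depth encoding: background 0, near clip 255, far clip 1, linear,
## rounded half-up
.encodeDepth <- function(depth, ez) {
  img <- matrix(0L, nrow(depth), ncol(depth))
  cov <- is.finite(depth)
  img[cov] <- as.integer(floor(1 + 254 * (depth[cov] + ez / 2) / ez + 0.5))
  img
}

#' Render multi-channel orthographic depth-map views
#'
#' Renders each scene channel as an orthographic, z-buffered 8-bit depth map
#' over the clip box of \code{config}, from \code{config$nPersp}
#' perspectives (perspective k = frame rotated about its first principal
#' component by k * phi degrees). All channels share the camera of the cell
#' channel. Depth encoding: background 0, near clip 255, far clip 1,
#' linear in between.
#'
#' @param scene a named list of \linkS4class{TriangleMesh} objects, one per
#'   channel (e.g. \code{list(cell = m, mi = mito)}); empty channels give
#'   all-zero images.
#' @param frame a \linkS4class{LocalFrame} from \code{\link{localFrame}}.
#' @param config a \code{\link{renderConfig}}.
#' @return a \linkS4class{ViewSet} with dimensions (x, y, persp, channel).
#' @export
renderViews <- function(scene, frame, config = renderConfig()) {
  if (is(scene, "TriangleMesh")) scene <- list(cell = scene)
  chn <- names(scene)
  stopifnot(!is.null(chn), all(nzchar(chn)))
  nx <- config$resolution[1]; ny <- config$resolution[2]
  ext <- config$extent * 1e3
  ang <- .perspAngles(config)
  arr <- array(0L, dim = c(nx, ny, length(ang), length(scene)))
  for (k in seq_along(ang)) {
    A <- .perspAxes(frame, ang[k])
    for (ci in seq_along(scene)) {
      m <- scene[[ci]]
      if (is.null(m) || nVertices(m) == 0L) next
      Vloc <- sweep(m@vertices, 2L, frame@origin, `-`) %*% A
      r <- .rasterize(Vloc, m@faces, nx, ny, ext)
      arr[, , k, ci] <- .encodeDepth(r$depth, ext[3])
    }
  }
  new("ViewSet", data = arr, location = frame@origin, channels = chn)
}

#' Render face-identity maps
#'
#' Same camera as \code{\link{renderViews}}, but every pixel stores the
#' 0-based index of the nearest intersecting face (z-buffer semantics);
#' background is -1. Exported images encode the id in 24-bit little-endian
#' RGB (see \code{\link{faceIdToRGB}}).
#'
#' @param mesh a \linkS4class{TriangleMesh}.
#' @param frame a \linkS4class{LocalFrame}.
#' @param config a \code{\link{renderConfig}}.
#' @return a list with one integer matrix (nx x ny) per perspective.
#' @export
renderFaceIds <- function(mesh, frame, config = renderConfig()) {
  nx <- config$resolution[1]; ny <- config$resolution[2]
  ext <- config$extent * 1e3
  lapply(.perspAngles(config), function(angle) {
    A <- .perspAxes(frame, angle)
    Vloc <- sweep(mesh@vertices, 2L, frame@origin, `-`) %*% A
    .rasterize(Vloc, mesh@faces, nx, ny, ext)$face
  })
}

#' Encode / decode face ids as 24-bit RGB
#'
#' Face id i (0-based) maps to (R, G, B) = (i mod 256, (i / 256) mod 256,
#' i / 65536) with the background reserved color (255, 255, 255).
#'
#' @param ids integer matrix from \code{\link{renderFaceIds}}.
#' @return \code{faceIdToRGB}: an (nx x ny x 3) integer array;
#'   \code{rgbToFaceId}: the integer id matrix.
#' @export
faceIdToRGB <- function(ids) {
  arr <- array(255L, dim = c(dim(ids), 3L))
  fg <- ids >= 0L
  arr[, , 1][fg] <- ids[fg] %% 256L
  arr[, , 2][fg] <- (ids[fg] %/% 256L) %% 256L
  arr[, , 3][fg] <- ids[fg] %/% 65536L
  arr
}

#' @rdname faceIdToRGB
#' @param rgb an (nx x ny x 3) integer array.
#' @export
rgbToFaceId <- function(rgb) {
  ids <- rgb[, , 1] + 256L * rgb[, , 2] + 65536L * rgb[, , 3]
  ids[rgb[, , 1] == 255L & rgb[, , 2] == 255L & rgb[, , 3] == 255L] <- -1L
  ids
}

#' Mask foreground pixels not connected to the central object
#'
#' 2D connected-component masking of an 8-bit view: only the 8-connected
#' foreground component containing the foreground pixel nearest the image
#' center is kept; all other foreground pixels are set to 0. An image
#' without foreground is returned unchanged.
#'
#' @param img integer matrix (8-bit view).
#' @return the masked image.
#' @export
maskUnconnected2D <- function(img) {
  fg <- img > 0L
  if (!any(fg)) return(img)
  nx <- nrow(img); ny <- ncol(img)
  ctr <- c((nx + 1) / 2, (ny + 1) / 2)
  w <- which(fg, arr.ind = TRUE)
  d2 <- (w[, 1] - ctr[1])^2 + (w[, 2] - ctr[2])^2
  seed <- w[which.min(d2), ]
  ## vectorized 8-connected flood fill by repeated dilation within fg
  comp <- matrix(FALSE, nx, ny)
  comp[seed[1], seed[2]] <- TRUE
  repeat {
    grown <- comp
    grown[-1, ] <- grown[-1, ] | comp[-nx, ]
    grown[-nx, ] <- grown[-nx, ] | comp[-1, ]
    grown[, -1] <- grown[, -1] | comp[, -ny]
    grown[, -ny] <- grown[, -ny] | comp[, -1]
    grown[-1, -1] <- grown[-1, -1] | comp[-nx, -ny]
    grown[-nx, -ny] <- grown[-nx, -ny] | comp[-1, -1]
    grown[-1, -ny] <- grown[-1, -ny] | comp[-nx, -1]
    grown[-nx, -1] <- grown[-nx, -1] | comp[-1, -ny]
    grown <- grown & fg
    if (all(grown == comp)) break
    comp <- grown
  }
  img[!comp] <- 0L
  img
}
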