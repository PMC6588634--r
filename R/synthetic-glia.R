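#' @include synthetic-neuron.R
NULL

#' Generate a synthetic glia fragment
#'
#' Builds an irregular, undulating sheet-like mesh (astrocyte-like
#' morphology) with optional thin filopodial processes; distinguishable from
#' the tubular neurites of \code{\link{makeNeuron}} by its surface
#' statistics. The sheet is cut into strip supervoxels labeled glia (1).
#'
#' @param config a \code{\link{synthesisConfig}}; the \code{glia*} fields
#'   control sheet count, extent (µm), undulation amplitude (µm), thickness
#'   (nm) and filopodium count.
#' @return a \linkS4class{GroundTruthBundle} with SV ids \code{g1, g2, ...}
#'   and all SV labels 1 (glia).
#' @export
makeGliaFragment <- function(config = synthesisConfig()) {
  stopifnot(inherits(config, "synthesisConfig"))
  .withSeed(config$seed + 77L, .makeGliaImpl(config))
}

.makeGliaImpl <- function(config) {
  um <- 1e3
  spacing <- 500
  svMesh <- list(); svVol <- numeric(0); svLoc <- list(); svEdge <- list()
  skNodes <- list(); skRad <- numeric(0); skEdge <- list()
  svN <- 0L
  for (sheet in seq_len(max(1L, config$gliaSheetCount))) {
    w <- config$gliaSheetSize[1] * um; h <- config$gliaSheetSize[2] * um
    nx <- max(2L, round(w / spacing) + 1L)
    ny <- max(2L, round(h / spacing) + 1L)
    xs <- seq(0, w, length.out = nx); ys <- seq(0, h, length.out = ny)
    ## random smooth undulation: sum of two sinusoids with random phase
    p1 <- stats::runif(1, 2.5, 6) * um; p2 <- stats::runif(1, 2.5, 6) * um
    f1 <- stats::runif(1, 0, 2 * pi); f2 <- stats::runif(1, 0, 2 * pi)
    amp <- config$gliaUndulation * um
    zmid <- outer(xs, ys, function(x, y)
      amp * 0.5 * (sin(2 * pi * x / p1 + f1) + sin(2 * pi * y / p2 + f2)))
    zoff <- (sheet - 1L) * 3 * um
    th <- config$gliaThickness
    nV <- nx * ny
    vid <- function(i, j, top) (if (top) 0L else nV) + (j - 1L) * nx + i
    V <- matrix(0, 2L * nV, 3)
    for (j in seq_len(ny)) for (i in seq_len(nx)) {
      V[vid(i, j, TRUE), ] <- c(xs[i], ys[j], zmid[i, j] + th / 2 + zoff)
      V[vid(i, j, FALSE), ] <- c(xs[i], ys[j], zmid[i, j] - th / 2 + zoff)
    }
    fs <- list()
    for (j in seq_len(ny - 1L)) for (i in seq_len(nx - 1L)) {
      a <- vid(i, j, TRUE); b <- vid(i + 1L, j, TRUE)
      c_ <- vid(i, j + 1L, TRUE); d <- vid(i + 1L, j + 1L, TRUE)
      fs[[length(fs) + 1L]] <- c(a, b, c_)
      fs[[length(fs) + 1L]] <- c(b, d, c_)
      a2 <- vid(i, j, FALSE); b2 <- vid(i + 1L, j, FALSE)
      c2 <- vid(i, j + 1L, FALSE); d2 <- vid(i + 1L, j + 1L, FALSE)
      fs[[length(fs) + 1L]] <- c(a2, c2, b2)
      fs[[length(fs) + 1L]] <- c(b2, c2, d2)
    }
    rim <- function(a, b) {  # two triangles between top edge (a,b) and bottom
      fs[[length(fs) + 1L]] <<- c(a, a + nV, b)
      fs[[length(fs) + 1L]] <<- c(b, a + nV, b + nV)
    }
    for (i in seq_len(nx - 1L)) {
      rim(vid(i, 1L, TRUE), vid(i + 1L, 1L, TRUE))
      rim(vid(i + 1L, ny, TRUE), vid(i, ny, TRUE))
    }
    for (j in seq_len(ny - 1L)) {
      rim(vid(1L, j + 1L, TRUE), vid(1L, j, TRUE))
      rim(vid(nx, j, TRUE), vid(nx, j + 1L, TRUE))
    }
    sheetMesh <- TriangleMesh(V, do.call(rbind, fs),
                              rep(SURFACE_OTHER, nrow(V)))
    ## filopodia from random boundary points, outward in the xy plane
    filos <- list()
    for (f in seq_len(config$gliaFilopodia)) {
      side <- sample(4L, 1L)
      t0 <- stats::runif(1)
      base <- switch(side,
                     c(t0 * w, 0, 0), c(t0 * w, h, 0),
                     c(0, t0 * h, 0), c(w, t0 * h, 0))
      dirx <- switch(side, c(0, -1, 0), c(0, 1, 0), c(-1, 0, 0), c(1, 0, 0))
      zb <- amp * 0.5 * (sin(2 * pi * base[1] / p1 + f1) +
                         sin(2 * pi * base[2] / p2 + f2)) + zoff
      base[3] <- zb
      len <- stats::runif(1, 2, 4) * um
      kk <- max(2L, ceiling(len / spacing))
      ctr <- matrix(0, kk, 3); ctr[1, ] <- base
      d <- dirx
      for (i in 2:kk) {
        d <- d + stats::rnorm(3, sd = 0.15); d <- d / sqrt(sum(d^2))
        ctr[i, ] <- ctr[i - 1, ] + d * spacing
      }
      filos[[f]] <- .tubeMesh(ctr, rep(60, kk), nSeg = 6L,
                              label = SURFACE_OTHER)
    }
    ## strip SVs along x, ~svSegmentLength µm wide
    stripW <- config$svSegmentLength * um
    strip <- pmin(floor(V[seq_len(nV), 1] / stripW),
                  max(0, floor((w - 1) / stripW)))
    prevSV <- 0L
    for (g in sort(unique(strip))) {
      keepX <- xs >= g * stripW - 1e-6 &
               xs < (g + 1) * stripW + spacing + 1e-6
      iKeep <- which(keepX)
      if (length(iKeep) < 2L) next
      vsub <- c(outer(iKeep, (seq_len(ny) - 1L) * nx, `+`))
      vsub <- sort(c(vsub, vsub + nV))
      fkeep <- vapply(fs, function(fc) all(fc %in% vsub), logical(1))
      remap <- integer(2L * nV); remap[vsub] <- seq_along(vsub)
      fsub <- do.call(rbind, lapply(fs[fkeep], function(fc) remap[fc]))
      msh <- TriangleMesh(V[vsub, , drop = FALSE], fsub,
                          rep(SURFACE_OTHER, length(vsub)))
      svFil <- Filter(function(fm) {
        bx <- fm@vertices[1, 1]
        bx >= g * stripW && bx < (g + 1) * stripW
      }, filos)
      msh <- mergeMeshes(c(list(msh), svFil))
      svN <- svN + 1L
      svMesh[[svN]] <- msh
      svVol[svN] <- (min((g + 1) * stripW, w) - g * stripW) / um *
        config$gliaSheetSize[2] * (th / um)
      ## sample locations: mid-surface points on a coarse sub-grid
      midIdx <- vsub[vsub <= nV]
      mids <- V[midIdx, , drop = FALSE]
      mids[, 3] <- mids[, 3] - th / 2
      svLoc[[svN]] <- mids[seq(1L, nrow(mids), by = 7L), , drop = FALSE]
      if (prevSV > 0L) svEdge[[length(svEdge) + 1L]] <- c(prevSV, svN)
      prevSV <- svN
      ## skeleton: strip midline
      yMid <- h / 2
      for (i in iKeep) {
        skNodes[[length(skNodes) + 1L]] <-
          c(xs[i], yMid, zmid[i, which.min(abs(ys - yMid))] + zoff)
        skRad[length(skRad) + 1L] <- th / 2
        if (length(skNodes) > 1L && i != iKeep[1])
          skEdge[[length(skEdge) + 1L]] <-
            c(length(skNodes) - 1L, length(skNodes))
      }
    }
  }
  ids <- paste0("g", seq_len(svN))
  em <- if (length(svEdge)) {
    e <- do.call(rbind, svEdge)
    cbind(ids[e[, 1]], ids[e[, 2]])
  } else matrix(character(0), 0, 2)
  graph <- SupervoxelGraph(ids, svMesh, volumes = svVol, locations = svLoc,
                           labels = rep(1L, svN), edges = em)
  skel <- Skeleton(do.call(rbind, skNodes),
                   if (length(skEdge)) do.call(rbind, skEdge)
                   else matrix(integer(0), 0, 2),
                   radii = skRad,
                   nodeLabels = rep(SURFACE_OTHER, length(skNodes)))
  new("GroundTruthBundle", mesh = mergeMeshes(svMesh), skeleton = skel,
      svGraph = graph, organelles = list(),
      plantedEdges = matrix(character(0), 0, 2),
      config = unclass(config))
}
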