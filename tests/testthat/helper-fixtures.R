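# shared fixtures and independent oracles used across the suite

# closed unit cube mesh (edge in nm), 8 vertices / 12 faces, Euler char 2
cubeMesh <- function(edge = 1000, origin = c(0, 0, 0)) {
  v <- as.matrix(expand.grid(0:1, 0:1, 0:1)) * edge
  v <- sweep(v, 2, origin, `+`)
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0
    c(5, 6, 7), c(6, 8, 7),   # z = 1
    c(1, 2, 5), c(2, 6, 5),   # y = 0
    c(3, 7, 4), c(4, 7, 8),   # y = 1
    c(1, 5, 3), c(3, 5, 7),   # x = 0
    c(2, 4, 6), c(4, 8, 6))   # x = 1
  TriangleMesh(v, f)
}

sphereFixture <- function(r = 1000, center = c(0, 0, 0), nLat = 16L,
                          nLon = 24L) {
  cellmorph:::.sphereMesh(center, r, nLat = nLat, nLon = nLon)
}

# small random mesh for rasterizer tests: triangles scattered in the clip box
randomTriangleSoup <- function(nFaces, extentNm = c(8000, 4000, 4000),
                               seed = 1) {
  set.seed(seed)
  ctr <- cbind(runif(nFaces, -extentNm[1] / 2, extentNm[1] / 2),
               runif(nFaces, -extentNm[2] / 2, extentNm[2] / 2),
               runif(nFaces, -extentNm[3] / 2, extentNm[3] / 2))
  vs <- matrix(0, nFaces * 3, 3)
  for (i in seq_len(nFaces)) {
    vs[(i - 1) * 3 + 1:3, ] <- ctr[rep(i, 3), ] +
      matrix(runif(9, -800, 800), 3, 3)
  }
  TriangleMesh(vs, matrix(seq_len(nFaces * 3), nFaces, 3, byrow = TRUE))
}

# independent ray-casting oracle for the orthographic camera: for each pixel
# center, cast a ray along -z and return the depth/face of the nearest
# intersection within the clip box (ties: lowest face index)
rayCastOracle <- function(Vloc, F, nx, ny, ext) {
  ex <- ext[1]; ey <- ext[2]; ez <- ext[3]
  px <- -ex / 2 + (seq_len(nx) - 0.5) * ex / nx
  py <- -ey / 2 + (seq_len(ny) - 0.5) * ey / ny
  depth <- matrix(-Inf, nx, ny)
  face <- matrix(-1L, nx, ny)
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    p <- c(px[i], py[j])
    bestZ <- -Inf; bestF <- -1L
    for (f in seq_len(nrow(F))) {
      a <- Vloc[F[f, 1], ]; b <- Vloc[F[f, 2], ]; c_ <- Vloc[F[f, 3], ]
      den <- (b[2] - c_[2]) * (a[1] - c_[1]) +
             (c_[1] - b[1]) * (a[2] - c_[2])
      if (abs(den) < 1e-12) next
      l1 <- ((b[2] - c_[2]) * (p[1] - c_[1]) +
             (c_[1] - b[1]) * (p[2] - c_[2])) / den
      l2 <- ((c_[2] - a[2]) * (p[1] - c_[1]) +
             (a[1] - c_[1]) * (p[2] - c_[2])) / den
      l3 <- 1 - l1 - l2
      if (l1 < 0 || l2 < 0 || l3 < 0) next
      z <- l1 * a[3] + l2 * b[3] + l3 * c_[3]
      if (z < -ez / 2 || z > ez / 2) next
      if (z > bestZ) { bestZ <- z; bestF <- f - 1L }
    }
    depth[i, j] <- bestZ; face[i, j] <- bestF
  }
  list(depth = depth, face = face)
}

# same ray-casting oracle with the per-face test vectorized over pixels
# (identical mathematics; used where many meshes are checked)
rayCastOracleVec <- function(Vloc, F, nx, ny, ext) {
  ex <- ext[1]; ey <- ext[2]; ez <- ext[3]
  px <- rep(-ex / 2 + (seq_len(nx) - 0.5) * ex / nx, times = ny)
  py <- rep(-ey / 2 + (seq_len(ny) - 0.5) * ey / ny, each = nx)
  depth <- rep(-Inf, nx * ny)
  face <- rep(-1L, nx * ny)
  for (f in seq_len(nrow(F))) {
    a <- Vloc[F[f, 1], ]; b <- Vloc[F[f, 2], ]; c_ <- Vloc[F[f, 3], ]
    den <- (b[2] - c_[2]) * (a[1] - c_[1]) + (c_[1] - b[1]) * (a[2] - c_[2])
    if (abs(den) < 1e-12) next
    l1 <- ((b[2] - c_[2]) * (px - c_[1]) + (c_[1] - b[1]) * (py - c_[2])) / den
    l2 <- ((c_[2] - a[2]) * (px - c_[1]) + (a[1] - c_[1]) * (py - c_[2])) / den
    l3 <- 1 - l1 - l2
    z <- l1 * a[3] + l2 * b[3] + l3 * c_[3]
    hit <- l1 >= 0 & l2 >= 0 & l3 >= 0 & z >= -ez / 2 & z <= ez / 2 &
           z > depth
    depth[hit] <- z[hit]
    face[hit] <- f - 1L
  }
  list(depth = matrix(depth, nx, ny), face = matrix(face, nx, ny))
}

# reference connected components via boolean matrix closure (independent of
# the union-find implementation)
componentsByClosure <- function(n, edges) {
  A <- diag(TRUE, n)
  if (nrow(edges)) {
    A[edges] <- TRUE
    A[edges[, c(2, 1), drop = FALSE]] <- TRUE
  }
  repeat {
    A2 <- (A %*% A) > 0
    if (all(A2 == A)) break
    A <- A2
  }
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cid <- cid + 1L
      comp[A[i, ]] <- cid
    }
  }
  comp
}

# random labeled supervoxel graph whose nodes carry 2-point "meshes"
randomLabeledGraph <- function(n, pEdge = 0.4, pGlia = 0.5, pLarge = 0.5,
                               seed = 1) {
  set.seed(seed)
  glia <- runif(n) < pGlia
  large <- runif(n) < pLarge
  e <- which(upper.tri(matrix(0, n, n)) & matrix(runif(n * n) < pEdge, n, n),
             arr.ind = TRUE)
  list(n = n, edges = e, glia = glia, large = large)
}

# per-node bounding boxes: small nodes span 0.5 um, large span 10 um, all
# anchored near the origin so a component is "large" iff it has a large node
nodeBoxes <- function(large) {
  t(vapply(seq_along(large), function(i) {
    half <- if (large[i]) 5e3 else 250
    c(-half, -half, -half, half, half, half)
  }, numeric(6)))
}

# step-literal re-implementation of the splitting heuristic (independent
# oracle; plain loops, components via matrix closure)
splitOracle <- function(n, edges, glia, boxes, bbdUm = 8) {
  ## components via boolean reachability closure on the full matrix
  A0 <- diag(TRUE, n)
  if (nrow(edges)) {
    A0[edges] <- TRUE
    A0[edges[, c(2, 1), drop = FALSE]] <- TRUE
  }
  comps <- function(keep) {
    idx <- which(keep)
    if (!length(idx)) return(list())
    A <- A0[idx, idx, drop = FALSE]
    repeat {
      A2 <- (A %*% A) > 0
      if (all(A2 == A)) break
      A <- A2
    }
    out <- list(); done <- logical(length(idx))
    for (i in seq_along(idx)) {
      if (done[i]) next
      mem <- which(A[i, ])
      done[mem] <- TRUE
      out[[length(out) + 1L]] <- idx[mem]
    }
    out
  }
  cbbd <- function(m) {
    lo <- apply(boxes[m, 1:3, drop = FALSE], 2, min)
    hi <- apply(boxes[m, 4:6, drop = FALSE], 2, max)
    sqrt(sum((hi - lo)^2)) / 1e3
  }
  lab <- glia
  removed <- logical(n)
  for (cc in comps(lab)) {
    if (cbbd(cc) >= bbdUm) removed[cc] <- TRUE else lab[cc] <- FALSE
  }
  demoted <- logical(n)
  for (cc in comps(!lab & !removed)) {
    if (cbbd(cc) < bbdUm) demoted[cc] <- TRUE
  }
  list(neuron = comps(!lab & !removed & !demoted),
       glia = comps(removed | demoted))
}

# all 120 permutations of 1..5
allPerms5 <- function() {
  p <- as.matrix(expand.grid(rep(list(1:5), 5)))
  p[apply(p, 1, function(x) length(unique(x)) == 5L), , drop = FALSE]
}

# canonical form of a side partition for comparison
canonicalSets <- function(sets) {
  s <- lapply(unname(sets), function(x) sort(as.integer(x)))
  s[order(vapply(s, function(x) paste(x, collapse = ","), character(1)))]
}

# quick small neuron / glia bundles shared by slower tests (memoized)
.fixtureCache <- new.env(parent = emptyenv())
smallNeuron <- function(seed = 1) {
  key <- paste0("n", seed)
  if (is.null(.fixtureCache[[key]]))
    .fixtureCache[[key]] <- makeNeuron(synthesisConfig(
      seed = seed, nBranches = 2L, branchLengthRange = c(6, 9),
      voxelSize = c(50, 50, 50)))
  .fixtureCache[[key]]
}
smallGlia <- function(seed = 1) {
  key <- paste0("g", seed)
  if (is.null(.fixtureCache[[key]]))
    .fixtureCache[[key]] <- makeGliaFragment(synthesisConfig(
      seed = seed, gliaSheetSize = c(6, 6), voxelSize = c(50, 50, 50)))
  .fixtureCache[[key]]
}
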