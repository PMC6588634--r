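test_that("generators are pure functions of the config seed", {
  cfg <- synthesisConfig(seed = 5, nBranches = 2L, voxelSize = c(50, 50, 50))
  a <- makeNeuron(cfg); b <- makeNeuron(cfg)
  expect_identical(vertices(a@mesh), vertices(b@mesh))
  expect_identical(a@svGraph@edges, b@svGraph@edges)
  g1 <- makeGliaFragment(cfg); g2 <- makeGliaFragment(cfg)
  expect_identical(vertices(g1@mesh), vertices(g2@mesh))
  # the generator must not disturb the caller's RNG stream
  set.seed(99); x1 <- runif(1)
  set.seed(99); invisible(makeNeuron(cfg)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("spine counts follow the configured density", {
  # a single 10 um dendrite at 2 spines/um: ~20 spines, reproducible
  cfg <- synthesisConfig(seed = 21, nBranches = 1L,
                         branchLengthRange = c(10, 10), spineDensity = 2,
                         somaRadius = 2, voxelSize = c(50, 50, 50))
  b <- makeNeuron(cfg)
  nHeads <- sum(vertexLabels(b@mesh) == 2L)
  headVerts <- nVertices(cellmorph:::.sphereMesh(c(0, 0, 0), 1,
                                                 nLat = 5L, nLon = 8L))
  nSpines <- nHeads / headVerts
  expect_gt(nSpines, 20 - 3 * sqrt(20))   # within 3 sd of Poisson(20)
  expect_lt(nSpines, 20 + 3 * sqrt(20))
  b2 <- makeNeuron(cfg)
  expect_identical(sum(vertexLabels(b2@mesh) == 2L), nHeads)
})

test_that("soma-only neuron has the bounding box of its sphere", {
  cfg <- synthesisConfig(seed = 1, nBranches = 0L, somaRadius = 5,
                         voxelSize = c(50, 50, 50))
  b <- makeNeuron(cfg)
  expect_equal(bbd(b@mesh), 2 * 5 * sqrt(3), tolerance = 0.02)
  expect_error(makeNeuron(synthesisConfig(nBranches = 0L, somaRadius = 0)),
               "soma or one branch")
})

test_that("glia sheets are flat at zero undulation and differ from tubes", {
  flat <- makeGliaFragment(synthesisConfig(seed = 2, gliaUndulation = 0,
                                           gliaFilopodia = 0L,
                                           gliaThickness = 200))
  zr <- range(vertices(flat@mesh)[, 3])
  expect_lte(diff(zr), 200 + 1e-6)   # all z within the sheet thickness
  # surface statistics differ from tubes by construction: triangle aspect
  aspect <- function(m) {
    V <- vertices(m); F <- faces(m)
    e1 <- sqrt(rowSums((V[F[, 1], ] - V[F[, 2], ])^2))
    e2 <- sqrt(rowSums((V[F[, 2], ] - V[F[, 3], ])^2))
    e3 <- sqrt(rowSums((V[F[, 1], ] - V[F[, 3], ])^2))
    mean(pmax(e1, e2, e3) / pmin(e1, e2, e3))
  }
  tube <- cellmorph:::.tubeMesh(cbind(seq(0, 5000, by = 500), 0, 0),
                                rep(300, 11))
  expect_gt(abs(aspect(flat@mesh) - aspect(tube)), 0.1)
})

test_that("SV decomposition covers the mesh and labels are recoverable", {
  b <- smallNeuron(3)
  svVerts <- do.call(rbind, lapply(svMeshes(b@svGraph), vertices))
  expect_identical(sort(round(as.vector(svVerts), 6)),
                   sort(round(as.vector(vertices(b@mesh)), 6)))
  # sanity ceiling: generator-internal labels give a perfect classifier
  g <- smallGlia(3)
  truth <- c(svLabels(b@svGraph), svLabels(g@svGraph))
  pred <- ifelse(grepl("^g", names(truth)), 1L, 0L)
  expect_identical(unname(pred), unname(truth))
})

test_that("plantMergeError bridges the nearest SV pairs", {
  b <- smallNeuron(4); g <- smallGlia(4)
  merged <- plantMergeError(b, g, nBridges = 1L)
  expect_identical(nrow(merged@plantedEdges), 1L)
  expect_identical(length(connectedComponents(merged@svGraph)), 1L)
  # labels preserved
  expect_identical(sum(svLabels(merged@svGraph) == 1L),
                   length(svIds(g@svGraph)))
  # removing the planted edge disconnects neuron from glia
  gr <- merged@svGraph
  pe <- merged@plantedEdges
  keep <- !(gr@edges[, 1] == pe[1, 1] & gr@edges[, 2] == pe[1, 2]) &
          !(gr@edges[, 1] == pe[1, 2] & gr@edges[, 2] == pe[1, 1])
  gr2 <- SupervoxelGraph(svIds(gr), svMeshes(gr), svVolumes(gr),
                         gr@locations, svLabels(gr),
                         edges = gr@edges[keep, , drop = FALSE])
  expect_identical(length(connectedComponents(gr2)), 2L)
  # the planted bridge is the globally nearest neuron/glia pair
  ids <- svIds(gr)
  neuron <- ids[svLabels(gr) == 0L]; glia <- ids[svLabels(gr) == 1L]
  best <- c(Inf, "", "")
  for (a in neuron) for (bb in glia) {
    A <- vertices(svMeshes(gr)[[a]]); B <- vertices(svMeshes(gr)[[bb]])
    d <- sqrt(min(outer(rowSums(A^2), rowSums(B^2), `+`) -
                  2 * A %*% t(B)))
    if (d < as.numeric(best[1])) best <- c(d, a, bb)
  }
  expect_setequal(as.vector(pe), best[2:3])
  expect_error(plantMergeError(b, g, nBridges = 0L), "nBridges")
})

test_that("voxelize matches analytic volumes and shift invariance", {
  sph <- sphereFixture(r = 1000)
  v <- voxelize(sph, 50)
  vol <- sum(v@data) * prod(v@voxelSize)
  expect_lt(abs(vol - 4 / 3 * pi * 1000^3) / (4 / 3 * pi * 1000^3), 0.05)
  # translation by whole voxels leaves the count unchanged
  sph2 <- TriangleMesh(sweep(vertices(sph), 2, c(150, -300, 450), `+`),
                       faces(sph))
  v2 <- voxelize(sph2, 50)
  expect_identical(sum(v2@data), sum(v@data))
  # anisotropic voxels
  cb <- cubeMesh(edge = 1000)
  vc <- voxelize(cb, c(40, 50, 100))
  expect_lt(abs(sum(vc@data) * prod(vc@voxelSize) - 1000^3) / 1000^3, 0.06)
  expect_error(voxelize(TriangleMesh(matrix(0, 1, 3)), 50), "degenerate")
})
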