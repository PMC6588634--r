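test_that("vertex graph connects only pairs within 120 nm", {
  V <- rbind(c(0, 0, 0), c(100, 0, 0), c(100, 100, 0), c(500, 0, 0))
  m <- TriangleMesh(V)
  adj <- vertexGraph(m, 120)
  expect_setequal(adj[[1]], 2L)                    # d(1,3) = 141 > 120
  expect_setequal(adj[[2]], c(1L, 3L))
  expect_identical(length(adj[[4]]), 0L)
  # symmetric
  for (i in seq_along(adj)) for (j in adj[[i]]) expect_true(i %in% adj[[j]])
})

test_that("label smoothing is a bounded-BFS majority vote", {
  # a dense line of vertices, 50 nm apart
  n <- 60
  m <- TriangleMesh(cbind(seq(0, (n - 1) * 50, by = 50), 0, 0))
  lab <- rep(1L, n)
  expect_identical(smoothVertexLabels(m, lab), lab)   # uniform unchanged
  lab2 <- lab; lab2[30] <- 2L                          # lone mislabel
  expect_identical(smoothVertexLabels(m, lab2), lab)
  # striped labels: equals a brute-force 40-vertex BFS vote
  lab3 <- rep(rep(1:2, each = 6), length.out = n)
  adj <- vertexGraph(m, 120)
  got <- smoothVertexLabels(m, lab3, graph = adj)
  ref <- vapply(seq_len(n), function(i) {
    coll <- cellmorph:::.bfsCollect(adj, i, 40L)
    tb <- table(lab3[coll])
    top <- as.integer(names(tb)[tb == max(tb)])
    if (length(top) == 1L) top else lab3[i]
  }, integer(1))
  expect_identical(got, ref)
  expect_error(smoothVertexLabels(TriangleMesh(matrix(numeric(0), 0, 3)),
                                  integer(0)), "empty")
})

test_that("ground-truth backmapping recovers labels on covered vertices", {
  b <- smallNeuron(6)
  mesh <- b@mesh
  cfg <- renderConfig(resolution = c(64L, 32L))
  L <- sampleRenderingLocations(mesh)
  L <- L[seq(1, nrow(L), length.out = min(6, nrow(L))), , drop = FALSE]
  labelMaps <- list(); faceMaps <- list()
  truth <- vertexLabels(mesh)
  for (q in seq_len(nrow(L))) {
    fr <- localFrame(mesh, L[q, ], cfg)
    fid <- renderFaceIds(mesh, fr, cfg)
    for (k in seq_along(fid)) {
      fm <- fid[[k]]
      lm <- matrix(0L, nrow(fm), ncol(fm))
      cov <- fm >= 0L
      # ground-truth pixel labels: majority label of the face's vertices
      lm[cov] <- apply(faces(mesh)[fm[cov] + 1L, , drop = FALSE], 1L,
                       function(vs) {
                         tb <- table(truth[vs])
                         as.integer(names(tb)[which.max(tb)])
                       })
      labelMaps[[length(labelMaps) + 1L]] <- lm
      faceMaps[[length(faceMaps) + 1L]] <- fm
    }
  }
  sl <- backmapLabels(labelMaps, faceMaps, mesh, nClasses = 4L)
  covered <- which(sl$provenance == "backmapped")
  expect_gt(length(covered), 100)
  # vertices of uniformly labeled faces recover their label exactly
  faceLab <- matrix(truth[faces(mesh)], ncol = 3)
  uniform <- faces(mesh)[faceLab[, 1] == faceLab[, 2] &
                         faceLab[, 2] == faceLab[, 3], , drop = FALSE]
  uniVerts <- intersect(unique(as.vector(uniform)), covered)
  mixVerts <- unique(as.vector(faces(mesh)[faceLab[, 1] != faceLab[, 2] |
                                           faceLab[, 2] != faceLab[, 3], ,
                                           drop = FALSE]))
  clean <- setdiff(uniVerts, mixVerts)
  expect_gt(length(clean), 50)
  expect_identical(sl$labels[clean], truth[clean])
  # kNN fill labels every vertex and flags provenance
  filled <- knnFill(sl, mesh, k = 20)
  expect_false(anyNA(filled$labels))
  expect_setequal(unique(filled$provenance[is.na(sl$labels)]), "knn-filled")
  expect_identical(filled$labels[covered], sl$labels[covered])
  # vertex votes equal an exhaustive pixel -> face -> vertex accumulation
  votes <- matrix(0L, nVertices(mesh), 4)
  for (q in seq_along(labelMaps)) {
    fm <- faceMaps[[q]]; lm <- labelMaps[[q]]
    sel <- which(fm >= 0L & lm >= 1L)
    for (p in sel) {
      vs <- faces(mesh)[fm[p] + 1L, ]
      for (v in vs) votes[v, lm[p]] <- votes[v, lm[p]] + 1L
    }
  }
  refLab <- rep(NA_integer_, nVertices(mesh))
  has <- rowSums(votes) > 0
  refLab[has] <- apply(votes[has, , drop = FALSE], 1,
                       function(v) which(v == max(v))[1])
  expect_identical(sl$labels, refLab)
})

test_that("coverage is a monotone fraction of visible faces", {
  m <- cubeMesh(edge = 2000, origin = c(-1000, -1000, -1000))
  cfg <- renderConfig(resolution = c(32L, 16L), nPersp = 1L)
  expect_identical(coverage(list(), m), 0)
  frontal <- renderFaceIds(m, new("LocalFrame", origin = c(0, 0, 0),
                                  axes = diag(3), degenerate = FALSE), cfg)
  c1 <- coverage(frontal, m)
  expect_gt(c1, 0); expect_lt(c1, 1)
  # add the five other axis directions: coverage can only grow
  maps <- frontal
  for (ax in list(c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0), c(0, -1, 0),
                  c(0, 0, -1))) {
    z <- ax / sqrt(sum(ax^2))
    x <- cellmorph:::.anyPerp(z); y <- cellmorph:::.cross3(z, x)
    fr <- new("LocalFrame", origin = c(0, 0, 0),
              axes = cbind(x, y, z), degenerate = FALSE)
    maps <- c(maps, renderFaceIds(m, fr, cfg))
    expect_gte(coverage(maps, m), c1)
  }
  expect_gte(coverage(maps, m), 0.9)   # convex mesh seen from 6 sides
})

test_that("surface model overfits small view sets", {
  set.seed(9)
  mkView <- function() {
    v <- array(0, dim = c(32, 16, 4))
    lab <- matrix(1L, 32, 16)          # class 1 = background here
    # bright band -> class 2
    r <- sample(4:24, 1)
    v[r:(r + 4), , 1] <- 220
    lab[r:(r + 4), ] <- 2L
    list(v = v, lab = lab)
  }
  vs <- replicate(5, mkView(), simplify = FALSE)
  m <- buildSurfaceModel(nClasses = 2L, nChannels = 4L,
                         filters = c(6L, 10L), seed = 2)
  m <- trainSurfaceModel(m, lapply(vs, `[[`, "v"), lapply(vs, `[[`, "lab"),
                         trainConfig(steps = 120L, batchSize = 4L,
                                     lr = 4e-3, weightDecay = 0,
                                     lrDecay = c(0.99, 100), seed = 3))
  acc <- mean(vapply(vs, function(x)
    mean(predictSurface(m, x$v) == x$lab), numeric(1)))
  expect_gte(acc, 0.95)
  # background-only view predicts background everywhere
  bg <- array(0, dim = c(32, 16, 4))
  bgl <- matrix(1L, 32, 16)
  m2 <- buildSurfaceModel(nClasses = 2L, nChannels = 4L,
                          filters = c(6L, 10L), seed = 2)
  m2 <- trainSurfaceModel(m2, list(bg), list(bgl),
                          trainConfig(steps = 30L, batchSize = 2L,
                                      lr = 4e-3, weightDecay = 0, seed = 3),
                          loss = "ce")
  expect_true(all(predictSurface(m2, bg) == 1L))
  expect_error(trainSurfaceModel(m2, list(bg), list(bgl[1:10, ])),
               "shape mismatch")
})

test_that("Lovasz-softmax gradients match numerical differentiation", {
  set.seed(4)
  Z <- matrix(rnorm(60), 20, 3)
  lab <- sample(1:3, 20, TRUE)
  got <- cellmorph:::.segLoss(Z, lab, type = "lovasz")
  eps <- 1e-6
  for (p in sample(length(Z), 12)) {
    Z2 <- Z; Z2[p] <- Z[p] + eps
    Z3 <- Z; Z3[p] <- Z[p] - eps
    num <- (cellmorph:::.segLoss(Z2, lab, "lovasz")$loss -
            cellmorph:::.segLoss(Z3, lab, "lovasz")$loss) / (2 * eps)
    expect_lt(abs(num - got$dZ[p]),
              1e-5 * max(1, abs(num)))
  }
})

test_that("synapse contacts are classified from the labeled surface", {
  b <- smallNeuron(7)
  mesh <- b@mesh
  truth <- vertexLabels(mesh)
  lab <- structure(list(labels = truth,
                        provenance = rep("backmapped", nVertices(mesh))),
                   class = "surfaceLabeling")
  heads <- which(truth == 2L)
  shafts <- which(truth == 3L)
  expect_gt(length(heads), 0)
  hc <- vertices(mesh)[heads[1], ]
  expect_identical(as.character(classifySynapseContact(hc, lab, mesh)),
                   "spinous")
  # a shaft vertex far from any spine
  d2spine <- cellmorph:::.knn(vertices(mesh)[truth %in% c(1L, 2L), ,
                                             drop = FALSE],
                              vertices(mesh)[shafts, , drop = FALSE],
                              1L)$dist[, 1]
  sc <- vertices(mesh)[shafts[which.max(d2spine)], ]
  expect_identical(as.character(classifySynapseContact(sc, lab, mesh)),
                   "shaft")
  # k nearest voting equals an exhaustive scan
  q <- vertices(mesh)[heads[1], ] + c(40, 40, 40)
  d <- sqrt(colSums((t(vertices(mesh)) - q)^2))
  nb <- truth[order(d)[1:20]]
  tb <- table(nb)
  want <- min(as.integer(names(tb)[tb == max(tb)]))
  got <- classifySynapseContact(q, lab, mesh, k = 20)
  expect_identical(as.character(got),
                   if (want %in% c(1L, 2L)) "spinous"
                   else if (want == 3L) "shaft" else "ambiguous")
})
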