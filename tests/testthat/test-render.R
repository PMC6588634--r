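test_that("localFrame recovers principal axes and handles degeneracy", {
  cfg <- renderConfig(resolution = c(64L, 32L))
  # 1D cloud along global x
  line <- TriangleMesh(cbind(seq(-3000, 3000, by = 50), 0, 0))
  fr <- localFrame(line, c(0, 0, 0), cfg)
  expect_false(fr@degenerate)
  expect_equal(abs(fr@axes[, 1]), c(1, 0, 0), tolerance = 1e-9)
  # isotropic point cloud (cubic lattice: exactly tied covariance) ->
  # degenerate flag, global axes
  iso <- TriangleMesh(as.matrix(expand.grid(seq(-1000, 1000, by = 250),
                                            seq(-1000, 1000, by = 250),
                                            seq(-1000, 1000, by = 250))))
  cfgAll <- renderConfig(resolution = c(64L, 32L), pcaFraction = 1)
  frIso <- localFrame(iso, c(0, 0, 0), cfgAll)
  expect_true(frIso@degenerate)
  expect_equal(frIso@axes, diag(3))
  # elongated 4:2:1 ellipsoid: axes within 2 degrees of the generators
  set.seed(4)
  E <- cbind(rnorm(6000, sd = 2000), rnorm(6000, sd = 1000),
             rnorm(6000, sd = 500))
  R <- cellmorph:::.rotationAboutAxis(c(1, 1, 1) / sqrt(3), 0.7)
  Erot <- E %*% t(R)
  fr2 <- localFrame(TriangleMesh(Erot), c(0, 0, 0),
                    renderConfig(extent = c(16, 16, 16),
                                 resolution = c(64L, 32L)))
  # oracle: full eigendecomposition on all vertices
  eg <- eigen(cov(Erot), symmetric = TRUE)
  for (j in 1:3) {
    ang <- acos(min(1, abs(sum(fr2@axes[, j] * eg$vectors[, j]))))
    expect_lt(ang * 180 / pi, 2)
  }
  # axes orthonormal and right-handed
  expect_lt(max(abs(crossprod(fr2@axes) - diag(3))), 1e-9)
  expect_gt(det(fr2@axes), 0)
})

test_that("depth encoding places a mid-depth triangle at 128", {
  cfg <- renderConfig(resolution = c(64L, 32L))
  # triangle parallel to the image plane at z = 0 (mid clip depth)
  tri <- TriangleMesh(rbind(c(-3000, -1500, 0), c(3000, -1500, 0),
                            c(0, 1800, 0)),
                      rbind(c(1L, 2L, 3L)))
  fr <- new("LocalFrame", origin = c(0, 0, 0), axes = diag(3),
            degenerate = FALSE)
  img <- viewArray(renderViews(list(cell = tri), fr, cfg))[, , 1, 1]
  fg <- img[img > 0]
  expect_gt(length(fg), 100)
  expect_true(all(abs(fg - 128) <= 1))
  # pixels outside the triangle are exactly 0
  expect_identical(img[1, 1], 0L)
  # empty clip box -> all zeros (not an error)
  far <- TriangleMesh(rbind(c(9e5, 9e5, 9e5), c(9.1e5, 9e5, 9e5),
                            c(9e5, 9.1e5, 9e5)), rbind(c(1L, 2L, 3L)))
  expect_true(all(viewArray(renderViews(list(cell = far), fr, cfg)) == 0L))
})

test_that("rasterizer agrees with the ray-casting oracle per pixel", {
  cfg <- renderConfig(resolution = c(32L, 16L))
  ext <- cfg$extent * 1e3
  fr <- new("LocalFrame", origin = c(0, 0, 0), axes = diag(3),
            degenerate = FALSE)
  for (seed in 1:4) {
    m <- randomTriangleSoup(25, seed = seed)
    r <- cellmorph:::.rasterize(vertices(m), faces(m), 32L, 16L, ext)
    o <- rayCastOracle(vertices(m), faces(m), 32L, 16L, ext)
    expect_identical(r$face, o$face)
    cov <- is.finite(o$depth)
    expect_lt(max(abs(r$depth[cov] - o$depth[cov])), 1e-9)
  }
})

test_that("rendering is equivariant under rigid transforms and pure", {
  cfg <- renderConfig(resolution = c(48L, 24L), nPersp = 2L)
  m <- randomTriangleSoup(40, seed = 9)
  fr <- localFrame(m, c(0, 0, 0), cfg)
  base <- viewArray(renderViews(list(cell = m), fr, cfg))
  expect_identical(base,
                   viewArray(renderViews(list(cell = m), fr, cfg)))  # pure
  set.seed(10)
  for (rep in 1:5) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    R <- cellmorph:::.rotationAboutAxis(ax, runif(1, 0, 2 * pi))
    tr <- rnorm(3, sd = 1e5)
    m2 <- TriangleMesh(sweep(vertices(m) %*% t(R), 2, tr, `+`), faces(m))
    fr2 <- new("LocalFrame", origin = as.numeric(R %*% fr@origin + tr),
               axes = R %*% fr@axes, degenerate = FALSE)
    got <- viewArray(renderViews(list(cell = m2), fr2, cfg))
    expect_identical(got, base)
  }
})

test_that("face-ID maps use z-buffer semantics and agree with depth", {
  cfg <- renderConfig(resolution = c(32L, 16L))
  fr <- new("LocalFrame", origin = c(0, 0, 0), axes = diag(3),
            degenerate = FALSE)
  # two stacked triangles: nearer face id wins where they overlap
  m <- TriangleMesh(rbind(c(-3000, -1500, -500), c(3000, -1500, -500),
                          c(0, 1800, -500),
                          c(-3000, -1500, 900), c(3000, -1500, 900),
                          c(0, 1800, 900)),
                    rbind(c(1L, 2L, 3L), c(4L, 5L, 6L)))
  ids <- renderFaceIds(m, fr, cfg)[[1]]
  expect_true(all(ids[ids >= 0] == 1L))  # nearer (z=900) face, 0-based id 1
  # single triangle covering a pixel -> id 0 there
  one <- TriangleMesh(vertices(m)[1:3, ], rbind(c(1L, 2L, 3L)))
  ids1 <- renderFaceIds(one, fr, cfg)[[1]]
  expect_true(all(ids1[ids1 >= 0] == 0L))
  expect_gt(sum(ids1 >= 0), 0)
  # face map and depth channel cover exactly the same pixels
  b <- smallNeuron(5)
  L <- sampleRenderingLocations(b@mesh)
  fr2 <- localFrame(b@mesh, L[2, ], cfg)
  dimg <- viewArray(renderViews(list(cell = b@mesh), fr2, cfg))[, , 1, 1]
  fids <- renderFaceIds(b@mesh, fr2, cfg)[[1]]
  expect_identical(fids >= 0L, dimg > 0L)
  # depth monotone: nearer surfaces have larger pixel values
  expect_true(all(dimg[fids >= 0L] >= 1))
  # RGB face-id encoding round trips
  expect_identical(rgbToFaceId(faceIdToRGB(fids)), fids)
})

test_that("maskUnconnected2D keeps only the central component", {
  img <- matrix(0L, 20, 20)
  img[9:12, 9:12] <- 100L      # central blob
  img[1:3, 1:3] <- 200L        # off-center blob
  got <- maskUnconnected2D(img)
  expect_true(all(got[1:3, 1:3] == 0L))
  expect_true(all(got[9:12, 9:12] == 100L))
  # single blob unchanged; empty image unchanged
  one <- matrix(0L, 10, 10); one[4:6, 4:6] <- 50L
  expect_identical(maskUnconnected2D(one), one)
  empty <- matrix(0L, 5, 5)
  expect_identical(maskUnconnected2D(empty), empty)
  # nested / touching blobs equal a reference flood fill from the center
  set.seed(12)
  for (rep in 1:5) {
    im <- matrix(0L, 24, 24)
    im[matrix(runif(576) < 0.45, 24, 24)] <- 77L
    got <- maskUnconnected2D(im)
    # reference: label all 8-connected components, keep the one holding the
    # foreground pixel nearest the center
    lab <- matrix(0L, 24, 24); cur <- 0L
    for (s in which(im > 0)) {
      if (lab[s] > 0L) next
      cur <- cur + 1L
      stack <- s
      while (length(stack)) {
        p <- stack[1]; stack <- stack[-1]
        if (lab[p] > 0L) next
        lab[p] <- cur
        i <- (p - 1L) %% 24L + 1L; j <- (p - 1L) %/% 24L + 1L
        for (di in -1:1) for (dj in -1:1) {
          ii <- i + di; jj <- j + dj
          if (ii >= 1 && ii <= 24 && jj >= 1 && jj <= 24) {
            q <- ii + (jj - 1L) * 24L
            if (im[q] > 0L && lab[q] == 0L) stack <- c(stack, q)
          }
        }
      }
    }
    w <- which(im > 0, arr.ind = TRUE)
    d2 <- (w[, 1] - 12.5)^2 + (w[, 2] - 12.5)^2
    keepLab <- lab[w[which.min(d2), 1], w[which.min(d2), 2]]
    ref <- im; ref[lab != keepLab] <- 0L
    expect_identical(got, ref)
  }
})
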