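test_that("mergeSkeletons repeatedly bridges the closest components", {
  s1 <- Skeleton(rbind(c(0, 0, 0), c(1000, 0, 0)), rbind(c(1L, 2L)))
  expect_identical(edges(mergeSkeletons(list(s1))), edges(s1))
  # two parts: the single added edge joins the nearest pair
  s2 <- Skeleton(rbind(c(5000, 100, 0), c(9000, 0, 0)), rbind(c(1L, 2L)))
  mg <- mergeSkeletons(list(s1, s2))
  expect_identical(nrow(edges(mg)), 3L)
  added <- edges(mg)[3, ]
  # brute-force nearest inter-part pair: node 2 (1000,0,0) & node 3 (5000,..)
  expect_setequal(added, c(2L, 3L))
  # three collinear parts with 1 um and 2 um gaps: first bridge = 1 um gap
  p1 <- Skeleton(matrix(c(0, 0, 0), 1, 3))
  p2 <- Skeleton(matrix(c(1000, 0, 0), 1, 3))
  p3 <- Skeleton(matrix(c(3000, 0, 0), 1, 3))
  mg3 <- mergeSkeletons(list(p1, p2, p3))
  expect_identical(nrow(edges(mg3)), 2L)
  expect_setequal(edges(mg3)[1, ], c(1L, 2L))   # the 1 um gap first
  # result is connected
  comp <- cellmorph:::.componentsUF(1:3, edges(mg3))
  expect_identical(length(unique(comp)), 1L)
})

test_that("sparsify implements the degree-2 removal rule", {
  # collinear chain, edges 100 nm each: dot = 1, lambda = 200 < 500 -> removed
  s <- Skeleton(rbind(c(0, 0, 0), c(100, 0, 0), c(200, 0, 0)),
                rbind(c(1L, 2L), c(2L, 3L)))
  out <- sparsify(s)
  expect_identical(nrow(nodes(out)), 2L)
  expect_identical(nrow(edges(out)), 1L)
  # right angle, edges 100 nm: dot = 0, lambda = 200 >= 50 -> kept
  r <- Skeleton(rbind(c(0, 0, 0), c(100, 0, 0), c(100, 100, 0)),
                rbind(c(1L, 2L), c(2L, 3L)))
  expect_identical(nrow(nodes(sparsify(r))), 3L)
  # 20 nm kink: lambda = 40 < 50 -> removed regardless of angle
  k <- Skeleton(rbind(c(0, 0, 0), c(20, 0, 0), c(20, 20, 0)),
                rbind(c(1L, 2L), c(2L, 3L)))
  expect_identical(nrow(nodes(sparsify(k))), 2L)
  # branch and end nodes never removed
  star <- Skeleton(rbind(c(0, 0, 0), c(10, 0, 0), c(-10, 0, 0),
                         c(0, 10, 0)),
                   rbind(c(1L, 2L), c(1L, 3L), c(1L, 4L)))
  expect_identical(nrow(nodes(sparsify(star))), 4L)
  # long straight chain collapses toward its endpoints
  n <- 21
  chain <- Skeleton(cbind(seq(0, 2000, length.out = n), 0, 0),
                    cbind(1:(n - 1), 2:n))
  sp <- sparsify(chain)
  expect_lt(nrow(nodes(sp)), n)
  expect_equal(pathLength(sp), 2000)  # endpoints preserved, length kept
})

test_that("estimateRadius is the median distance to the 10 nearest vertices", {
  # exactly 10 vertices at distances 1..10 -> median 5.5
  m <- TriangleMesh(cbind(c(1, 2, -3, 4, -5, 6, 7, -8, 9, 10), 0, 0))
  r <- estimateRadius(matrix(0, 1, 3), m)
  expect_equal(unname(r), 5.5)
  # node on the axis of a dense cylinder of radius 300 nm
  th <- seq(0, 2 * pi, length.out = 60)[-60]
  cyl <- do.call(rbind, lapply(seq(-500, 500, by = 50), function(x)
    cbind(x, 300 * cos(th), 300 * sin(th))))
  rc <- estimateRadius(matrix(0, 1, 3), TriangleMesh(cyl))
  expect_lt(abs(rc - 300), 10)
  # coincident vertex cluster -> ~0; < 10 vertices flagged
  clus <- TriangleMesh(matrix(rep(c(5, 5, 5), 4), 4, 3, byrow = TRUE))
  r0 <- estimateRadius(matrix(c(5, 5, 5), 1, 3), clus)
  expect_equal(as.numeric(r0), 0)
  expect_true(isTRUE(attr(r0, "partial")))
})

test_that("extractFeatures returns the 23-component descriptor", {
  # uniform chain, all diameters 500 nm
  n <- 9
  sk <- Skeleton(cbind(seq(0, 4000, length.out = n), 0, 0),
                 cbind(1:(n - 1), 2:n), radii = rep(250, n))
  f <- extractFeatures(sk, 5L, config = featureConfig(context = 1500))
  expect_identical(length(f), 23L)
  expect_identical(names(f), featureNames())
  expect_equal(unname(f["diam_mean"]), 500)
  expect_equal(unname(f["diam_sd"]), 0)
  hist <- unname(f[paste0("diam_hist", 1:10)])
  expect_equal(hist, c(0, 0, 1, 0, 0, 0, 0, 0, 0, 0))  # 500 in [400,600)
  expect_equal(sum(hist), 1)
  # hand-built toy skeleton with organelles: manual arithmetic oracle
  sk2 <- Skeleton(rbind(c(0, 0, 0), c(1000, 0, 0), c(2000, 0, 0),
                        c(3000, 0, 0), c(2000, 1000, 0), c(9000, 0, 0)),
                  rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L), c(3L, 5L),
                        c(4L, 6L)),
                  radii = c(100, 200, 300, 400, 500, 600))
  orgs <- data.frame(class = c("MI", "MI", "VC", "SJ"),
                     size = c(1000, 3000, 500, 900),
                     node = c(2L, 4L, 5L, 6L))
  f2 <- extractFeatures(sk2, 1L, orgs, featureConfig(context = 3500))
  # traversal from node 1, context 3.5 um: nodes 1..4 (paths 0,1000,2000,
  # 3000) and node 5 (2000 + 1000 = 3000); node 6 (3000 + 6000) is out
  expect_equal(unname(f2["diam_mean"]), mean(2 * c(100, 200, 300, 400, 500)))
  expect_equal(unname(f2["mi_count"]), 2)
  expect_equal(unname(f2["mi_size_mean"]), 2000)
  expect_equal(unname(f2["mi_size_sd"]), 1000)   # population sd
  expect_equal(unname(f2["vc_count"]), 1)        # node 5 traversed
  expect_equal(unname(f2["sj_count"]), 0)        # node 6 not traversed
  expect_equal(unname(f2["degree_mean"]), mean(c(1, 2, 3, 2, 1)))
  # density: 5 traversed nodes inside the (2 x 3.5 um)^3 box
  expect_equal(unname(f2["node_density"]), 5 / 7^3)
  # isolated node: features from the node alone
  iso <- Skeleton(matrix(0, 1, 3), radii = 150)
  fi <- extractFeatures(iso, 1L)
  expect_identical(length(fi), 23L)
  expect_equal(unname(fi["diam_mean"]), 300)
  # rigid-transform invariance
  R <- cellmorph:::.rotationAboutAxis(c(0, 0, 1), 1.1)
  sk2r <- Skeleton(sweep(nodes(sk2) %*% t(R), 2, c(1e5, 2e5, -3e4), `+`),
                   edges(sk2), radii = radii(sk2))
  f2r <- extractFeatures(sk2r, 1L, orgs, featureConfig(context = 3500))
  expect_equal(f2, f2r, tolerance = 1e-9)
})

test_that("sliding majority vote smooths labels along the skeleton", {
  n <- 30
  sk <- Skeleton(cbind(seq(0, 29000, length.out = n), 0, 0),
                 cbind(1:(n - 1), 2:n))
  lab <- rep(1L, n)
  expect_identical(slidingMajorityVote(sk, lab), lab)   # uniform unchanged
  lab2 <- lab; lab2[15] <- 2L
  expect_identical(slidingMajorityVote(sk, lab2), lab)  # flip corrected
  # alternating labels: equals a brute-force windowed vote (ties keep own)
  lab3 <- rep(c(1L, 2L), 15)
  got <- slidingMajorityVote(sk, lab3, window = 5000)
  D <- as.matrix(dist(nodes(sk)))
  ref <- vapply(seq_len(n), function(i) {
    w <- lab3[D[i, ] <= 5000]   # chain: path distance = euclidean here
    tb <- table(w)
    top <- as.integer(names(tb)[tb == max(tb)])
    if (length(top) == 1L) top else lab3[i]
  }, integer(1))
  expect_identical(got, ref)
})

test_that("voronoiPropagate matches brute-force nearest labels", {
  P <- rbind(c(-1000, 0, 0), c(1000, 0, 0))
  lab <- c(7L, 3L)
  expect_identical(voronoiPropagate(P, lab, matrix(c(200, 0, 0), 1, 3)), 3L)
  expect_identical(voronoiPropagate(P, lab, P), lab)   # coincident points
  # tie -> lowest label code
  expect_identical(voronoiPropagate(P, lab, matrix(0, 1, 3)), 3L)
  expect_error(voronoiPropagate(matrix(numeric(0), 0, 3), integer(0),
                                matrix(0, 1, 3)), "no labeled")
  set.seed(31)
  Pts <- matrix(rnorm(60, sd = 5000), 20, 3)
  labs <- sample(1:4, 20, TRUE)
  Q <- matrix(rnorm(3000, sd = 5000), 1000, 3)
  got <- voronoiPropagate(Pts, labs, Q)
  ref <- apply(Q, 1, function(q) {
    d <- sqrt(colSums((t(Pts) - q)^2))
    labs[which.min(d)]
  })
  expect_identical(got, as.integer(ref))
})

test_that("random-forest baseline behaves sanely on separable features", {
  set.seed(5)
  n <- 120
  X <- matrix(rnorm(n * 23), n, 23)
  y <- rep(1:3, length.out = n)
  X[, 1] <- X[, 1] + 5 * y          # separable along feature 1
  pred <- rfcBaseline(X, y, X, seed = 2)
  expect_gte(mean(pred == y), 0.95)
  # permuted labels -> chance accuracy
  yp <- sample(y)
  predP <- rfcBaseline(X, yp, X[1:60, ], seed = 2)
  expect_lt(abs(mean(predP == y[1:60]) - 1 / 3), 0.25)
  # single-class training -> constant predictor
  predC <- rfcBaseline(X[y == 1, ], rep(1L, sum(y == 1)), X, seed = 2)
  expect_true(all(predC == 1L))
  expect_error(rfcBaseline(X, y[-1], X), "mismatch")
})
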