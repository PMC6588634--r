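test_that("the reference glia architecture yields exactly 35,770 parameters", {
  m <- buildCmn(cmnArchitecture(), nClasses = 2L, nChannels = 1L)
  expect_identical(countParameters(m), 35770L)
  # parameter count is architecture-pure: independent of init seed
  m2 <- buildCmn(cmnArchitecture(), nClasses = 2L, nChannels = 1L,
                 seed = 999L)
  expect_identical(countParameters(m2), 35770L)
  # a third output class adds exactly 30 weights + 1 bias
  m3 <- buildCmn(cmnArchitecture(), nClasses = 3L, nChannels = 1L)
  expect_identical(countParameters(m3) - 35770L, 31L)
  # flattened size before FC1: 31 filters x z=2 x 3 x 1 spatial
  fc1 <- Filter(function(l) identical(l$name, "fc L1"), m$layers)[[1]]
  expect_identical(nrow(fc1$W), 186L)
  # an oversized kernel errors naming the layer
  bad <- cmnArchitecture(filters = c(5L, 5L),
                         kernels = list(c(1, 5, 5), c(1, 99, 99)),
                         pools = list(c(1, 2, 2), c(1, 1, 1)), fc = 10L)
  expect_error(buildCmn(bad, 2L, 1L, inputSize = c(64L, 32L)), "conv L2")
  # z kernel size must stay 1 (shared filters across views)
  expect_error(cmnArchitecture(kernels = list(c(2, 5, 5), c(1, 5, 5),
                                              c(1, 4, 4), c(1, 4, 4),
                                              c(1, 2, 2), c(1, 1, 1),
                                              c(1, 1, 1))), "z kernel")
})

test_that("tripletLoss evaluates its closed-form definition", {
  # all-zero embeddings: r = 0, alpha = 0.2 > 0, lambda2 = 0 -> 0.2
  expect_equal(tripletLoss(c(0, 0), c(0, 0), c(0, 0)), 0.2)
  # ref = plus = e1, minus = e2: alpha = 0.2 - sqrt(2) < 0 -> lambda2 = 1
  expect_equal(tripletLoss(c(1, 0), c(1, 0), c(0, 1)), 1)
  # swapping plus and minus never decreases the margin term
  set.seed(17)
  for (i in 1:20) {
    r <- rnorm(6); p <- rnorm(6); m <- rnorm(6)
    l1 <- tripletLoss(r, p, m); l2 <- tripletLoss(r, m, p)
    lam2 <- (sqrt(sum(r^2)) + sqrt(sum(p^2)) + sqrt(sum(m^2))) / 3
    expect_gte(l1, 0)
    # direct evaluation of its closed-form definition as oracle
    a <- sqrt(sum((r - p)^2)) - sqrt(sum((r - m)^2)) + 0.2
    expect_equal(l1, if (a > 0) a + lam2 else lam2, tolerance = 1e-12)
    expect_gte(l2 + l1, 2 * lam2)   # at most one of the two margins < 0
  }
  expect_error(tripletLoss(1:3, 1:3, 1:2), "mismatch")
})

test_that("assembleNviews follows the 2M/N splitting rule", {
  ids <- sprintf("v%03d", 1:100)
  sets <- assembleNviews(ids, 10L, shuffle = TRUE, seed = 4)
  expect_identical(length(sets), 10L)
  expect_true(all(lengths(sets) == 10L))
  expect_setequal(unlist(sets), ids)              # disjoint, no reuse
  expect_identical(anyDuplicated(unlist(sets)), 0L)
  # padded case: 6 views, N = 10 -> one set with all 6 plus 4 redraws
  s2 <- assembleNviews(ids[1:6], 10L, seed = 4)
  expect_identical(length(s2), 1L)
  expect_identical(length(s2[[1]]), 10L)
  expect_true(all(ids[1:6] %in% s2[[1]]))
  expect_true(all(s2[[1]] %in% ids[1:6]))
  # unshuffled sets keep creation order (contiguous blocks)
  s3 <- assembleNviews(ids, 10L, shuffle = FALSE)
  expect_identical(s3[[1]], ids[1:10])
  expect_identical(s3[[7]], ids[61:70])
  # shuffle on/off yields the same multiset of views (N dividing 2M)
  expect_setequal(unlist(assembleNviews(ids, 20L, shuffle = TRUE, seed = 1)),
                  unlist(assembleNviews(ids, 20L, shuffle = FALSE)))
  expect_error(assembleNviews(character(0), 5L), "no views")
})

test_that("majorityVote breaks ties by probability then class index", {
  expect_identical(majorityVote(c(1L, 1L, 2L)), 1L)
  expect_identical(majorityVote(3L), 3L)
  pr <- rbind(c(0.9, 0.1), c(0.5, 0.5), c(0.2, 0.8), c(0.3, 0.7))
  # labels 1,1,2,2: tie; summed probs class1 = 1.9 > class2 = 1.5... use
  # hand-computed sums: col1 = 0.9+0.5+0.2+0.3 = 1.9, col2 = 2.1 -> class 2
  expect_identical(majorityVote(c(1L, 1L, 2L, 2L), pr), 2L)
  # equal sums -> lowest class index
  pr2 <- rbind(c(0.6, 0.4), c(0.4, 0.6))
  expect_identical(majorityVote(c(1L, 2L), pr2), 1L)
  expect_identical(majorityVote(c(1L, 2L)), 1L)   # no probs: lowest index
})

test_that("knnEmbedClassify matches a brute-force kNN", {
  set.seed(23)
  tr <- rbind(matrix(rnorm(100, mean = 0), 50, 2),
              matrix(rnorm(100, mean = 6), 50, 2))
  lab <- rep(1:2, each = 50)
  q <- rbind(matrix(rnorm(40, mean = 0), 20, 2),
             matrix(rnorm(40, mean = 6), 20, 2))
  pred <- knnEmbedClassify(tr, lab, q, k = 5)
  expect_gte(mean(pred == rep(1:2, each = 20)), 0.95)
  # query equal to a training point with k = 1 returns its label
  expect_identical(knnEmbedClassify(tr, lab, tr[7, , drop = FALSE], k = 1),
                   1L)
  # brute-force agreement on random data
  tr2 <- matrix(rnorm(300), 100, 3); lab2 <- sample(1:3, 100, TRUE)
  q2 <- matrix(rnorm(60), 20, 3)
  got <- knnEmbedClassify(tr2, lab2, q2, k = 5)
  ref <- apply(q2, 1, function(x) {
    d <- sqrt(colSums((t(tr2) - x)^2))
    nb <- lab2[order(d)[1:5]]
    tb <- table(nb)
    min(as.integer(names(tb)[tb == max(tb)]))
  })
  expect_identical(got, as.integer(ref))
  expect_error(knnEmbedClassify(matrix(numeric(0), 0, 3), integer(0), q2),
               "empty")
})

test_that("pcaColor maps embeddings to vertex RGB", {
  mesh <- cubeMesh(edge = 1000)
  locs <- rbind(c(0, 0, 0), c(1000, 0, 0), c(0, 1000, 0), c(1000, 1000, 1000))
  # identical embeddings -> one uniform color
  E0 <- matrix(1, 4, 6)
  c0 <- pcaColor(E0, locs, mesh)
  expect_identical(nrow(c0), nVertices(mesh))
  expect_true(all(apply(c0, 2, function(x) diff(range(x))) < 1e-12))
  # variation along one latent axis -> exactly one RGB channel varies
  E1 <- matrix(0, 4, 6); E1[, 3] <- c(0, 1, 2, 3)
  c1 <- pcaColor(E1, locs, mesh)
  varying <- apply(c1, 2, function(x) diff(range(x)) > 1e-9)
  expect_identical(sum(varying), 1L)
  # vertex -> location assignment equals a brute-force nearest scan
  set.seed(2)
  E2 <- matrix(rnorm(24), 4, 6)
  c2 <- pcaColor(E2, locs, mesh)
  nnRef <- apply(vertices(mesh), 1, function(v) {
    which.min(colSums((t(locs) - v)^2))
  })
  pc <- prcomp(E2)$x[, 1:3]
  sc <- apply(pc, 2, function(x) (x - min(x)) / diff(range(x)))
  expect_equal(c2, sc[nnRef, ], ignore_attr = TRUE)
  # fewer than 3 locations -> flagged grayscale
  cg <- pcaColor(E2[1:2, ], locs[1:2, ], mesh)
  expect_true(attr(cg, "grayscale"))
  expect_identical(cg[, 1], cg[, 2])
})

test_that("a small classifier learns a separable view task", {
  # synthetic 2-class images: bright blob left vs right
  set.seed(6)
  mk <- function(side) {
    a <- array(0, dim = c(16, 8, 1, 2))
    rows <- if (side == 1) 2:6 else 10:14
    a[rows, 3:6, 1, ] <- 200
    a + array(runif(length(a), 0, 30), dim = dim(a))
  }
  samples <- c(replicate(20, mk(1), simplify = FALSE),
               replicate(20, mk(2), simplify = FALSE))
  labels <- rep(1:2, each = 20)
  arch <- cmnArchitecture(filters = c(4L, 6L),
                          kernels = list(c(1, 3, 3), c(1, 3, 3)),
                          pools = list(c(1, 2, 2), c(1, 1, 1)), fc = 8L)
  m <- buildCmn(arch, 2L, 1L, inputSize = c(16L, 8L), z = 2L, seed = 3)
  m <- trainCmnClassifier(m, samples, labels,
                          trainConfig(steps = 60L, batchSize = 10L,
                                      lr = 2e-3, seed = 8))
  pred <- apply(predictCmn(m, samples), 1, which.max)
  expect_gte(mean(pred == labels), 0.95)
  # training loss decreased
  tr <- attr(m, "lossTrace")
  expect_lt(mean(tail(tr, 5)), 0.9 * mean(head(tr, 5)))
})
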