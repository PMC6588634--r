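test_that("classifySv combines mean threshold and the 70% vote rule", {
  cfg <- svClassificationConfig(theta = 0.5)
  # 8/10 glia votes, mean 0.75 -> glia
  expect_identical(classifySv(c(rep(0.9, 8), 0.1, 0.05), cfg), 1L)
  # 6/10 glia votes (< 70%) even with high mean -> neuron
  p <- c(rep(0.99, 6), rep(0.45, 4))
  expect_identical(classifySv(p, cfg), 0L)
  # mean exactly theta -> neuron (strict >)
  expect_identical(classifySv(rep(0.5, 4), cfg), 0L)
  expect_error(classifySv(numeric(0)), "no view")
  # theta tuning maximizes glia F1 on validation data
  set.seed(3)
  probs <- c(lapply(1:20, function(i) runif(8, 0.6, 1)),
             lapply(1:20, function(i) runif(8, 0, 0.4)))
  truth <- rep(c(1L, 0L), each = 20)
  tuned <- tuneTheta(probs, truth)
  pred <- vapply(probs, classifySv, integer(1), config = tuned)
  expect_identical(pred, truth)
})

test_that("splitSsv resolves the quoted textbook cases", {
  mkGraph <- function(labels, large, edges) {
    n <- length(labels)
    ids <- LETTERS[seq_len(n)]
    meshes <- lapply(seq_len(n), function(i) {
      half <- if (large[i]) 5e3 else 250
      TriangleMesh(rbind(c(-half, -half, -half), c(half, half, half)))
    })
    SupervoxelGraph(ids, meshes, labels = labels,
                    edges = cbind(ids[edges[, 1]], ids[edges[, 2]]))
  }
  # all neuron chain -> one neuron SSV, no glia
  g1 <- mkGraph(c(0L, 0L, 0L), c(TRUE, TRUE, TRUE), rbind(1:2, 2:3))
  r1 <- splitSsv(g1)
  expect_identical(length(r1$neuron), 1L)
  expect_identical(length(r1$glia), 0L)
  # large glia between two large neurons -> glia removed, neurons split
  g2 <- mkGraph(c(0L, 1L, 0L), c(TRUE, TRUE, TRUE), rbind(1:2, 2:3))
  r2 <- splitSsv(g2)
  expect_identical(length(r2$neuron), 2L)
  expect_identical(length(r2$glia), 1L)
  expect_setequal(r2$glia[[1]], "B")
  # small glia bridged into a single neuron SSV
  g3 <- mkGraph(c(0L, 1L, 0L), c(TRUE, FALSE, TRUE), rbind(1:2, 2:3))
  r3 <- splitSsv(g3)
  expect_identical(length(r3$neuron), 1L)
  expect_setequal(r3$neuron[[1]], c("A", "B", "C"))
  expect_identical(length(r3$glia), 0L)
  expect_error(splitSsv(mkGraph(c(0L, NA, 0L), rep(TRUE, 3),
                                rbind(1:2, 2:3))), "unlabeled")
})

test_that("splitSsv output partitions the node set (fuzz)", {
  for (seed in 1:60) {
    rg <- randomLabeledGraph(n = sample(3:9, 1), seed = seed)
    boxes <- nodeBoxes(rg$large)
    got <- cellmorph:::.splitGraph(rg$n, rg$edges, rg$glia, boxes)
    all_ <- c(unlist(got$neuron), unlist(got$glia))
    expect_identical(sort(all_), seq_len(rg$n))
    # oracle agreement
    ref <- splitOracle(rg$n, rg$edges, rg$glia, boxes)
    expect_identical(canonicalSets(got$neuron), canonicalSets(ref$neuron))
    expect_identical(canonicalSets(got$glia), canonicalSets(ref$glia))
  }
})

test_that("raising the BBD threshold never removes more glia components", {
  for (seed in 1:10) {
    rg <- randomLabeledGraph(n = 8, seed = seed)
    boxes <- nodeBoxes(rg$large)
    nRemoved <- vapply(c(4, 8, 12, 20), function(th) {
      r <- cellmorph:::.splitGraph(rg$n, rg$edges, rg$glia, boxes, th)
      sum(r$log$action == "extract_glia")
    }, numeric(1))
    expect_true(all(diff(nRemoved) <= 0))
  }
})

test_that("re-running splitSsv on its neuron outputs is a no-op", {
  for (seed in 1:10) {
    rg <- randomLabeledGraph(n = 8, seed = seed)
    boxes <- nodeBoxes(rg$large)
    r <- cellmorph:::.splitGraph(rg$n, rg$edges, rg$glia, boxes)
    for (cc in r$neuron) {
      sub <- rg$edges[rg$edges[, 1] %in% cc & rg$edges[, 2] %in% cc, ,
                      drop = FALSE]
      remap <- match(seq_len(rg$n), cc)
      e2 <- cbind(remap[sub[, 1]], remap[sub[, 2]])
      # after the split every kept SV counts as neuron
      r2 <- cellmorph:::.splitGraph(length(cc), e2,
                                    rep(FALSE, length(cc)),
                                    boxes[cc, , drop = FALSE])
      expect_identical(length(r2$glia), 0L)
      expect_identical(canonicalSets(r2$neuron),
                       canonicalSets(list(seq_along(cc))))
    }
  }
})

test_that("assembleGliaCells assigns SVs to the nearest soma by path", {
  # single soma, chain of locations -> all assigned
  locs <- list(s1 = matrix(c(0, 0, 0), 1, 3),
               s2 = matrix(c(5000, 0, 0), 1, 3),
               s3 = matrix(c(10000, 0, 0), 1, 3))
  soma <- matrix(c(-2000, 0, 0), 1, 3)
  a <- assembleGliaCells(locs, soma, k = 3, maxDist = 10000)
  expect_true(all(a$soma == 1L))
  # SV adjacent to soma 1 goes to soma 1
  soma2 <- rbind(c(-2000, 0, 0), c(12000, 0, 0))
  a2 <- assembleGliaCells(locs, soma2, k = 3, maxDist = 10000)
  expect_identical(a2$soma[a2$sv == "s1"], 1L)
  expect_identical(a2$soma[a2$sv == "s3"], 2L)
  # unreachable SV flagged unassigned
  locs2 <- c(locs, list(far = matrix(c(1e6, 0, 0), 1, 3)))
  a3 <- assembleGliaCells(locs2, soma, k = 3, maxDist = 10000)
  expect_true(is.na(a3$soma[a3$sv == "far"]))
  expect_error(assembleGliaCells(locs, matrix(numeric(0), 0, 3)), "soma")
  # random instance vs a brute-force all-pairs shortest path oracle
  set.seed(44)
  P <- matrix(runif(150, 0, 20000), 50, 3)
  svLoc <- split.data.frame(P, rep(1:10, each = 5))
  names(svLoc) <- paste0("sv", 1:10)
  svLoc <- lapply(svLoc, as.matrix)
  seeds <- matrix(runif(6, 0, 20000), 2, 3)
  got <- assembleGliaCells(svLoc, seeds, k = 15, maxDist = 10000)
  # oracle: dense Floyd-Warshall on the same kNN graph definition
  allP <- rbind(do.call(rbind, svLoc), seeds)
  np <- nrow(allP)
  D <- matrix(Inf, np, np); diag(D) <- 0
  dm <- as.matrix(dist(allP))
  for (i in seq_len(np)) {
    nb <- order(dm[i, ])[2:min(16, np)]
    nb <- nb[dm[i, nb] <= 10000]
    D[i, nb] <- dm[i, nb]; D[nb, i] <- dm[i, nb]
  }
  for (k_ in seq_len(np)) for (i in seq_len(np)) {
    upd <- D[i, k_] + D[k_, ]
    better <- upd < D[i, ]
    D[i, better] <- upd[better]
  }
  seedRows <- (np - 1):np
  owner <- rep(paste0("sv", 1:10), each = 5)
  for (sv in paste0("sv", 1:10)) {
    rows <- which(owner == sv)
    dd <- D[rows, seedRows, drop = FALSE]
    if (all(is.infinite(dd))) {
      expect_true(is.na(got$soma[got$sv == sv]))
    } else {
      best <- which(dd == min(dd), arr.ind = TRUE)[1, ]
      expect_identical(got$soma[got$sv == sv], as.integer(best[2]))
      expect_equal(got$dist[got$sv == sv], min(dd), tolerance = 1e-9)
    }
  }
})

test_that("evaluateSplit scores sides and counts new neuron splits", {
  ids <- c("A", "B", "C", "D")
  meshes <- lapply(1:4, function(i) TriangleMesh(matrix(rnorm(3), 1, 3)))
  g <- SupervoxelGraph(ids, meshes, volumes = c(99, 1, 50, 50),
                       labels = c(0L, 1L, 0L, 0L),
                       edges = rbind(c("A", "B"), c("B", "C"),
                                     c("C", "D")))
  truth <- c(A = 0L, B = 1L, C = 0L, D = 0L)
  # perfect split: glia = {B}; neuron components {A}, {C, D}
  perfect <- structure(list(neuron = list("A", c("C", "D")),
                            glia = list("B"),
                            log = data.frame()), class = "splitResult")
  ev <- evaluateSplit(perfect, g, truth)
  expect_true(all(ev$perClass$f1 == 1))
  expect_true(all(ev$weighted$f1 == 1))
  # ground truth neuron components: {A} and {C,D} -> no new splits
  expect_identical(ev$newNeuronSplits, 0L)
  # one small SV wrong: B (1 um^3) predicted neuron while A (99) right
  g2 <- SupervoxelGraph(ids[1:2], meshes[1:2], volumes = c(99, 1),
                        labels = c(0L, 1L),
                        edges = rbind(c("A", "B")))
  wrong <- structure(list(neuron = list(c("A", "B")), glia = list(),
                          log = data.frame()), class = "splitResult")
  ev2 <- evaluateSplit(wrong, g2, c(A = 0L, B = 1L))
  # volume-weighted neuron recall 1, precision 99/100
  expect_equal(ev2$weighted["neuron", "precision"], 0.99)
  expect_equal(ev2$perClass["neuron", "precision"], 0.5)
  # splitting a gt component into two predicted SSVs counts one new split
  split2 <- structure(list(neuron = list("C", "D"), glia = list(c("A", "B")),
                           log = data.frame()), class = "splitResult")
  ev3 <- evaluateSplit(split2, g, truth)
  expect_identical(ev3$newNeuronSplits, 1L)
  expect_error(evaluateSplit(perfect, g, truth[1:2]), "cover")
})
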