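#' @include skeleton.R
NULL

#' Feature configuration for the skeleton node descriptor
#'
#' @param context maximal traversed path length from the source node, nm
#'   (4 or 8 µm in the reference setting).
#' @param histBreaks diameter histogram bin edges, nm; 10 bins with fixed
#'   edges 0-2000 nm in 200 nm steps, the last bin open above.
#' @return a list with class \code{"featureConfig"}.
#' @export
featureConfig <- function(context = 4000,
                          histBreaks = c(seq(0, 1800, by = 200), Inf)) {
  stopifnot(context > 0, length(histBreaks) == 11L)
  structure(list(context = context, histBreaks = histBreaks),
            class = "featureConfig")
}

#' Names of the 23 skeleton node features
#' @return character vector of length 23.
#' @export
featureNames <- function() {
  c("diam_mean", "diam_sd", paste0("diam_hist", 1:10), "degree_mean",
    "node_density",
    "mi_count", "mi_size_mean", "mi_size_sd",
    "sj_count", "sj_size_mean", "sj_size_sd",
    "vc_count", "vc_size_mean", "vc_size_sd")
}

## shortest-path distances (nm) from one source over skeleton edges
.skeletonDistances <- function(skeleton, from = NULL) {
  n <- nrow(skeleton@nodes)
  e <- skeleton@edges
  w <- if (nrow(e)) sqrt(rowSums((skeleton@nodes[e[, 1], , drop = FALSE] -
                                  skeleton@nodes[e[, 2], , drop = FALSE])^2))
       else numeric(0)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(e)) g <- igraph::add_edges(g, t(e))
  igraph::distances(g, v = if (is.null(from)) igraph::V(g) else from,
                    weights = w)
}

#' Assign organelles to their nearest skeleton nodes
#'
#' Each (mapped) organelle is assigned to the skeleton node closest to its
#' voxel centroid.
#'
#' @param skeleton a \linkS4class{Skeleton}.
#' @param organelles list of organelle objects (fields \code{class},
#'   \code{size} and either \code{center} (nm) or \code{voxels} +
#'   \code{voxelSize}).
#' @return data.frame with columns \code{class}, \code{size}, \code{node}.
#' @export
assignOrganellesToNodes <- function(skeleton, organelles) {
  if (!length(organelles))
    return(data.frame(class = character(0), size = integer(0),
                      node = integer(0)))
  ctr <- do.call(rbind, lapply(organelles, function(o) {
    if (!is.null(o$center)) o$center
    else colMeans((o$voxels + 0.5) %*% diag(o$voxelSize))
  }))
  nn <- .knn(skeleton@nodes, ctr, 1L)
  data.frame(class = vapply(organelles, `[[`, character(1), "class"),
             size = vapply(organelles, function(o)
               if (!is.null(o$size)) o$size else nrow(o$voxels), numeric(1)),
             node = nn$index[, 1])
}

#' Extract the 23-component skeleton node feature vector
#'
#' Features are computed from the nodes reachable within the context path
#' length (source included): mean and population s.d. of node diameters
#' (2 x radius), a 10-bin diameter histogram (normalized by traversed node
#' count), mean node degree, node density within the axis-aligned cube of
#' edge 2 x context centered on the source (per µm³), and per organelle
#' class (MI, SJ, VC, restricted to organelles assigned to traversed
#' nodes): count, mean size and population s.d. of size (voxels). The s.d.
#' of one or zero values is 0.
#'
#' @param skeleton a \linkS4class{Skeleton} with radii.
#' @param node source node index; \code{NULL} computes all nodes.
#' @param organelleAssignments data.frame from
#'   \code{\link{assignOrganellesToNodes}}.
#' @param config a \code{\link{featureConfig}}.
#' @return a numeric vector of length 23 (named per
#'   \code{\link{featureNames}}), or a matrix (nodes x 23) when
#'   \code{node} is NULL.
#' @export
extractFeatures <- function(skeleton, node = NULL,
                            organelleAssignments = NULL,
                            config = featureConfig()) {
  if (is.null(organelleAssignments))
    organelleAssignments <- assignOrganellesToNodes(skeleton, list())
  if (is.null(node)) {
    D <- .skeletonDistances(skeleton)
    out <- t(vapply(seq_len(nrow(skeleton@nodes)), function(i)
      .featuresFromDist(skeleton, i, D[i, ], organelleAssignments, config),
      numeric(23L)))
    colnames(out) <- featureNames()
    return(out)
  }
  d <- .skeletonDistances(skeleton, from = node)[1, ]
  .featuresFromDist(skeleton, node, d, organelleAssignments, config)
}

.featuresFromDist <- function(skeleton, node, d, orgAssign, config) {
  trav <- which(d <= config$context)
  diam <- 2 * skeleton@radii[trav]
  nT <- length(trav)
  sdPop <- function(x) if (length(x) <= 1L) 0 else
    sqrt(mean((x - mean(x))^2))
  h <- tabulate(.bincode(diam, config$histBreaks, right = FALSE),
                nbins = 10L)
  h <- if (nT) h / nT else rep(0, 10)
  deg <- tabulate(skeleton@edges, nbins = nrow(skeleton@nodes))
  src <- skeleton@nodes[node, ]
  half <- config$context
  inBox <- abs(skeleton@nodes[trav, 1] - src[1]) <= half &
           abs(skeleton@nodes[trav, 2] - src[2]) <= half &
           abs(skeleton@nodes[trav, 3] - src[3]) <= half
  dens <- sum(inBox) / (2 * config$context / 1e3)^3
  orgF <- unlist(lapply(c("MI", "SJ", "VC"), function(cl) {
    sz <- orgAssign$size[orgAssign$class == cl & orgAssign$node %in% trav]
    c(length(sz), if (length(sz)) mean(sz) else 0, sdPop(sz))
  }))
  out <- c(if (nT) mean(diam) else 0, sdPop(diam), h,
           if (nT) mean(deg[trav]) else 0, dens, orgF)
  names(out) <- featureNames()
  out
}

#' Sliding-window majority vote over skeleton labels
#'
#' Every node is assigned the majority label among the nodes within the
#' traversal window (maximum path length along the skeleton, source
#' included). Ties keep the node's original label.
#'
#' @param skeleton a \linkS4class{Skeleton}.
#' @param labels integer labels, one per node.
#' @param window maximal traversal length, nm (default 12.5 µm).
#' @return integer vector of smoothed labels.
#' @export
slidingMajorityVote <- function(skeleton, labels, window = 12500) {
  n <- nrow(skeleton@nodes)
  stopifnot(length(labels) == n)
  D <- .skeletonDistances(skeleton)
  out <- labels
  for (i in seq_len(n)) {
    lab <- labels[D[i, ] <= window]
    tb <- table(lab)
    top <- as.integer(names(tb)[tb == max(tb)])
    if (length(top) == 1L) out[i] <- top
  }
  out
}

#' Voronoi label propagation
#'
#' Each query point takes the label of its nearest labeled point (Euclidean
#' distance); exact distance ties go to the lowest label code.
#'
#' @param labeledPoints k x 3 matrix (nm).
#' @param labels integer labels of the labeled points.
#' @param queryPoints m x 3 matrix (nm).
#' @return integer labels, one per query point.
#' @export
voronoiPropagate <- function(labeledPoints, labels, queryPoints) {
  labeledPoints <- as.matrix(labeledPoints)
  if (!nrow(labeledPoints)) stop("voronoiPropagate: no labeled points")
  stopifnot(length(labels) == nrow(labeledPoints))
  queryPoints <- as.matrix(queryPoints)
  nn <- .knn(labeledPoints, queryPoints, min(8L, nrow(labeledPoints)))
  vapply(seq_len(nrow(queryPoints)), function(i) {
    tied <- nn$dist[i, ] <= nn$dist[i, 1] + 1e-9
    min(labels[nn$index[i, tied]])
  }, numeric(1)) |> as.integer()
}

#' Random-forest baseline on skeleton features
#'
#' Multi-class random forest on the 23-feature node descriptor; prediction
#' is the argmax of the class probabilities. Seeded and reproducible.
#'
#' @param trainFeatures matrix with 23 columns.
#' @param trainLabels integer/factor labels (one per row).
#' @param testFeatures matrix with 23 columns.
#' @param ntree number of trees.
#' @param seed RNG seed.
#' @return integer vector of predicted labels for the test rows.
#' @export
rfcBaseline <- function(trainFeatures, trainLabels, testFeatures,
                        ntree = 200L, seed = 1L) {
  trainFeatures <- as.matrix(trainFeatures)
  testFeatures <- as.matrix(testFeatures)
  if (nrow(trainFeatures) != length(trainLabels))
    stop("rfcBaseline: feature/label length mismatch")
  stopifnot(ncol(trainFeatures) == 23L, ncol(testFeatures) == 23L)
  y <- factor(trainLabels)
  if (nlevels(y) == 1L)   # degenerate: constant predictor
    return(rep(as.integer(levels(y)), nrow(testFeatures)))
  fit <- .withSeed(seed,
    randomForest::randomForest(trainFeatures, y, ntree = ntree))
  pr <- predict(fit, testFeatures, type = "prob")
  cls <- as.integer(colnames(pr))
  apply(pr, 1L, function(p) min(cls[p == max(p)]))
}
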