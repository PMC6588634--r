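#' @include cmn-train.R
NULL

#' Triplet (Neuron2vec) training configuration
#'
#' @param dz latent dimension (10 or 25).
#' @param lambda1 margin parameter of the triplet loss (0.2).
#' @param nR positive-neighborhood size: with nR = 1 the similar view is
#'   the rotated view of the same rendering location; with nR > 1 views
#'   from the nR - 1 nearest rendering locations of the same cell are also
#'   eligible.
#' @param phi rotation between the two views at one location, degrees (50
#'   in the reference setting; applied at render time).
#' @return a list with class \code{"tripletConfig"}.
#' @export
tripletConfig <- function(dz = 10L, lambda1 = 0.2, nR = 1L, phi = 50) {
  stopifnot(dz >= 1L, lambda1 > 0, nR >= 1L)
  structure(list(dz = as.integer(dz), lambda1 = lambda1,
                 nR = as.integer(nR), phi = phi),
            class = "tripletConfig")
}

#' Assemble a view corpus for embedding training
#'
#' @param views list of single-view arrays (x, y, channels).
#' @param cell integer cell id per view.
#' @param location n x 3 matrix of rendering locations (nm) per view.
#' @param persp perspective index per view (1 = aligned, 2 = rotated).
#' @return a list with class \code{"viewCorpus"}.
#' @export
viewCorpus <- function(views, cell, location, persp) {
  stopifnot(length(views) == length(cell),
            nrow(location) == length(cell),
            length(persp) == length(cell))
  structure(list(views = views, cell = as.integer(cell),
                 location = as.matrix(location), persp = as.integer(persp)),
            class = "viewCorpus")
}

## per-view candidate positive indices under the nR rule
.positivePools <- function(corpus, nR) {
  n <- length(corpus$views)
  locKey <- paste(corpus$cell, corpus$location[, 1], corpus$location[, 2],
                  corpus$location[, 3])
  pools <- vector("list", n)
  for (i in seq_len(n)) {
    sameLoc <- which(locKey == locKey[i])
    cand <- setdiff(sameLoc, i)
    if (nR > 1L) {
      sameCell <- which(corpus$cell == corpus$cell[i] & locKey != locKey[i])
      if (length(sameCell)) {
        uniqLoc <- !duplicated(locKey[sameCell])
        locs <- corpus$location[sameCell[uniqLoc], , drop = FALSE]
        d2 <- rowSums(sweep(locs, 2L, corpus$location[i, ], `-`)^2)
        nearKeys <- locKey[sameCell[uniqLoc]][order(d2)[
          seq_len(min(nR - 1L, length(d2)))]]
        cand <- c(cand, sameCell[locKey[sameCell] %in% nearKeys])
      }
    }
    pools[[i]] <- if (length(cand)) cand else i
  }
  pools
}

#' Train a Neuron2vec triplet encoder
#'
#' Each training triplet consists of a reference view, a similar view
#' (the rotated view of the same rendering location, or with nR > 1 a view
#' from one of the nR - 1 nearest locations of the same cell) and a
#' dissimilar view drawn from a different cell.
#'
#' @param model a triplet encoder from \code{\link{buildTripletCmn}}.
#' @param corpus a \code{\link{viewCorpus}} spanning at least 2 cells.
#' @param tconfig a \code{\link{tripletConfig}}.
#' @param config a \code{\link{trainConfig}} (batchSize = triplets per
#'   step).
#' @return the trained model with attribute \code{"lossTrace"}.
#' @export
trainTriplet <- function(model, corpus, tconfig = tripletConfig(),
                         config = trainConfig()) {
  stopifnot(inherits(corpus, "viewCorpus"))
  if (length(unique(corpus$cell)) < 2L)
    stop("trainTriplet: corpus must span at least 2 cells (no valid x-)")
  pools <- .positivePools(corpus, tconfig$nR)
  Xn <- lapply(corpus$views, function(v) {
    if (length(dim(v)) == 2L) dim(v) <- c(dim(v), 1L)
    v / 255
  })
  n <- length(Xn)
  .withSeed(config$seed, {
    state <- .optimInit(model)
    trace <- numeric(config$steps)
    for (t in seq_len(config$steps)) {
      iR <- sample(n, config$batchSize, replace = TRUE)
      iP <- vapply(iR, function(i) {
        p <- pools[[i]]
        if (length(p) == 1L) p else sample(p, 1L)
      }, integer(1))
      iM <- vapply(iR, function(i) {
        cand <- which(corpus$cell != corpus$cell[i])
        cand[sample.int(length(cand), 1L)]
      }, integer(1))
      X <- .stackSamples(c(Xn[iR], Xn[iP], Xn[iM]))
      fw <- nnForward(model, X, training = TRUE)
      E <- fw$out
      B <- config$batchSize
      dR <- E[seq_len(B), , drop = FALSE] -
            E[B + seq_len(B), , drop = FALSE]
      dMm <- E[seq_len(B), , drop = FALSE] -
             E[2L * B + seq_len(B), , drop = FALSE]
      rp <- sqrt(rowSums(dR^2)); rm <- sqrt(rowSums(dMm^2))
      alpha <- rp - rm + tconfig$lambda1
      nrm <- sqrt(rowSums(E^2))
      trace[t] <- mean(ifelse(alpha > 0, alpha, 0) +
                       (nrm[seq_len(B)] + nrm[B + seq_len(B)] +
                        nrm[2L * B + seq_len(B)]) / 3)
      dE <- .tripletLossBatch(E, tconfig$lambda1)
      bw <- nnBackward(model, fw$caches, dE)
      up <- .optimStep(model, bw$grads, state, t, config$lr, config)
      model <- up$model; state <- up$state
    }
    attr(model, "lossTrace") <- trace
    model
  })
}

#' k-nearest-neighbor classification on embeddings
#'
#' Uniform-weight majority among the k nearest training embeddings
#' (Euclidean distance); ties go to the lowest class code.
#'
#' @param trainEmbeddings matrix (n x d).
#' @param trainLabels integer labels.
#' @param queryEmbeddings matrix (m x d).
#' @param k neighbors (default 5).
#' @return integer labels for the queries.
#' @export
knnEmbedClassify <- function(trainEmbeddings, trainLabels, queryEmbeddings,
                             k = 5L) {
  trainEmbeddings <- as.matrix(trainEmbeddings)
  if (!nrow(trainEmbeddings)) stop("knnEmbedClassify: empty training set")
  stopifnot(k <= nrow(trainEmbeddings))
  as.integer(.knnVote(trainEmbeddings, as.integer(trainLabels),
                      as.matrix(queryEmbeddings), k))
}

#' PCA RGB coloring of a mesh from location embeddings
#'
#' The first three principal components of the location embeddings are
#' min-max scaled to [0, 1] per channel and used as RGB; every mesh vertex
#' takes the color of its nearest rendering location. With fewer than 3
#' locations a flagged grayscale fallback (first PC only) is returned.
#'
#' @param embeddings matrix (locations x d).
#' @param locations matrix (locations x 3), nm.
#' @param mesh a \linkS4class{TriangleMesh}.
#' @return matrix (vertices x 3) of RGB values in [0, 1]; attribute
#'   \code{"grayscale"} is TRUE for the fallback.
#' @export
pcaColor <- function(embeddings, locations, mesh) {
  embeddings <- as.matrix(embeddings)
  locations <- as.matrix(locations)
  stopifnot(nrow(embeddings) == nrow(locations))
  gray <- nrow(embeddings) < 3L
  scale01 <- function(x) {
    r <- range(x)
    if (diff(r) < 1e-12) rep(0.5, length(x)) else (x - r[1]) / diff(r)
  }
  if (gray) {
    v <- scale01(embeddings[, 1])
    cols <- cbind(v, v, v)
  } else {
    pc <- stats::prcomp(embeddings, center = TRUE, scale. = FALSE)
    k <- min(3L, ncol(pc$x))
    S <- pc$x[, seq_len(k), drop = FALSE]
    if (k < 3L) S <- cbind(S, matrix(0, nrow(S), 3L - k))
    cols <- apply(S, 2L, scale01)
  }
  nn <- .knn(locations, mesh@vertices, 1L)
  out <- cols[nn$index[, 1], , drop = FALSE]
  attr(out, "grayscale") <- gray
  out
}
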