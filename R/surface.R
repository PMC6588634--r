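#' @include render.R cmn-arch.R
NULL

SURFACE_CLASSES <- c(neck = 1L, head = 2L, shaft = 3L, other = 4L)

#' Vertex proximity graph of a mesh
#'
#' Edges connect vertex pairs within \code{maxDist} (default 120 nm),
#' independent of mesh topology. Grid hashing keeps the construction
#' near-linear.
#'
#' @param mesh a \linkS4class{TriangleMesh}.
#' @param maxDist maximal edge length, nm.
#' @return adjacency list (integer vectors, one per vertex).
#' @export
vertexGraph <- function(mesh, maxDist = 120) {
  V <- mesh@vertices
  n <- nrow(V)
  cellIdx <- floor(V / maxDist)
  key <- paste(cellIdx[, 1], cellIdx[, 2], cellIdx[, 3])
  byCell <- split(seq_len(n), key)
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  adj <- vector("list", n)
  for (ci in names(byCell)) {
    members <- byCell[[ci]]
    base <- cellIdx[members[1], ]
    keys <- paste(base[1] + nb[, 1], base[2] + nb[, 2], base[3] + nb[, 3])
    cand <- unlist(byCell[keys], use.names = FALSE)
    for (i in members) {
      d2 <- (V[cand, 1] - V[i, 1])^2 + (V[cand, 2] - V[i, 2])^2 +
            (V[cand, 3] - V[i, 3])^2
      adj[[i]] <- cand[d2 <= maxDist^2 & cand != i]
    }
  }
  adj
}

#' Smooth per-vertex labels by bounded breadth-first majority
#'
#' Every vertex is assigned the majority label of the first \code{nBfs}
#' vertices (default 40) reached by a breadth-first search from it on the
#' vertex graph (fewer when the component is smaller); ties keep the
#' original label.
#'
#' @param mesh a \linkS4class{TriangleMesh}.
#' @param labels integer labels, one per vertex.
#' @param nBfs vertices collected per BFS.
#' @param graph optional precomputed \code{\link{vertexGraph}}.
#' @param maxDist edge length for the vertex graph, nm.
#' @return integer vector of smoothed labels.
#' @export
smoothVertexLabels <- function(mesh, labels, nBfs = 40L, graph = NULL,
                               maxDist = 120) {
  n <- nVertices(mesh)
  if (!n) stop("smoothVertexLabels: empty mesh")
  stopifnot(length(labels) == n)
  if (is.null(graph)) graph <- vertexGraph(mesh, maxDist)
  out <- labels
  for (i in seq_len(n)) {
    coll <- .bfsCollect(graph, i, nBfs)
    tb <- table(labels[coll])
    top <- as.integer(names(tb)[tb == max(tb)])
    if (length(top) == 1L) out[i] <- top
  }
  out
}

## first nMax vertices in BFS order (source first; within a level, by index)
.bfsCollect <- function(adj, start, nMax) {
  visited <- c(start)
  seen <- new.env(hash = TRUE)
  assign(as.character(start), TRUE, envir = seen)
  frontier <- start
  while (length(visited) < nMax && length(frontier)) {
    nxt <- sort(unique(unlist(adj[frontier], use.names = FALSE)))
    nxt <- nxt[!vapply(as.character(nxt), exists, logical(1),
                       envir = seen)]
    if (!length(nxt)) break
    for (v in nxt) assign(as.character(v), TRUE, envir = seen)
    take <- nxt[seq_len(min(length(nxt), nMax - length(visited)))]
    visited <- c(visited, take)
    frontier <- nxt
  }
  visited
}

#' Build the surface segmentation model
#'
#' VGG-style fully convolutional encoder-decoder for per-pixel multi-class
#' prediction on single multi-channel views: stacked same-padded 3 x 3
#' convolutions with ReLU, 2 x 2 max pooling in the encoder, nearest
#' upsampling in the decoder and a final 1 x 1 class layer. The default
#' depth is scaled by \code{width}; with \code{width = 1} the encoder has
#' 13 weight layers.
#'
#' @param nClasses output classes (5: neck, head, shaft, background,
#'   axon/soma).
#' @param nChannels input channels (4: cell, MI, SJ, VC).
#' @param filters filter counts of the encoder stages.
#' @param seed RNG seed.
#' @return a model object (class \code{"cmnModel"}, kind "segmenter").
#' @export
buildSurfaceModel <- function(nClasses = 5L, nChannels = 4L,
                              filters = c(8L, 16L, 24L), seed = 1L) {
  .withSeed(seed, {
    layers <- list()
    C <- nChannels
    for (i in seq_along(filters)) {
      layers[[length(layers) + 1L]] <-
        .convLayer(sprintf("enc%d", i), C, filters[i], c(3L, 3L),
                   pad = "same")
      layers[[length(layers) + 1L]] <- list(type = "relu")
      if (i < length(filters))
        layers[[length(layers) + 1L]] <- list(type = "pool",
                                              size = c(2L, 2L))
      C <- filters[i]
    }
    for (i in rev(seq_len(length(filters) - 1L))) {
      layers[[length(layers) + 1L]] <- list(type = "upsample", factor = 2L)
      layers[[length(layers) + 1L]] <-
        .convLayer(sprintf("dec%d", i), C, filters[i], c(3L, 3L),
                   pad = "same")
      layers[[length(layers) + 1L]] <- list(type = "relu")
      C <- filters[i]
    }
    layers[[length(layers) + 1L]] <-
      .convLayer("out", C, nClasses, c(1L, 1L), pad = "same")
    structure(list(layers = layers, z = 1L, nClasses = as.integer(nClasses),
                   nChannels = as.integer(nChannels), kind = "segmenter"),
              class = "cmnModel")
  })
}

#' Train the surface segmentation model
#'
#' Mini-batch Adam training of per-pixel classification with the
#' Lovász-Softmax loss (cross-entropy available as fallback); views are
#' flipped in x or y with probability 0.5 as augmentation.
#'
#' @param model from \code{\link{buildSurfaceModel}}.
#' @param views list of arrays (x, y, channels), 8-bit.
#' @param labelImages list of integer matrices (x, y) with 1-based class
#'   labels; must match the view sizes.
#' @param config a \code{\link{trainConfig}} (reference setting: Adam,
#'   lr 4e-3, exponential decay 0.99).
#' @param loss \code{"lovasz"} or \code{"ce"}.
#' @return the trained model with attribute \code{"lossTrace"}.
#' @export
trainSurfaceModel <- function(model, views, labelImages,
                              config = trainConfig(lr = 4e-3,
                                                   lrDecay = c(0.99, 100)),
                              loss = c("lovasz", "ce")) {
  loss <- match.arg(loss)
  stopifnot(length(views) == length(labelImages))
  for (i in seq_along(views))
    if (!all(dim(views[[i]])[1:2] == dim(labelImages[[i]])))
      stop("trainSurfaceModel: view/label shape mismatch at ", i)
  Xn <- lapply(views, function(v) {
    if (length(dim(v)) == 2L) dim(v) <- c(dim(v), 1L)
    v / 255
  })
  .withSeed(config$seed, {
    state <- .optimInit(model)
    trace <- numeric(config$steps)
    for (t in seq_len(config$steps)) {
      idx <- sample(seq_along(Xn), config$batchSize,
                    replace = length(Xn) < config$batchSize)
      xs <- Xn[idx]; ys <- labelImages[idx]
      for (q in seq_along(xs)) {
        if (stats::runif(1) < 0.5) {
          xs[[q]] <- xs[[q]][rev(seq_len(dim(xs[[q]])[1])), , , drop = FALSE]
          ys[[q]] <- ys[[q]][rev(seq_len(nrow(ys[[q]]))), , drop = FALSE]
        }
        if (stats::runif(1) < 0.5) {
          xs[[q]] <- xs[[q]][, rev(seq_len(dim(xs[[q]])[2])), , drop = FALSE]
          ys[[q]] <- ys[[q]][, rev(seq_len(ncol(ys[[q]]))), drop = FALSE]
        }
      }
      X <- .stackSamples(xs)
      fw <- nnForward(model, X, training = TRUE)
      d <- dim(fw$out)  # (H, W, K, b)
      Z <- matrix(aperm(fw$out, c(1, 2, 4, 3)), ncol = d[3])
      lab <- unlist(lapply(ys, as.vector))
      ls <- .segLoss(Z, lab, type = loss)
      trace[t] <- ls$loss
      dZ <- array(ls$dZ, dim = c(d[1], d[2], d[4], d[3]))
      bw <- nnBackward(model, fw$caches, aperm(dZ, c(1, 2, 4, 3)))
      lr <- config$lr
      if (!is.null(config$lrDecay))
        lr <- lr * config$lrDecay[1]^(t / config$lrDecay[2])
      up <- .optimStep(model, bw$grads, state, t, lr, config)
      model <- up$model; state <- up$state
    }
    attr(model, "lossTrace") <- trace
    model
  })
}

#' Per-pixel class prediction
#'
#' @param model a segmenter from \code{\link{buildSurfaceModel}}.
#' @param view array (x, y, channels), 8-bit.
#' @return integer matrix (x, y) of 1-based class labels.
#' @export
predictSurface <- function(model, view) {
  if (length(dim(view)) == 2L) dim(view) <- c(dim(view), 1L)
  dim(view) <- c(dim(view), 1L)
  out <- nnForward(model, view / 255, training = FALSE)$out
  d <- dim(out)
  apply(out[, , , 1, drop = FALSE], c(1, 2), which.max) |>
    matrix(d[1], d[2])
}

#' Back-map pixel labels onto mesh vertices
#'
#' Every non-background pixel of every label map contributes one vote for
#' its label to each of the three vertices of the face it shows (via the
#' matching face-ID map). Vertices take their majority label (ties to the
#' lowest class code); uncovered vertices stay NA.
#'
#' @param labelMaps list of integer matrices (x, y) of pixel labels;
#'   \code{backgroundClass} pixels are ignored.
#' @param faceIdMaps list of integer matrices from
#'   \code{\link{renderFaceIds}} (same cameras, same order).
#' @param mesh the rendered \linkS4class{TriangleMesh}.
#' @param nClasses number of classes.
#' @param backgroundClass label treated as background (default 0; pass the
#'   background class index of the pixel model when it has one).
#' @return a list with class \code{"surfaceLabeling"}: \code{labels}
#'   (integer per vertex, NA = uncovered) and \code{provenance} (character
#'   per vertex).
#' @export
backmapLabels <- function(labelMaps, faceIdMaps, mesh, nClasses = 4L,
                          backgroundClass = 0L) {
  stopifnot(length(labelMaps) == length(faceIdMaps))
  nV <- nVertices(mesh)
  votes <- matrix(0L, nV, nClasses)
  F <- mesh@faces
  for (q in seq_along(labelMaps)) {
    lm <- labelMaps[[q]]; fm <- faceIdMaps[[q]]
    if (!all(dim(lm) == dim(fm)))
      stop("backmapLabels: camera mismatch (map sizes differ) at view ", q)
    sel <- fm >= 0L & lm != backgroundClass & lm >= 1L & lm <= nClasses
    if (!any(sel)) next
    fid <- fm[sel] + 1L
    lab <- lm[sel]
    for (corner in 1:3) {
      vi <- F[fid, corner]
      tab <- stats::aggregate(rep(1L, length(vi)),
                              by = list(v = vi, l = lab), FUN = sum)
      votes[cbind(tab$v, tab$l)] <- votes[cbind(tab$v, tab$l)] + tab$x
    }
  }
  labels <- rep(NA_integer_, nV)
  covered <- rowSums(votes) > 0L
  if (any(covered)) {
    labels[covered] <- apply(votes[covered, , drop = FALSE], 1L,
                             function(v) which(v == max(v))[1])
  }
  structure(list(labels = labels,
                 provenance = ifelse(covered, "backmapped", "uncovered")),
            class = "surfaceLabeling")
}

#' Fill uncovered vertices by kNN label propagation
#'
#' @param labeling a \code{"surfaceLabeling"} from
#'   \code{\link{backmapLabels}}.
#' @param mesh the mesh.
#' @param k neighbors (default 20).
#' @return the labeling with every vertex labeled; filled vertices carry
#'   provenance "knn-filled".
#' @export
knnFill <- function(labeling, mesh, k = 20L) {
  lab <- labeling$labels
  unl <- which(is.na(lab))
  if (!length(unl)) return(labeling)
  src <- which(!is.na(lab))
  if (!length(src)) stop("knnFill: no labeled vertices")
  V <- mesh@vertices
  filled <- .knnVote(V[src, , drop = FALSE], lab[src],
                     V[unl, , drop = FALSE], min(k, length(src)))
  lab[unl] <- as.integer(filled)
  labeling$labels <- lab
  labeling$provenance[unl] <- "knn-filled"
  labeling
}

#' Face coverage of a set of views
#'
#' Fraction of mesh faces visible in at least one face-ID map; monotone
#' non-decreasing in the set of views.
#'
#' @param faceIdMaps list of integer matrices (possibly from several
#'   locations and perspectives).
#' @param mesh the mesh (or the face count).
#' @return numeric fraction in [0, 1].
#' @export
coverage <- function(faceIdMaps, mesh) {
  nF <- if (is(mesh, "TriangleMesh")) nFaces(mesh) else as.integer(mesh)
  if (!length(faceIdMaps) || nF == 0L) return(0)
  seen <- unique(unlist(lapply(faceIdMaps, function(m) m[m >= 0L])))
  length(seen) / nF
}

#' Classify a synaptic contact as spinous or shaft
#'
#' Majority label among the k nearest labeled vertices of the contact
#' coordinate: head or neck votes give "spinous", shaft gives "shaft",
#' anything else is flagged "ambiguous". With fewer than k labeled
#' vertices all are used and the result is flagged.
#'
#' @param contact length-3 coordinate (nm).
#' @param labeling a \code{"surfaceLabeling"} (all vertices labeled).
#' @param mesh the labeled mesh.
#' @param k neighbors (default 20).
#' @param headOnly restrict the spinous class to spine heads.
#' @return character: "spinous", "shaft" or "ambiguous"; attribute
#'   \code{"partial"} when fewer than k labeled vertices existed.
#' @export
classifySynapseContact <- function(contact, labeling, mesh, k = 20L,
                                   headOnly = FALSE) {
  lab <- labeling$labels
  src <- which(!is.na(lab))
  if (!length(src)) stop("classifySynapseContact: unlabeled surface")
  partial <- length(src) < k
  vote <- .knnVote(mesh@vertices[src, , drop = FALSE], lab[src],
                   matrix(as.numeric(contact), 1, 3), min(k, length(src)))
  spin <- if (headOnly) SURFACE_CLASSES[["head"]]
          else c(SURFACE_CLASSES[["head"]], SURFACE_CLASSES[["neck"]])
  out <- if (vote %in% spin) "spinous"
         else if (vote == SURFACE_CLASSES[["shaft"]]) "shaft"
         else "ambiguous"
  if (partial) attr(out, "partial") <- TRUE
  out
}
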