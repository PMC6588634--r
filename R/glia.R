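#' @include AllClasses.R geometry-utils.R
NULL

#' Supervoxel classification / splitting configuration
#'
#' @param theta glia probability threshold (mean multi-view glia
#'   probability must be strictly above theta).
#' @param voteFraction minimum fraction of views whose argmax is glia
#'   (default 0.7).
#' @param bbdThreshold bounding-box-diagonal threshold in µm for the
#'   splitting heuristic (default 8.0; glia removal uses >= , the
#'   neuron-to-glia demotion uses <).
#' @return a list with class \code{"svClassificationConfig"}.
#' @export
svClassificationConfig <- function(theta = 0.5, voteFraction = 0.7,
                                   bbdThreshold = 8.0) {
  stopifnot(theta >= 0, theta <= 1, voteFraction >= 0, voteFraction <= 1,
            bbdThreshold > 0)
  structure(list(theta = theta, voteFraction = voteFraction,
                 bbdThreshold = bbdThreshold),
            class = "svClassificationConfig")
}

#' Classify one supervoxel from its multi-view glia probabilities
#'
#' A supervoxel is glia iff the mean of its multi-view glia probabilities
#' is strictly above theta AND at least \code{voteFraction} of the views
#' have glia as their argmax (probability > 0.5).
#'
#' @param probs numeric vector of per-view glia probabilities (>= 1).
#' @param config a \code{\link{svClassificationConfig}}.
#' @return integer label: 1 (glia) or 0 (neuron).
#' @export
classifySv <- function(probs, config = svClassificationConfig()) {
  if (!length(probs)) stop("classifySv: no view predictions")
  gliaVotes <- mean(probs > 0.5)
  as.integer(mean(probs) > config$theta &&
             gliaVotes >= config$voteFraction)
}

#' Choose theta by maximizing F1 on validation predictions
#'
#' Scans theta over [0, 1] in steps of 0.01 and returns the threshold with
#' the best glia F1-score of the induced SV classification.
#'
#' @param viewProbs list of per-SV glia-probability vectors.
#' @param truth integer vector of true SV labels (1 = glia).
#' @param config base \code{\link{svClassificationConfig}}.
#' @return the config with optimized \code{theta}.
#' @export
tuneTheta <- function(viewProbs, truth, config = svClassificationConfig()) {
  thetas <- seq(0, 1, by = 0.01)
  f1 <- vapply(thetas, function(th) {
    cfg <- config; cfg$theta <- th
    pred <- vapply(viewProbs, classifySv, integer(1), config = cfg)
    tp <- sum(pred == 1L & truth == 1L)
    fp <- sum(pred == 1L & truth == 0L)
    fn <- sum(pred == 0L & truth == 1L)
    if (tp == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  config$theta <- thetas[which.max(f1)]
  config
}

## core of the splitting heuristic, operating on plain structures:
## edges: m x 2 integer; glia: logical per node; boxes: n x 6 matrix of
## per-node bounding boxes (xmin, ymin, zmin, xmax, ymax, zmax) in nm.
## Returns list(neuron = list of integer vectors, glia = ..., log = df).
.splitGraph <- function(n, edgesI, glia, boxes, bbdUm = 8.0) {
  ## adjacency list once; components by iterative DFS on integer vectors
  adj <- vector("list", n)
  if (nrow(edgesI)) {
    for (q in seq_len(nrow(edgesI))) {
      a <- edgesI[q, 1]; b <- edgesI[q, 2]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  subComponents <- function(keepL) {
    out <- list()
    seen <- !keepL
    for (s in seq_len(n)) {
      if (seen[s]) next
      stack <- s; seen[s] <- TRUE; cc <- integer(0)
      while (length(stack)) {
        u <- stack[length(stack)]; stack <- stack[-length(stack)]
        cc[length(cc) + 1L] <- u
        for (v in adj[[u]]) if (!seen[v]) {
          seen[v] <- TRUE; stack[length(stack) + 1L] <- v
        }
      }
      out[[length(out) + 1L]] <- cc
    }
    out
  }
  compBbd <- function(members) {
    if (length(members) == 1L) {
      d <- boxes[members, 4:6] - boxes[members, 1:3]
    } else {
      sub <- boxes[members, , drop = FALSE]
      d <- c(max(sub[, 4]) - min(sub[, 1]), max(sub[, 5]) - min(sub[, 2]),
             max(sub[, 6]) - min(sub[, 3]))
    }
    sqrt(sum(d * d)) / 1e3
  }
  lab <- glia
  logAction <- character(0); logSize <- integer(0); logBbd <- numeric(0)
  ## (1)+(2): glia-induced CCs; extract the large ones
  removed <- logical(n)
  for (cc in subComponents(lab)) {
    b <- compBbd(cc)
    if (b >= bbdUm) {
      removed[cc] <- TRUE
      logAction <- c(logAction, "extract_glia")
    } else {
      ## (3): small glia CCs are bridged into the neuron class
      lab[cc] <- FALSE
      logAction <- c(logAction, "bridge_glia")
    }
    logSize <- c(logSize, length(cc)); logBbd <- c(logBbd, b)
  }
  ## (4): neuron CCs on the reduced graph; demote the small ones
  demoted <- logical(n)
  for (cc in subComponents(!lab & !removed)) {
    b <- compBbd(cc)
    if (b < bbdUm) {
      demoted[cc] <- TRUE
      logAction <- c(logAction, "demote_neuron")
      logSize <- c(logSize, length(cc)); logBbd <- c(logBbd, b)
    }
  }
  ## (5): final CCs of each side
  list(neuron = subComponents(!lab & !removed & !demoted),
       glia = subComponents(removed | demoted),
       log = data.frame(action = logAction, size = logSize, bbd = logBbd))
}

#' Split glia merge errors out of an SSV
#'
#' Implements the top-down splitting heuristic on a labeled SV graph:
#' (1) compute the label-induced connected components; (2) glia components
#' with a bounding-box diagonal (BBD) >= 8 µm are separated into the glia
#' graph; (3) the remaining small glia components are relabeled neuron
#' (bridging small misclassifications); (4) neuron components of the
#' reduced graph with BBD < 8 µm are moved to the glia side; (5) the final
#' connected components of each side become individual neuron and glia
#' SSVs. Node BBDs are computed over the mesh vertices of the component's
#' SVs.
#'
#' @param graph a connected \linkS4class{SupervoxelGraph} with all SVs
#'   labeled (0 = neuron, 1 = glia).
#' @param config a \code{\link{svClassificationConfig}} (uses
#'   \code{bbdThreshold}).
#' @return a list with class \code{"splitResult"}: \code{neuron} and
#'   \code{glia} (lists of SV-id sets) and \code{log} (moved components
#'   with sizes and BBDs).
#' @export
splitSsv <- function(graph, config = svClassificationConfig()) {
  lab <- svLabels(graph)
  if (anyNA(lab)) stop("splitSsv: unlabeled SV(s): ",
                       paste(names(lab)[is.na(lab)], collapse = ", "))
  ids <- svIds(graph)
  n <- length(ids)
  edgesI <- cbind(match(graph@edges[, 1], ids),
                  match(graph@edges[, 2], ids))
  if (!nrow(graph@edges)) edgesI <- matrix(integer(0), 0, 2)
  boxes <- t(vapply(ids, function(i) {
    V <- graph@meshes[[i]]@vertices
    if (!nrow(V)) V <- graph@locations[[i]]
    if (!nrow(V) || anyNA(V))
      stop("splitSsv: SV '", i, "' has neither mesh vertices nor sample ",
           "locations; BBDs cannot be computed")
    c(apply(V, 2, min), apply(V, 2, max))
  }, numeric(6)))
  r <- .splitGraph(n, edgesI, lab == 1L, boxes, config$bbdThreshold)
  structure(list(neuron = lapply(r$neuron, function(x) ids[x]),
                 glia = lapply(r$glia, function(x) ids[x]),
                 log = r$log),
            class = "splitResult")
}

#' Assemble glia cells around soma seeds
#'
#' Builds a location graph over all glia SV sample locations and the soma
#' seed coordinates (edges to the up-to-k nearest locations within
#' \code{maxDist}, weighted by Euclidean distance) and assigns every SV to
#' the soma with the smallest shortest-path (Dijkstra) distance from any of
#' the SV's locations. Unreachable SVs are reported as unassigned (NA).
#'
#' @param locations named list: per SV, a matrix of sample locations (nm).
#' @param somaSeeds matrix (s x 3) of soma coordinates (nm).
#' @param k nearest-neighbor degree of the location graph (default 15).
#' @param maxDist maximum edge length, nm (default 10 µm).
#' @return data.frame with columns \code{sv}, \code{soma} (seed index or
#'   NA), \code{dist} (nm).
#' @export
assembleGliaCells <- function(locations, somaSeeds, k = 15L,
                              maxDist = 10000) {
  somaSeeds <- as.matrix(somaSeeds)
  if (!nrow(somaSeeds)) stop("assembleGliaCells: no soma seeds")
  svNames <- names(locations)
  stopifnot(!is.null(svNames))
  P <- do.call(rbind, c(locations, list(somaSeeds)))
  owner <- c(rep(svNames, vapply(locations, nrow, integer(1))),
             rep(NA_character_, nrow(somaSeeds)))
  seedIdx <- which(is.na(owner))
  nP <- nrow(P)
  kk <- min(k + 1L, nP)
  nn <- .knn(P, P, kk)
  ei <- rep(seq_len(nP), each = kk - 1L)
  ej <- as.vector(t(nn$index[, -1, drop = FALSE]))
  ew <- as.vector(t(nn$dist[, -1, drop = FALSE]))
  keep <- ew <= maxDist
  g <- igraph::make_empty_graph(nP, directed = FALSE)
  g <- igraph::add_edges(g, rbind(ei[keep], ej[keep]))
  D <- igraph::distances(g, v = seedIdx, weights = ew[keep])
  best <- apply(D, 2L, min)
  bestSoma <- apply(D, 2L, which.min)
  out <- lapply(svNames, function(sv) {
    rows <- which(owner == sv)
    d <- best[rows]
    if (all(is.infinite(d)))
      data.frame(sv = sv, soma = NA_integer_, dist = NA_real_)
    else {
      i <- rows[which.min(d)]
      data.frame(sv = sv, soma = as.integer(bestSoma[i]), dist = best[i])
    }
  })
  do.call(rbind, out)
}

#' Evaluate a split result against ground truth
#'
#' Per-class precision/recall/F1 of the final side assignment, unweighted
#' (per SV) and volume-weighted (each SV weighted by its voxel volume),
#' plus the number of newly introduced neuron splits: for every
#' ground-truth neuron component (components of the graph restricted to
#' truly-neuron SVs) the number of predicted neuron SSVs intersecting it
#' minus one, summed.
#'
#' @param result a \code{"splitResult"} from \code{\link{splitSsv}}.
#' @param graph the input \linkS4class{SupervoxelGraph}.
#' @param truth named integer vector of true SV labels (0 neuron, 1 glia)
#'   covering all SVs.
#' @param volumes named numeric SV volumes (µm³); defaults to the graph's.
#' @return a list with \code{perClass} (data.frame), \code{weighted}
#'   (data.frame) and \code{newNeuronSplits} (integer).
#' @export
evaluateSplit <- function(result, graph, truth, volumes = svVolumes(graph)) {
  ids <- svIds(graph)
  if (!all(ids %in% names(truth)))
    stop("evaluateSplit: ground truth must cover all SVs")
  pred <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  for (s in result$neuron) pred[s] <- 0L
  for (s in result$glia) pred[s] <- 1L
  tr <- truth[ids]
  if (anyNA(volumes[ids]))
    stop("evaluateSplit: missing volumes")
  prf <- function(w) {
    do.call(rbind, lapply(c(neuron = 0L, glia = 1L), function(cl) {
      tp <- sum(w[pred == cl & tr == cl])
      fp <- sum(w[pred == cl & tr != cl])
      fn <- sum(w[pred != cl & tr == cl])
      p <- if (tp + fp > 0) tp / (tp + fp) else 0
      r <- if (tp + fn > 0) tp / (tp + fn) else 0
      data.frame(precision = p, recall = r,
                 f1 = if (p + r > 0) 2 * p * r / (p + r) else 0)
    }))
  }
  perClass <- prf(stats::setNames(rep(1, length(ids)), ids))
  weighted <- prf(volumes[ids])
  ## new neuron splits relative to ground-truth neuron components
  gtComp <- connectedComponents(graph, ids[tr == 0L])
  splits <- 0L
  for (cc in gtComp) {
    hit <- sum(vapply(result$neuron, function(s)
      any(cc %in% s), logical(1)))
    splits <- splits + max(0L, hit - 1L)
  }
  list(perClass = perClass, weighted = weighted,
       newNeuronSplits = splits)
}
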