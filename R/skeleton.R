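#' @include AllClasses.R geometry-utils.R
NULL

#' Merge skeleton parts into one connected skeleton
#'
#' The parts are combined and, while more than one connected component
#' remains, an edge is added between the globally closest pair of nodes
#' lying in different components.
#'
#' @param parts list of \linkS4class{Skeleton} objects (>= 1).
#' @return a single connected \linkS4class{Skeleton}.
#' @export
mergeSkeletons <- function(parts) {
  stopifnot(length(parts) >= 1L)
  sk <- Reduce(.mergeSkeletonParts, parts)
  n <- nrow(sk@nodes)
  if (n == 0L) return(sk)
  comp <- .componentsUF(seq_len(n), sk@edges)
  newE <- list()
  while (length(unique(comp)) > 1L) {
    ## globally closest inter-component node pair at this iteration
    best <- c(Inf, NA, NA)
    for (ci in unique(comp)) {
      A <- which(comp == ci); B <- which(comp != ci)
      nn <- .knn(sk@nodes[B, , drop = FALSE], sk@nodes[A, , drop = FALSE], 1L)
      i <- which.min(nn$dist[, 1])
      if (nn$dist[i, 1] < best[1])
        best <- c(nn$dist[i, 1], A[i], B[nn$index[i, 1]])
    }
    a <- best[2]; b <- best[3]
    newE[[length(newE) + 1L]] <- c(a, b)
    comp[comp == comp[b]] <- comp[a]
  }
  if (length(newE))
    sk <- Skeleton(sk@nodes, rbind(sk@edges, do.call(rbind, newE)),
                   radii = sk@radii, nodeLabels = sk@nodeLabels)
  sk
}

#' Sparsify a skeleton by removing redundant degree-2 nodes
#'
#' A degree-2 node is removed (its two edges replaced by one) when the
#' summed length lambda of its adjacent edges is below \code{lambdaShort},
#' or when the dot product of the two unit edge vectors exceeds
#' \code{dotMin} while lambda stays below \code{lambdaDot}. Branch nodes
#' (degree >= 3) and end nodes (degree 1) are never removed. The rule is
#' applied repeatedly until a fixpoint is reached.
#'
#' @param skeleton a \linkS4class{Skeleton}.
#' @param lambdaShort nm threshold for unconditional removal (default 50).
#' @param dotMin minimum unit-edge dot product (default 0.8).
#' @param lambdaDot nm bound on lambda for the collinearity rule
#'   (default 500).
#' @return the sparsified \linkS4class{Skeleton}.
#' @export
sparsify <- function(skeleton, lambdaShort = 50, dotMin = 0.8,
                     lambdaDot = 500) {
  V <- skeleton@nodes
  n <- nrow(V)
  adj <- lapply(.adjList(n, skeleton@edges), identity)
  alive <- rep(TRUE, n)
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    for (u in seq_len(n)) {
      if (!alive[u] || length(adj[[u]]) != 2L) next
      a <- adj[[u]][1]; b <- adj[[u]][2]
      if (a == b) next
      e1 <- V[u, ] - V[a, ]; e2 <- V[b, ] - V[u, ]
      l1 <- sqrt(sum(e1^2)); l2 <- sqrt(sum(e2^2))
      lam <- l1 + l2
      dp <- if (l1 > 0 && l2 > 0) sum(e1 * e2) / (l1 * l2) else 1
      if (lam < lambdaShort || (dp > dotMin && lam < lambdaDot)) {
        alive[u] <- FALSE
        adj[[a]] <- unique(c(setdiff(adj[[a]], u), b))
        adj[[b]] <- unique(c(setdiff(adj[[b]], u), a))
        adj[[u]] <- integer(0)
        changed <- TRUE
      }
    }
  }
  keep <- which(alive)
  remap <- integer(n); remap[keep] <- seq_along(keep)
  e <- list()
  for (u in keep) for (v in adj[[u]]) if (u < v)
    e[[length(e) + 1L]] <- c(remap[u], remap[v])
  Skeleton(V[keep, , drop = FALSE],
           if (length(e)) do.call(rbind, e) else matrix(integer(0), 0, 2),
           radii = skeleton@radii[keep],
           nodeLabels = if (length(skeleton@nodeLabels))
             skeleton@nodeLabels[keep] else integer(0))
}

#' Estimate node radii from the surface mesh
#'
#' The cell radius at a skeleton node is the median of the distances to the
#' ten nearest mesh vertices. When the mesh has fewer than ten vertices all
#' of them are used and the result is flagged with attribute
#' \code{"partial"}.
#'
#' @param skeleton a \linkS4class{Skeleton} (or an n x 3 position matrix).
#' @param mesh a \linkS4class{TriangleMesh}.
#' @param k number of nearest vertices (default 10).
#' @return numeric vector of radii (nm), one per node.
#' @export
estimateRadius <- function(skeleton, mesh, k = 10L) {
  P <- if (is(skeleton, "Skeleton")) skeleton@nodes else as.matrix(skeleton)
  V <- mesh@vertices
  partial <- nrow(V) < k
  nn <- .knn(V, P, k)
  r <- apply(nn$dist, 1L, stats::median)
  if (partial) attr(r, "partial") <- TRUE
  r
}

#' Apply estimated radii to a skeleton
#'
#' @param skeleton a \linkS4class{Skeleton}.
#' @param mesh the surface \linkS4class{TriangleMesh}.
#' @param k nearest vertices used per node.
#' @return the skeleton with updated radii.
#' @export
withEstimatedRadii <- function(skeleton, mesh, k = 10L) {
  skeleton@radii <- as.numeric(estimateRadius(skeleton, mesh, k))
  skeleton
}
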