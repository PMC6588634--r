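#' @include synthetic-mesh.R
NULL

#' Synthesis configuration for the synthetic-data generators
#'
#' Collects every tunable of the seeded generators. All generators are pure
#' functions of this configuration: the same config (including seed) yields
#' byte-identical outputs. Lengths are in µm, radii in nm, densities per µm,
#' voxel sizes in nm.
#'
#' @param seed integer RNG seed.
#' @param nBranches number of neurite branches leaving the soma (dendrites
#'   and axons alternate).
#' @param branchLengthRange µm range branch lengths are drawn from.
#' @param tubeRadiusRange nm range of dendrite tube radii; axon radii are
#'   scaled down by \code{axonRadiusFactor}.
#' @param axonRadiusFactor multiplier applied to axon tube radii.
#' @param somaRadius soma sphere radius, µm (0 = no soma).
#' @param spineDensity dendritic spines per µm of dendrite.
#' @param spineHeadRadius,spineNeckRadius,spineNeckLength spine geometry, nm.
#' @param boutonDensity axonal bouton swellings per µm of axon.
#' @param gliaSheetCount number of undulating glia sheets.
#' @param gliaSheetSize µm extent (x, y) of one sheet.
#' @param gliaUndulation undulation amplitude, µm.
#' @param gliaThickness sheet thickness, nm.
#' @param gliaFilopodia number of thin filopodial processes per sheet.
#' @param organelleDensity named per-µm densities for the organelle classes
#'   MI (mitochondrion), SJ (synaptic junction), VC (vesicle cloud).
#' @param voxelSize nm voxel edges of the (anisotropic) label grid used for
#'   organelle voxel sets, e.g. \code{c(9, 9, 20)}.
#' @param svSegmentLength µm length of the supervoxel segments branches are
#'   cut into.
#' @param ringSpacing nm distance between tube rings (mesh resolution).
#' @param nSeg vertices per tube ring.
#' @return a named list with class \code{"synthesisConfig"}.
#' @export
synthesisConfig <- function(seed = 1L, nBranches = 4L,
                            branchLengthRange = c(8, 15),
                            tubeRadiusRange = c(350, 600),
                            axonRadiusFactor = 0.45,
                            somaRadius = 5,
                            spineDensity = 1.5,
                            spineHeadRadius = 250, spineNeckRadius = 80,
                            spineNeckLength = 600,
                            boutonDensity = 0.3,
                            gliaSheetCount = 1L, gliaSheetSize = c(8, 8),
                            gliaUndulation = 1, gliaThickness = 200,
                            gliaFilopodia = 4L,
                            organelleDensity = c(MI = 0.25, SJ = 0.3,
                                                 VC = 0.25),
                            voxelSize = c(9, 9, 20),
                            svSegmentLength = 5,
                            ringSpacing = 500, nSeg = 10L) {
  cfg <- list(seed = as.integer(seed), nBranches = as.integer(nBranches),
              branchLengthRange = branchLengthRange,
              tubeRadiusRange = tubeRadiusRange,
              axonRadiusFactor = axonRadiusFactor, somaRadius = somaRadius,
              spineDensity = spineDensity,
              spineHeadRadius = spineHeadRadius,
              spineNeckRadius = spineNeckRadius,
              spineNeckLength = spineNeckLength,
              boutonDensity = boutonDensity,
              gliaSheetCount = as.integer(gliaSheetCount),
              gliaSheetSize = gliaSheetSize,
              gliaUndulation = gliaUndulation,
              gliaThickness = gliaThickness,
              gliaFilopodia = as.integer(gliaFilopodia),
              organelleDensity = organelleDensity,
              voxelSize = voxelSize,
              svSegmentLength = svSegmentLength,
              ringSpacing = ringSpacing, nSeg = as.integer(nSeg))
  stopifnot(all(cfg$branchLengthRange > 0), all(cfg$tubeRadiusRange > 0),
            cfg$somaRadius >= 0, cfg$spineDensity >= 0,
            all(cfg$organelleDensity >= 0), all(cfg$voxelSize > 0),
            cfg$svSegmentLength > 0, cfg$ringSpacing > 0)
  class(cfg) <- "synthesisConfig"
  cfg
}

## surface class codes
SURFACE_NECK <- 1L; SURFACE_HEAD <- 2L; SURFACE_SHAFT <- 3L; SURFACE_OTHER <- 4L
## compartment codes (SWC convention)
COMP_SOMA <- 1L; COMP_AXON <- 2L; COMP_DENDRITE <- 3L

#' Generate a synthetic neuron with ground truth
#'
#' Builds a branched tubular neuron: a spherical soma, dendrites carrying
#' spines (neck + head, labeled per vertex) at the configured density, and
#' thinner axons with bouton swellings and vesicle clouds. The mesh is cut
#' into contiguous supervoxel segments of about \code{svSegmentLength} µm
#' along the skeleton, with adjacency edges between consecutive segments.
#' Organelles (MI inside neurites, VC at boutons, SJ straddling the membrane
#' at spine heads and boutons) are returned as sparse voxel sets on the
#' configured grid together with their surface meshes.
#'
#' @param config a \code{\link{synthesisConfig}}.
#' @return a \linkS4class{GroundTruthBundle}; SV ids are \code{n1, n2, ...}
#'   and all SV labels are 0 (neuron).
#' @examples
#' b <- makeNeuron(synthesisConfig(seed = 7, nBranches = 2,
#'                                 branchLengthRange = c(5, 6),
#'                                 voxelSize = c(40, 40, 40)))
#' b
#' @export
makeNeuron <- function(config = synthesisConfig()) {
  stopifnot(inherits(config, "synthesisConfig"))
  if (config$nBranches == 0L && config$somaRadius == 0)
    stop("makeNeuron: need at least a soma or one branch")
  .withSeed(config$seed, .makeNeuronImpl(config))
}

.makeNeuronImpl <- function(config) {
  um <- 1e3
  svMesh <- list(); svVol <- numeric(0); svLoc <- list(); svEdge <- list()
  skNodes <- list(); skLab <- integer(0); skRad <- numeric(0)
  skEdge <- list(); skSV <- integer(0)   # owning SV index per skeleton node
  organelles <- list()
  svN <- 0L
  newSV <- function(mesh, vol, loc) {
    svN <<- svN + 1L
    svMesh[[svN]] <<- mesh; svVol[svN] <<- vol
    svLoc[[svN]] <<- loc
    svN
  }
  somaSV <- 0L
  if (config$somaRadius > 0) {
    rs <- config$somaRadius * um
    soma <- .sphereMesh(c(0, 0, 0), rs, nLat = 10L, nLon = 14L,
                        label = SURFACE_OTHER)
    somaSV <- newSV(soma, 4 / 3 * pi * config$somaRadius^3,
                    matrix(0, 1, 3))
    skNodes[[1]] <- c(0, 0, 0); skLab[1] <- COMP_SOMA; skRad[1] <- rs
    skSV[1] <- somaSV
  }
  nBr <- config$nBranches
  for (b in seq_len(nBr)) {
    isDend <- (b %% 2L == 1L)
    comp <- if (isDend) COMP_DENDRITE else COMP_AXON
    L <- stats::runif(1, config$branchLengthRange[1],
                      config$branchLengthRange[2]) * um
    dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
    step <- config$ringSpacing
    k <- max(2L, ceiling(L / step) + 1L)
    centers <- matrix(0, k, 3)
    centers[1, ] <- dir * config$somaRadius * um
    d <- dir
    for (i in 2:k) {
      d <- d + stats::rnorm(3, sd = 0.12)
      d <- d / sqrt(sum(d^2))
      centers[i, ] <- centers[i - 1, ] + d * step
    }
    arc <- c(0, cumsum(sqrt(rowSums(diff(centers)^2))))
    r0 <- stats::runif(1, config$tubeRadiusRange[1],
                       config$tubeRadiusRange[2])
    if (!isDend) r0 <- r0 * config$axonRadiusFactor
    ringR <- rep(r0, k)
    boutonPos <- numeric(0)
    if (!isDend && config$boutonDensity > 0) {
      nBou <- stats::rpois(1, config$boutonDensity * L / um)
      boutonPos <- sort(stats::runif(nBou, 0.1, 0.9)) * arc[k]
      for (s0 in boutonPos)
        ringR <- ringR + r0 * 1.1 * exp(-((arc - s0) / 400)^2)
    }
    label <- if (isDend) SURFACE_SHAFT else SURFACE_OTHER
    ## skeleton chain for this branch
    nOff <- length(skLab)
    for (i in seq_len(k)) {
      skNodes[[nOff + i]] <- centers[i, ]
      skLab[nOff + i] <- comp; skRad[nOff + i] <- ringR[i]
    }
    for (i in seq_len(k - 1L))
      skEdge[[length(skEdge) + 1L]] <- c(nOff + i, nOff + i + 1L)
    if (somaSV > 0L)
      skEdge[[length(skEdge) + 1L]] <- c(1L, nOff + 1L)
    ## spines on dendrites
    spines <- list()   # per spine: ring index, mesh
    if (isDend && config$spineDensity > 0) {
      nSp <- stats::rpois(1, config$spineDensity * L / um)
      for (s in seq_len(nSp)) {
        ri <- sample(2:(k - 1L), 1L)
        tangent <- centers[min(ri + 1L, k), ] - centers[max(ri - 1L, 1L), ]
        tangent <- tangent / sqrt(sum(tangent^2))
        perp <- .anyPerp(tangent)
        ang <- stats::runif(1, 0, 2 * pi)
        R <- .rotationAboutAxis(tangent, ang)
        outd <- as.vector(R %*% perp)
        base <- centers[ri, ] + outd * ringR[ri]
        tip <- base + outd * config$spineNeckLength
        neck <- .tubeMesh(rbind(base, (base + tip) / 2, tip),
                          rep(config$spineNeckRadius, 3), nSeg = 6L,
                          label = SURFACE_NECK, cap = FALSE)
        headC <- tip + outd * config$spineHeadRadius * 0.8
        head <- .sphereMesh(headC, config$spineHeadRadius, nLat = 5L,
                            nLon = 8L, label = SURFACE_HEAD)
        spines[[length(spines) + 1L]] <-
          list(ring = ri, mesh = mergeMeshes(list(neck, head)),
               headCenter = headC, outd = outd)
        ## synaptic junction straddling the spine-head membrane
        if (config$organelleDensity[["SJ"]] > 0 &&
            stats::runif(1) < min(1, config$organelleDensity[["SJ"]] /
                                     config$spineDensity)) {
          sjC <- headC + outd * config$spineHeadRadius
          organelles[[length(organelles) + 1L]] <-
            .makeOrganelle("SJ", sjC,
                           c(config$spineHeadRadius * 0.9,
                             config$spineHeadRadius * 0.9, 130),
                           .frameWithZ(outd), config$voxelSize)
        }
      }
    }
    ## organelles inside the lumen
    nMI <- stats::rpois(1, config$organelleDensity[["MI"]] * L / um)
    for (s in seq_len(nMI)) {
      s0 <- stats::runif(1, 0.05, 0.95) * arc[k]
      ri <- which.min(abs(arc - s0))
      tangent <- centers[min(ri + 1L, k), ] - centers[max(ri - 1L, 1L), ]
      tangent <- tangent / sqrt(sum(tangent^2))
      organelles[[length(organelles) + 1L]] <-
        .makeOrganelle("MI", centers[ri, ],
                       c(600, 0.45 * r0, 0.45 * r0),
                       .frameWithZ(tangent, zIsX = TRUE), config$voxelSize)
    }
    if (!isDend) {
      for (s0 in boutonPos) {  # vesicle cloud in each bouton
        ri <- which.min(abs(arc - s0))
        organelles[[length(organelles) + 1L]] <-
          .makeOrganelle("VC", centers[ri, ], rep(0.8 * max(ringR), 3),
                         diag(3), config$voxelSize)
        if (config$organelleDensity[["SJ"]] > 0) {
          tangent <- centers[min(ri + 1L, k), ] - centers[max(ri - 1L, 1L), ]
          tangent <- tangent / sqrt(sum(tangent^2))
          outd <- .anyPerp(tangent)
          organelles[[length(organelles) + 1L]] <-
            .makeOrganelle("SJ", centers[ri, ] + outd * ringR[ri],
                           c(300, 300, 130), .frameWithZ(outd),
                           config$voxelSize)
        }
      }
    }
    ## cut the branch into SV segments of ~svSegmentLength µm
    segId <- pmin(floor(arc / (config$svSegmentLength * um)),
                  max(0, floor(arc[k] / (config$svSegmentLength * um))))
    prevSV <- somaSV
    for (g in sort(unique(segId))) {
      rings <- which(segId == g)
      lo <- max(1L, rings[1] - 1L)           # share the cut ring
      sub <- lo:rings[length(rings)]
      if (length(sub) < 2L) next
      tube <- .tubeMesh(centers[sub, , drop = FALSE], ringR[sub],
                        nSeg = config$nSeg, label = label,
                        cap = (g == 0 && somaSV == 0L) ||
                              g == max(segId))
      segSpines <- Filter(function(sp) sp$ring %in% rings, spines)
      msh <- mergeMeshes(c(list(tube), lapply(segSpines, `[[`, "mesh")))
      segLen <- (arc[sub[length(sub)]] - arc[sub[1]]) / um
      vol <- pi * (r0 / um)^2 * segLen
      sv <- newSV(msh, vol, centers[rings, , drop = FALSE])
      for (i in rings) skSV[nOff + i] <- sv
      if (prevSV > 0L)
        svEdge[[length(svEdge) + 1L]] <- c(prevSV, sv)
      prevSV <- sv
    }
  }
  ids <- paste0("n", seq_len(svN))
  em <- if (length(svEdge)) {
    e <- do.call(rbind, svEdge)
    cbind(ids[e[, 1]], ids[e[, 2]])
  } else matrix(character(0), 0, 2)
  graph <- SupervoxelGraph(ids, svMesh, volumes = svVol, locations = svLoc,
                           labels = rep(0L, svN), edges = em)
  skel <- Skeleton(do.call(rbind, skNodes),
                   if (length(skEdge)) do.call(rbind, skEdge)
                   else matrix(integer(0), 0, 2),
                   radii = skRad, nodeLabels = skLab)
  mesh <- mergeMeshes(svMesh)
  new("GroundTruthBundle", mesh = mesh, skeleton = skel, svGraph = graph,
      organelles = organelles,
      plantedEdges = matrix(character(0), 0, 2),
      config = unclass(config))
}

## rotation with given unit z axis (or x axis when zIsX)
.frameWithZ <- function(z, zIsX = FALSE) {
  z <- z / sqrt(sum(z^2))
  a <- .anyPerp(z); b <- .cross3(z, a)
  if (zIsX) cbind(z, a, b) else cbind(a, b, z)
}

## organelle object: sparse voxel set + surface mesh
.makeOrganelle <- function(class, center, semiAxes, R, voxelSize) {
  vox <- .ellipsoidVoxels(center, semiAxes, R, voxelSize)
  list(class = class, center = center, semiAxes = semiAxes, rotation = R,
       voxels = vox, size = nrow(vox),
       mesh = .ellipsoidMesh(center, semiAxes, R))
}

#' Plant a neuron-glia merge error
#'
#' Joins a neuron bundle and a glia bundle into a single connected SSV graph
#' by adding \code{nBridges} edges between the spatially nearest
#' neuron-SV/glia-SV pairs (minimum vertex-to-vertex distance). Unless
#' \code{offset} is given, the glia fragment is first translated so its
#' bounding box abuts the neuron's with a small gap, emulating an
#' astrocyte-neurite merger.
#'
#' @param neuron,glia \linkS4class{GroundTruthBundle}s from
#'   \code{\link{makeNeuron}} / \code{\link{makeGliaFragment}}.
#' @param nBridges number of bridge edges (>= 1).
#' @param offset optional length-3 nm translation applied to the glia bundle
#'   (\code{c(0, 0, 0)} keeps it in place).
#' @param gap nm clearance used by the automatic placement.
#' @return a \linkS4class{GroundTruthBundle} whose \code{svGraph} contains
#'   both label populations (0 = neuron, 1 = glia) and whose
#'   \code{plantedEdges} records the bridges.
#' @export
plantMergeError <- function(neuron, glia, nBridges = 1L, offset = NULL,
                            gap = 500) {
  stopifnot(is(neuron, "GroundTruthBundle"), is(glia, "GroundTruthBundle"))
  if (nBridges < 1L) stop("plantMergeError: nBridges must be >= 1")
  if (!length(neuron@svGraph@ids) || !length(glia@svGraph@ids))
    stop("plantMergeError: both bundles must be non-empty")
  if (is.null(offset)) {
    nr <- apply(neuron@mesh@vertices, 2, range)
    gr <- apply(glia@mesh@vertices, 2, range)
    offset <- c(nr[2, 1] + gap - gr[1, 1],
                mean(nr[, 2]) - mean(gr[, 2]),
                mean(nr[, 3]) - mean(gr[, 3]))
  }
  glia <- translateBundle(glia, offset)
  ng <- neuron@svGraph; gg <- glia@svGraph
  ids <- c(ng@ids, gg@ids)
  if (anyDuplicated(ids)) stop("plantMergeError: SV ids collide")
  meshes <- c(ng@meshes, gg@meshes)
  ## nearest pairs by minimum vertex-vertex distance, exhaustive over pairs
  pairD <- expand.grid(a = ng@ids, b = gg@ids, stringsAsFactors = FALSE)
  pairD$d <- mapply(function(a, b)
    .minPointSetDist(meshes[[a]]@vertices, meshes[[b]]@vertices),
    pairD$a, pairD$b)
  pairD <- pairD[order(pairD$d), , drop = FALSE]
  nB <- min(nBridges, nrow(pairD))
  bridges <- cbind(pairD$a[seq_len(nB)], pairD$b[seq_len(nB)])
  graph <- SupervoxelGraph(
    ids, meshes,
    volumes = c(ng@volumes, gg@volumes),
    locations = c(ng@locations, gg@locations),
    labels = c(ng@labels, gg@labels),
    probs = c(ng@probs, gg@probs),
    edges = rbind(ng@edges, gg@edges, bridges))
  lab <- c(neuron@mesh@vertexLabels, glia@mesh@vertexLabels)
  new("GroundTruthBundle",
      mesh = mergeMeshes(list(neuron@mesh, glia@mesh)),
      skeleton = .mergeSkeletonParts(neuron@skeleton, glia@skeleton),
      svGraph = graph,
      organelles = c(neuron@organelles, glia@organelles),
      plantedEdges = bridges,
      config = neuron@config)
}

## disjoint union of two skeletons (no new edges)
.mergeSkeletonParts <- function(a, b) {
  off <- nrow(a@nodes)
  Skeleton(rbind(a@nodes, b@nodes),
           rbind(a@edges, b@edges + off),
           radii = c(a@radii, b@radii),
           nodeLabels = c(
             if (length(a@nodeLabels)) a@nodeLabels else rep(NA_integer_, nrow(a@nodes)),
             if (length(b@nodeLabels)) b@nodeLabels else rep(NA_integer_, nrow(b@nodes))))
}

#' Translate every geometric part of a bundle
#'
#' @param bundle a \linkS4class{GroundTruthBundle}.
#' @param offset length-3 nm translation.
#' @return the translated bundle.
#' @export
translateBundle <- function(bundle, offset) {
  offset <- as.numeric(offset)
  shift <- function(m) sweep(m, 2L, offset, `+`)
  mesh <- bundle@mesh
  mesh@vertices <- shift(mesh@vertices)
  sk <- bundle@skeleton
  sk@nodes <- shift(sk@nodes)
  g <- bundle@svGraph
  g@meshes <- lapply(g@meshes, function(m) {
    m@vertices <- shift(m@vertices); m
  })
  g@locations <- lapply(g@locations, function(l)
    if (nrow(l)) shift(l) else l)
  org <- lapply(bundle@organelles, function(o) {
    o$center <- o$center + offset
    o$mesh@vertices <- shift(o$mesh@vertices)
    o$voxels <- sweep(o$voxels, 2L,
                      round(offset / bundle@config$voxelSize), `+`)
    o
  })
  new("GroundTruthBundle", mesh = mesh, skeleton = sk, svGraph = g,
      organelles = org, plantedEdges = bundle@plantedEdges,
      config = bundle@config)
}

## minimum Euclidean distance between two nm point sets
.minPointSetDist <- function(A, B) {
  if (nrow(A) > nrow(B)) { tmp <- A; A <- B; B <- tmp }
  min(.knn(B, A, 1L)$dist)
}
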