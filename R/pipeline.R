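#' @include glia.R triplet.R sampling.R synthetic-glia.R metrics.R
NULL

#' Build the multi-channel scene of a bundle
#'
#' @param bundle a \linkS4class{GroundTruthBundle}.
#' @param channels channel names; organelle channels are the merged meshes
#'   of the matching class (MI, SJ, VC).
#' @return named list of \linkS4class{TriangleMesh} (NULL for empty
#'   channels), usable with \code{\link{renderViews}}.
#' @export
organelleScene <- function(bundle, channels = c("cell", "mi", "sj", "vc")) {
  out <- list()
  for (ch in channels) {
    out[[ch]] <- if (ch == "cell") bundle@mesh else {
      cls <- toupper(ch)
      ms <- lapply(Filter(function(o) o$class == cls, bundle@organelles),
                   `[[`, "mesh")
      if (length(ms)) mergeMeshes(ms) else NULL
    }
  }
  out
}

#' Render multi-view samples for the SVs of a graph
#'
#' For every SV, rendering locations are sampled from its mesh and a
#' multi-view sample (x, y, channels, perspectives) is rendered at each
#' location; optionally the 2D connected-component mask is applied
#' (keeping only the component containing the central pixel).
#'
#' @param graph a \linkS4class{SupervoxelGraph}.
#' @param rconfig a \code{\link{renderConfig}}.
#' @param sconfig a \code{\link{samplingConfig}}.
#' @param scene optional named scene list rendered instead of the SV mesh
#'   (the SV's locations are still used).
#' @param maxPerSv cap on locations per SV.
#' @param mask apply \code{\link{maskUnconnected2D}} per image.
#' @param ids SV subset.
#' @return list with \code{samples} (list of arrays), \code{sv} (id per
#'   sample) and \code{location} (matrix of rendering locations).
#' @export
svViewSamples <- function(graph, rconfig = renderConfig(),
                          sconfig = samplingConfig(), scene = NULL,
                          maxPerSv = Inf, mask = FALSE,
                          ids = svIds(graph)) {
  samples <- list(); sv <- character(0); locs <- list()
  for (id in ids) {
    mesh <- graph@meshes[[id]]
    if (!nVertices(mesh)) next
    L <- sampleRenderingLocations(mesh, sconfig)
    if (nrow(L) > maxPerSv) L <- L[seq_len(maxPerSv), , drop = FALSE]
    scn <- if (is.null(scene)) list(cell = mesh) else scene
    for (q in seq_len(nrow(L))) {
      fr <- localFrame(mesh, L[q, ], rconfig)
      vs <- viewArray(renderViews(scn, fr, rconfig))
      a <- aperm(vs, c(1L, 2L, 4L, 3L))  # (x, y, channel, persp)
      if (mask)
        for (k in seq_len(dim(a)[4])) for (c_ in seq_len(dim(a)[3]))
          a[, , c_, k] <- maskUnconnected2D(a[, , c_, k])
      samples[[length(samples) + 1L]] <- a
      sv <- c(sv, id)
      locs[[length(locs) + 1L]] <- L[q, ]
    }
  }
  list(samples = samples, sv = sv,
       location = if (length(locs)) do.call(rbind, locs)
                  else matrix(numeric(0), 0, 3))
}

#' Compartment labels for rendering locations
#'
#' Labels each rendering location with the compartment of the skeleton node
#' whose represented surface is nearest: the distance to a node is the
#' Euclidean distance minus the node radius (so the single soma node, whose
#' radius is the soma radius, correctly claims the soma surface). Locations
#' with a differently-labeled node surface within \code{ambiguity} nm of
#' the best distance are flagged ambiguous (compartment boundaries).
#'
#' @param bundle a \linkS4class{GroundTruthBundle} with labeled skeleton.
#' @param locations matrix (k x 3) of locations, nm.
#' @param ambiguity ambiguity margin, nm (default 2 µm).
#' @return list: \code{labels} (integer per location) and \code{ambiguous}
#'   (logical per location).
#' @export
locationCompartmentLabels <- function(bundle, locations,
                                      ambiguity = 2000) {
  nodes <- bundle@skeleton@nodes
  nlab <- bundle@skeleton@nodeLabels
  rad <- bundle@skeleton@radii
  locations <- as.matrix(locations)
  labels <- integer(nrow(locations))
  amb <- logical(nrow(locations))
  for (q in seq_len(nrow(locations))) {
    d <- sqrt(rowSums(sweep(nodes, 2L, locations[q, ], `-`)^2)) - rad
    i <- which.min(d)
    labels[q] <- nlab[i]
    other <- nlab != nlab[i]
    amb[q] <- any(other) && min(d[other]) < d[i] + ambiguity
  }
  list(labels = labels, ambiguous = amb)
}

#' Build labeled view corpora from synthetic cells
#'
#' Convenience constructors for the scaled-down training corpora used by the
#' packaged experiments: glia-vs-neuron SV fragment views, compartment
#' multi-views at unambiguous rendering locations, and single-view corpora
#' for embedding training. All are deterministic in the given seeds.
#'
#' @param neuronSeeds,gliaSeeds,seeds generator seeds (one synthetic cell
#'   each).
#' @param rconfig a \code{\link{renderConfig}}.
#' @param maxPerSv rendering locations per SV (glia corpus).
#' @param maxLoc locations per cell (compartment/triplet corpora).
#' @param voxelSize organelle grid passed to \code{\link{synthesisConfig}}.
#' @return \code{buildGliaViewCorpus}: list with \code{samples} (arrays
#'   (x, y, 1, persp)) and \code{labels} (1 = neuron, 2 = glia).
#'   \code{buildCompartmentViewCorpus}: list with 4-channel \code{samples},
#'   \code{labels} (1 soma, 2 axon, 3 dendrite) and \code{cells}.
#'   \code{buildTripletViewCorpus}: list with a \code{\link{viewCorpus}} and
#'   per-view compartment \code{labels}.
#' @export
buildGliaViewCorpus <- function(neuronSeeds = 1:4, gliaSeeds = 1:6,
                                rconfig = renderConfig(resolution = c(64L, 32L)),
                                maxPerSv = c(neuron = 3L, glia = 12L),
                                voxelSize = c(50, 50, 50)) {
  sc <- samplingConfig()
  samples <- list(); labels <- integer(0)
  for (i in neuronSeeds) {
    b <- makeNeuron(synthesisConfig(seed = i, voxelSize = voxelSize))
    s <- svViewSamples(b@svGraph, rconfig, sc,
                       maxPerSv = maxPerSv[["neuron"]], mask = TRUE)
    samples <- c(samples, s$samples)
    labels <- c(labels, rep(1L, length(s$samples)))
  }
  for (i in gliaSeeds) {
    g <- makeGliaFragment(synthesisConfig(seed = i, voxelSize = voxelSize))
    s <- svViewSamples(g@svGraph, rconfig, sc,
                       maxPerSv = maxPerSv[["glia"]], mask = TRUE)
    samples <- c(samples, s$samples)
    labels <- c(labels, rep(2L, length(s$samples)))
  }
  list(samples = samples, labels = labels)
}

#' @rdname buildGliaViewCorpus
#' @export
buildCompartmentViewCorpus <- function(seeds,
                                       rconfig = renderConfig(resolution = c(64L, 32L)),
                                       maxLoc = 60L,
                                       voxelSize = c(50, 50, 50)) {
  sc <- samplingConfig()
  samples <- list(); labels <- integer(0); cells <- integer(0)
  for (i in seeds) {
    b <- makeNeuron(synthesisConfig(seed = i, voxelSize = voxelSize))
    L <- sampleRenderingLocations(b@mesh, sc)
    cl <- locationCompartmentLabels(b, L)
    L <- L[!cl$ambiguous, , drop = FALSE]
    lab <- cl$labels[!cl$ambiguous]
    keep <- .withSeed(i, sample(nrow(L), min(maxLoc, nrow(L))))
    L <- L[keep, , drop = FALSE]; lab <- lab[keep]
    scn <- organelleScene(b)
    for (q in seq_len(nrow(L))) {
      fr <- localFrame(b@mesh, L[q, ], rconfig)
      a <- aperm(viewArray(renderViews(scn, fr, rconfig)), c(1, 2, 4, 3))
      samples[[length(samples) + 1L]] <- a
      labels <- c(labels, lab[q]); cells <- c(cells, i)
    }
  }
  list(samples = samples, labels = labels, cells = cells)
}

#' @rdname buildGliaViewCorpus
#' @export
buildTripletViewCorpus <- function(seeds,
                                   rconfig = renderConfig(extent = c(8, 4, 8),
                                                          resolution = c(64L, 32L),
                                                          phi = 50),
                                   maxLoc = 25L,
                                   voxelSize = c(50, 50, 50)) {
  sc <- samplingConfig()
  views <- list(); cell <- integer(0); locs <- list()
  persp <- integer(0); labs <- integer(0)
  for (i in seeds) {
    b <- makeNeuron(synthesisConfig(seed = i, voxelSize = voxelSize))
    L <- sampleRenderingLocations(b@mesh, sc)
    cl <- locationCompartmentLabels(b, L)
    L <- L[!cl$ambiguous, , drop = FALSE]
    lab <- cl$labels[!cl$ambiguous]
    keep <- .withSeed(i, sample(nrow(L), min(maxLoc, nrow(L))))
    L <- L[keep, , drop = FALSE]; lab <- lab[keep]
    scn <- organelleScene(b)
    for (q in seq_len(nrow(L))) {
      fr <- localFrame(b@mesh, L[q, ], rconfig)
      a <- viewArray(renderViews(scn, fr, rconfig))
      for (k in seq_len(dim(a)[3])) {
        views[[length(views) + 1L]] <- a[, , k, ]
        cell <- c(cell, i); persp <- c(persp, k)
        labs <- c(labs, lab[q])
        locs[[length(locs) + 1L]] <- L[q, ]
      }
    }
  }
  list(corpus = viewCorpus(views, cell, do.call(rbind, locs), persp),
       labels = labs)
}

#' Pipeline run configuration
#'
#' Nested configuration of the end-to-end synthetic pipeline. A single
#' top-level seed fans out to per-stage seeds (seed * 100 + stage index),
#' so one number reproduces the whole run.
#'
#' @param seed top-level seed.
#' @param outDir output directory (default: tempdir subdirectory).
#' @param resolution rendered view size in pixels.
#' @param extent clip extent, µm.
#' @param nNeurons,nGlia training cells per class.
#' @param maxPerSv rendering locations per SV.
#' @param trainSteps classifier training iterations.
#' @param lr learning rate of the scaled-down training runs.
#' @param synth overrides passed to \code{\link{synthesisConfig}} (list).
#' @param stages character vector of stages to run, in order.
#' @return a list with class \code{"runConfig"}.
#' @export
runConfig <- function(seed = 1L, outDir = NULL,
                      resolution = c(64L, 32L), extent = c(8, 4, 4),
                      nNeurons = 3L, nGlia = 3L, maxPerSv = 4L,
                      trainSteps = 120L, lr = 1e-3,
                      synth = list(),
                      stages = c("synthesize", "render", "train",
                                 "split")) {
  structure(list(seed = as.integer(seed), outDir = outDir,
                 resolution = as.integer(resolution), extent = extent,
                 nNeurons = as.integer(nNeurons), nGlia = as.integer(nGlia),
                 maxPerSv = as.integer(maxPerSv),
                 trainSteps = as.integer(trainSteps), lr = lr,
                 synth = synth, stages = stages),
            class = "runConfig")
}

#' Read / write a run configuration (YAML)
#'
#' Unknown keys in the file are rejected.
#'
#' @param path YAML file path.
#' @return \code{readRunConfig}: a \code{\link{runConfig}}.
#' @export
readRunConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(runConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("readRunConfig: unknown key(s): ", paste(bad, collapse = ", "))
  do.call(runConfig, vals)
}

#' @rdname readRunConfig
#' @param config a \code{\link{runConfig}}.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the end-to-end synthetic pipeline
#'
#' Synthesizes neuron and glia cells, renders multi-view samples per SV,
#' trains a scaled-down glia CMN, classifies the SVs of a planted
#' neuron-glia merger, applies the top-down splitting heuristic and scores
#' the result against the planted ground truth. Deterministic for a fixed
#' seed; metrics are written to \code{metrics.json} in \code{outDir}.
#'
#' @param config a \code{\link{runConfig}}.
#' @return the metrics list (invisibly: also written as JSON).
#' @export
runPipeline <- function(config = runConfig()) {
  t0 <- Sys.time()
  outDir <- config$outDir
  if (is.null(outDir))
    outDir <- file.path(tempdir(), sprintf("cmnrun_seed%d", config$seed))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  sSeed <- function(i) config$seed * 100L + i
  if (!("synthesize" %in% config$stages))
    stop("runPipeline: stage 'synthesize' disabled but required by ",
         "downstream stages; enable it or provide inputs")
  synthArgs <- config$synth
  mkSynth <- function(seed) do.call(synthesisConfig,
                                    c(list(seed = seed), synthArgs))
  neurons <- lapply(seq_len(config$nNeurons),
                    function(i) makeNeuron(mkSynth(sSeed(i))))
  glias <- lapply(seq_len(config$nGlia),
                  function(i) makeGliaFragment(mkSynth(sSeed(50L + i))))
  merged <- plantMergeError(makeNeuron(mkSynth(sSeed(90L))),
                            makeGliaFragment(mkSynth(sSeed(91L))),
                            nBridges = 1L)
  if (!("render" %in% config$stages))
    stop("runPipeline: stage 'render' disabled but 'train' needs views")
  rc <- renderConfig(extent = config$extent,
                     resolution = config$resolution)
  sc <- samplingConfig()
  corpus <- list(samples = list(), label = integer(0))
  for (b in neurons) {
    s <- svViewSamples(b@svGraph, rc, sc, maxPerSv = config$maxPerSv,
                       mask = TRUE)
    corpus$samples <- c(corpus$samples, s$samples)
    corpus$label <- c(corpus$label, rep(1L, length(s$samples)))
  }
  for (b in glias) {
    s <- svViewSamples(b@svGraph, rc, sc, maxPerSv = config$maxPerSv,
                       mask = TRUE)
    corpus$samples <- c(corpus$samples, s$samples)
    corpus$label <- c(corpus$label, rep(2L, length(s$samples)))
  }
  if (!("train" %in% config$stages))
    stop("runPipeline: stage 'train' disabled but 'split' needs a model")
  arch <- if (min(config$resolution) >= 32L) cmnArchitecture("small")
          else cmnArchitecture(filters = c(6L, 10L),
                               kernels = list(c(1, 5, 5), c(1, 3, 3)),
                               pools = list(c(1, 2, 2), c(1, 2, 2)),
                               fc = 16L)
  model <- buildCmn(arch, nClasses = 2L,
                    nChannels = 1L, inputSize = config$resolution,
                    z = rc$nPersp, seed = sSeed(7L))
  model <- trainCmnClassifier(model, corpus$samples, corpus$label,
                              trainConfig(steps = config$trainSteps,
                                          batchSize = 10L,
                                          lr = config$lr,
                                          seed = sSeed(8L)))
  metrics <- list(seed = config$seed,
                  nTrainViews = length(corpus$samples))
  if ("split" %in% config$stages) {
    sv <- svViewSamples(merged@svGraph, rc, sc,
                        maxPerSv = config$maxPerSv, mask = TRUE)
    probs <- predictCmn(model, sv$samples)[, 2]
    svProb <- split(probs, sv$sv)
    g <- merged@svGraph
    labs <- vapply(svIds(g), function(id)
      if (!is.null(svProb[[id]])) classifySv(svProb[[id]]) else 0L,
      integer(1))
    svLabels(g) <- labs
    res <- splitSsv(g)
    truth <- merged@svGraph@labels
    ev <- evaluateSplit(res, g, truth)
    svScore <- scoreClassification(truth[svIds(g)], labs)
    metrics$svLevel <- list(f1 = svScore$average,
                            perClass = svScore$perClass$f1)
    metrics$split <- list(
      unweightedF1 = mean(ev$perClass$f1),
      volumeWeightedF1 = mean(ev$weighted$f1),
      newNeuronSplits = ev$newNeuronSplits,
      nNeuronSSV = length(res$neuron), nGliaSSV = length(res$glia))
  }
  jsonlite::write_json(metrics, file.path(outDir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  rt <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  logLines <- c(sprintf("seed: %d", config$seed),
                sprintf("stages: %s", paste(config$stages, collapse = ",")),
                sprintf("train views: %d", length(corpus$samples)),
                sprintf("runtime_s: %.1f", rt))
  writeLines(logLines, file.path(outDir, "run.log"))
  invisible(metrics)
}
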