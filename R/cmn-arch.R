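#' @include nn-losses.R
NULL

#' CMN architecture specification
#'
#' Describes the convolutional stack of a cellular morphology network as a
#' list of (filters, kernel (z, x, y), max-pool (z, x, y)) layers followed
#' by fully connected layer sizes. The z kernel size is always 1: filters
#' are shared across the views of a multi-view input (the z axis is folded
#' into the batch during convolution). The default is the reference glia
#' architecture; \code{cmnArchitecture("small")} is a reduced member of the
#' same family for scaled-down experiments on 64 x 32 views.
#'
#' @param preset \code{"glia"} (default, the full 256 x 128 architecture)
#'   or \code{"small"}.
#' @param filters,kernels,pools,fc override the preset: integer vector of
#'   filter counts, list of length-3 kernels, list of length-3 pool sizes,
#'   integer vector of fully connected hidden sizes.
#' @return a list with class \code{"cmnArchitecture"}.
#' @examples
#' arch <- cmnArchitecture()
#' countParameters(buildCmn(arch, nClasses = 2, nChannels = 1))  # 35770
#' @export
cmnArchitecture <- function(preset = c("glia", "small"), filters = NULL,
                            kernels = NULL, pools = NULL, fc = NULL) {
  preset <- match.arg(preset)
  if (preset == "glia") {
    f <- c(13L, 17L, 21L, 25L, 29L, 30L, 31L)
    ks <- list(c(1, 5, 5), c(1, 5, 5), c(1, 4, 4), c(1, 4, 4), c(1, 2, 2),
               c(1, 1, 1), c(1, 1, 1))
    ps <- list(c(1, 2, 2), c(1, 2, 2), c(1, 2, 2), c(1, 2, 2), c(1, 2, 2),
               c(1, 2, 2), c(1, 1, 1))
    fcs <- c(50L, 30L)
  } else {
    f <- c(8L, 12L, 16L)
    ks <- list(c(1, 5, 5), c(1, 5, 5), c(1, 4, 4))
    ps <- list(c(1, 2, 2), c(1, 2, 2), c(1, 2, 2))
    fcs <- c(32L)
  }
  if (!is.null(filters)) f <- as.integer(filters)
  if (!is.null(kernels)) ks <- kernels
  if (!is.null(pools)) ps <- pools
  if (!is.null(fc)) fcs <- as.integer(fc)
  stopifnot(length(f) == length(ks), length(f) == length(ps))
  for (k in ks) if (k[1] != 1)
    stop("cmnArchitecture: z kernel size must be 1 (shared view filters)")
  structure(list(filters = f, kernels = ks, pools = ps, fc = fcs),
            class = "cmnArchitecture")
}

#' Build a CMN classifier model
#'
#' Instantiates the architecture with valid-mode convolutions, ReLU after
#' every hidden layer, non-overlapping max pooling (floor division on odd
#' sizes), dropout on the fully connected hidden layers, and a final
#' n-class linear layer read out through a softmax. The multi-view z axis
#' shares all convolution filters.
#'
#' @param arch a \code{\link{cmnArchitecture}}.
#' @param nClasses number of output classes.
#' @param nChannels input channels per view (1 or 4).
#' @param inputSize pixels (x, y), default \code{c(256, 128)}.
#' @param z number of views per sample (2 for 2-views, N for N-views).
#' @param dropout dropout rate on FC hidden layers.
#' @param seed RNG seed for weight initialization.
#' @return a model object (list with class \code{"cmnModel"}).
#' @export
buildCmn <- function(arch, nClasses, nChannels = 1L,
                     inputSize = c(256L, 128L), z = 2L, dropout = 0.1,
                     seed = 1L) {
  stopifnot(inherits(arch, "cmnArchitecture"), nClasses >= 2L)
  .withSeed(seed, {
    layers <- list()
    H <- inputSize[1]; W <- inputSize[2]; C <- nChannels
    for (i in seq_along(arch$filters)) {
      k <- arch$kernels[[i]][2:3]; p <- arch$pools[[i]][2:3]
      nm <- sprintf("conv L%d", i)
      if (H < k[1] || W < k[2])
        stop("buildCmn: ", nm, " kernel ", k[1], "x", k[2],
             " exceeds input ", H, "x", W)
      layers[[length(layers) + 1L]] <- .convLayer(nm, C, arch$filters[i], k)
      layers[[length(layers) + 1L]] <- list(type = "relu")
      H <- H - k[1] + 1L; W <- W - k[2] + 1L
      if (any(p > 1)) {
        layers[[length(layers) + 1L]] <- list(type = "pool",
                                              size = as.integer(p))
        H <- H %/% p[1]; W <- W %/% p[2]
        if (H < 1L || W < 1L)
          stop("buildCmn: ", nm, " pooling underflows the feature map")
      }
      C <- arch$filters[i]
    }
    layers[[length(layers) + 1L]] <- list(type = "flatten")
    nIn <- H * W * C * z
    for (j in seq_along(arch$fc)) {
      layers[[length(layers) + 1L]] <-
        .fcLayer(sprintf("fc L%d", j), nIn, arch$fc[j])
      layers[[length(layers) + 1L]] <- list(type = "relu")
      if (dropout > 0)
        layers[[length(layers) + 1L]] <- list(type = "dropout", p = dropout)
      nIn <- arch$fc[j]
    }
    layers[[length(layers) + 1L]] <-
      .fcLayer(sprintf("fc L%d", length(arch$fc) + 1L), nIn, nClasses)
    structure(list(layers = layers, z = as.integer(z),
                   nClasses = as.integer(nClasses),
                   nChannels = as.integer(nChannels),
                   inputSize = as.integer(inputSize), kind = "classifier"),
              class = "cmnModel")
  })
}

#' Build a triplet (Neuron2vec) encoder
#'
#' Same convolutional family as \code{\link{buildCmn}} operating on single
#' views (z = 1), with max pooling removed from the layers in
#' \code{poolOff} (L2 and L6 in the reference setting), dropout restricted
#' to the middle convolutional layers (\code{dropoutLayers}), a single
#' hidden FC layer and a linear d_z-dimensional output.
#'
#' @param arch a \code{\link{cmnArchitecture}}.
#' @param dz latent dimension (10 or 25 in the reference setting).
#' @param nChannels input channels.
#' @param inputSize pixels (x, y).
#' @param poolOff conv layer indices whose pooling is removed.
#' @param dropoutLayers conv layer indices followed by dropout.
#' @param dropout dropout rate.
#' @param seed RNG seed.
#' @return a model object (class \code{"cmnModel"}, kind "triplet").
#' @export
buildTripletCmn <- function(arch, dz = 10L, nChannels = 1L,
                            inputSize = c(256L, 128L),
                            poolOff = c(2L, 6L),
                            dropoutLayers = 3:5, dropout = 0.1,
                            seed = 1L) {
  stopifnot(inherits(arch, "cmnArchitecture"), dz >= 1L)
  .withSeed(seed, {
    layers <- list()
    H <- inputSize[1]; W <- inputSize[2]; C <- nChannels
    for (i in seq_along(arch$filters)) {
      k <- arch$kernels[[i]][2:3]; p <- arch$pools[[i]][2:3]
      nm <- sprintf("conv L%d", i)
      if (H < k[1] || W < k[2])
        stop("buildTripletCmn: ", nm, " kernel exceeds input ", H, "x", W)
      layers[[length(layers) + 1L]] <- .convLayer(nm, C, arch$filters[i], k)
      layers[[length(layers) + 1L]] <- list(type = "relu")
      H <- H - k[1] + 1L; W <- W - k[2] + 1L
      if (i %in% dropoutLayers && dropout > 0)
        layers[[length(layers) + 1L]] <- list(type = "dropout", p = dropout)
      if (!(i %in% poolOff) && any(p > 1)) {
        layers[[length(layers) + 1L]] <- list(type = "pool",
                                              size = as.integer(p))
        H <- H %/% p[1]; W <- W %/% p[2]
      }
      C <- arch$filters[i]
    }
    layers[[length(layers) + 1L]] <- list(type = "flatten")
    nIn <- H * W * C
    layers[[length(layers) + 1L]] <- .fcLayer("fc L1", nIn, arch$fc[1])
    layers[[length(layers) + 1L]] <- list(type = "relu")
    layers[[length(layers) + 1L]] <- .fcLayer("fc out", arch$fc[1], dz)
    structure(list(layers = layers, z = 1L, nClasses = as.integer(dz),
                   nChannels = as.integer(nChannels),
                   inputSize = as.integer(inputSize), kind = "triplet"),
              class = "cmnModel")
  })
}

#' Count trainable parameters of a model
#'
#' Sum of weight and bias counts over all layers; a pure function of the
#' architecture. The reference glia architecture with two output classes and
#' one input channel has 35,770 trainable parameters.
#'
#' @param model a model from \code{\link{buildCmn}} /
#'   \code{\link{buildTripletCmn}} / \code{\link{buildSurfaceModel}}.
#' @return integer parameter count.
#' @export
countParameters <- function(model) {
  sum(vapply(model$layers, function(l)
    if (is.null(l$W)) 0L else length(l$W) + length(l$b), integer(1)))
}

## stack a list of (H, W, C, z) samples into the engine's (H, W, C, z*b)
## batch layout (sample-major grouping)
.stackSamples <- function(samples) {
  d <- dim(samples[[1]])
  if (length(d) == 3L) d <- c(d, 1L)
  X <- array(0, dim = c(d[1], d[2], d[3], d[4] * length(samples)))
  for (i in seq_along(samples)) {
    X[, , , (i - 1L) * d[4] + seq_len(d[4])] <- samples[[i]]
  }
  X
}

#' Class probabilities for view samples
#'
#' @param model a classifier from \code{\link{buildCmn}}.
#' @param samples list of input arrays (x, y, channels, z), 8-bit values
#'   (normalized internally by 255).
#' @return matrix (samples x classes) of softmax probabilities.
#' @export
predictCmn <- function(model, samples) {
  X <- .stackSamples(samples) / 255
  .softmax(nnForward(model, X, training = FALSE)$out)
}

#' Latent embeddings for single views
#'
#' @param model a triplet encoder from \code{\link{buildTripletCmn}}.
#' @param views list of single-view arrays (x, y, channels) or one array
#'   (x, y, channels, n).
#' @return matrix (views x d_z) of embeddings.
#' @export
embedViews <- function(model, views) {
  if (is.list(views))
    views <- .stackSamples(lapply(views, function(v) {
      if (length(dim(v)) == 2L) dim(v) <- c(dim(v), 1L)
      v
    }))
  if (length(dim(views)) == 3L) dim(views) <- c(dim(views), 1L)
  nnForward(model, views / 255, training = FALSE)$out
}
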