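#' @include cmn-arch.R
NULL

#' Training configuration for CMN models
#'
#' Defaults mirror the reference hyper-parameters: batch size 20, Adam with
#' learning rate 1e-4 and momenta (0.9, 0.99), weight decay 5e-4, dropout
#' 0.1, and view-order inversion with probability 0.5. The cell-type model
#' uses dropout 0.08 and exponential learning-rate decay of 0.98 per 1000
#' steps (\code{lrDecay = c(0.98, 1000)}).
#'
#' @param steps number of training iterations.
#' @param batchSize mini-batch size.
#' @param lr Adam learning rate.
#' @param beta Adam momenta (beta1, beta2).
#' @param weightDecay L2 weight decay on weights (not biases).
#' @param dropout dropout rate.
#' @param swapProb probability of inverting the order of the views of a
#'   sample during training.
#' @param classWeights optional per-class loss weights (e.g. dendrite 2,
#'   axon 1, soma 1).
#' @param classBalanced draw every batch with equal class counts.
#' @param lrDecay optional \code{c(rate, everySteps)} exponential decay.
#' @param optimizer \code{"adam"} or \code{"sgd"} (momentum SGD; momentum =
#'   \code{beta[1]}). The triplet objective trains more stably with SGD,
#'   whose updates preserve the balance between the margin and norm terms.
#' @param seed RNG seed for batch sampling and dropout.
#' @return a list with class \code{"trainConfig"}.
#' @export
trainConfig <- function(steps = 300L, batchSize = 20L, lr = 1e-4,
                        beta = c(0.9, 0.99), weightDecay = 5e-4,
                        dropout = 0.1, swapProb = 0.5, classWeights = NULL,
                        classBalanced = FALSE, lrDecay = NULL,
                        optimizer = c("adam", "sgd"), seed = 1L) {
  stopifnot(steps >= 1, batchSize >= 1, lr > 0, swapProb >= 0,
            swapProb <= 1)
  optimizer <- match.arg(optimizer)
  structure(list(steps = as.integer(steps), batchSize = as.integer(batchSize),
                 lr = lr, beta = beta, weightDecay = weightDecay,
                 dropout = dropout, swapProb = swapProb,
                 classWeights = classWeights, classBalanced = classBalanced,
                 lrDecay = lrDecay, optimizer = optimizer,
                 seed = as.integer(seed)),
            class = "trainConfig")
}

## one optimizer step dispatching on config$optimizer; state initialized by
## .optimInit
.optimInit <- function(model) .adamInit(model)

.optimStep <- function(model, grads, state, t, lr, config) {
  if (identical(config$optimizer, "sgd")) {
    mom <- config$beta[1]
    for (li in seq_along(model$layers)) {
      g <- grads[[li]]
      if (is.null(g)) next
      s <- state[[li]]
      s$mW <- mom * s$mW - lr * (g$dW + config$weightDecay *
                                   model$layers[[li]]$W)
      s$mb <- mom * s$mb - lr * g$db
      model$layers[[li]]$W <- model$layers[[li]]$W + s$mW
      model$layers[[li]]$b <- model$layers[[li]]$b + s$mb
      state[[li]] <- s
    }
    return(list(model = model, state = state))
  }
  .adamStep(model, grads, state, t, lr, config$beta[1], config$beta[2],
            config$weightDecay)
}

#' Train a CMN classifier on view samples
#'
#' Mini-batch Adam training with softmax cross-entropy. Samples are drawn
#' uniformly (or class-balanced); with probability \code{swapProb} the view
#' order (z axis) of a sample is inverted, the multi-view analogue of a
#' flip augmentation.
#'
#' @param model a classifier from \code{\link{buildCmn}}.
#' @param samples list of arrays (x, y, channels, z), 8-bit values.
#' @param labels integer class labels in 1..nClasses.
#' @param config a \code{\link{trainConfig}}.
#' @return the trained model; attribute \code{"lossTrace"} carries the
#'   per-step training loss.
#' @export
trainCmnClassifier <- function(model, samples, labels,
                               config = trainConfig()) {
  stopifnot(length(samples) == length(labels),
            all(labels >= 1L), all(labels <= model$nClasses))
  Xn <- lapply(samples, function(s) s / 255)
  .withSeed(config$seed, {
    state <- .optimInit(model)
    trace <- numeric(config$steps)
    byClass <- split(seq_along(labels), labels)
    for (t in seq_len(config$steps)) {
      idx <- if (config$classBalanced) {
        per <- max(1L, config$batchSize %/% length(byClass))
        unlist(lapply(byClass, function(v)
          sample(v, per, replace = length(v) < per)))
      } else sample(seq_along(Xn), config$batchSize,
                    replace = length(Xn) < config$batchSize)
      batch <- lapply(Xn[idx], function(s) {
        if (model$z > 1L && stats::runif(1) < config$swapProb)
          s[, , , rev(seq_len(dim(s)[4])), drop = FALSE] else s
      })
      X <- .stackSamples(batch)
      fw <- nnForward(model, X, training = TRUE)
      ls <- .softmaxCE(fw$out, labels[idx], config$classWeights)
      trace[t] <- ls$loss
      bw <- nnBackward(model, fw$caches, ls$dZ)
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
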