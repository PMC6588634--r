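#' @include geometry-utils.R
NULL

## ---------------------------------------------------------------------------
## Minimal CPU neural-network engine used by the CMN models.
## Tensors are 4D arrays (H, W, C, N); the multi-view z axis is folded into
## the batch axis during the convolutional stack (filters shared across
## views) and concatenated back at the flatten step, mirroring the
## z-filter-size-1 convolutions of the CMN architecture.
## ---------------------------------------------------------------------------

## im2col gather index for one image (H, W, C) and kernel (k1, k2), valid;
## the batch-expanded index (P*N x K) is cached per shape
.nnIndexCache <- new.env(parent = emptyenv())

.im2colIndex <- function(H, W, C, k1, k2, N) {
  key <- paste(H, W, C, k1, k2, N, sep = "_")
  hit <- .nnIndexCache[[key]]
  if (!is.null(hit)) return(hit)
  OH <- H - k1 + 1L; OW <- W - k2 + 1L
  lin0 <- outer(seq_len(OH), (seq_len(OW) - 1L) * H, `+`)  # OH x OW
  offs <- as.vector(outer(as.vector(outer(0:(k1 - 1L), (0:(k2 - 1L)) * H,
                                          `+`)),
                          (0:(C - 1L)) * H * W, `+`))
  A <- outer(as.vector(lin0), offs, `+`)
  P <- OH * OW
  IDX <- A[rep(seq_len(P), N), , drop = FALSE] +
    rep((seq_len(N) - 1L) * H * W * C, each = P)
  out <- list(IDX = IDX, OH = OH, OW = OW, K = ncol(A))
  .nnIndexCache[[key]] <- out
  out
}

.convForward <- function(layer, X, cache = TRUE) {
  d <- dim(X); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  k1 <- layer$kernel[1]; k2 <- layer$kernel[2]
  if (identical(layer$pad, "same")) {
    p1 <- (k1 - 1L) %/% 2L; p2 <- (k2 - 1L) %/% 2L
    Xp <- array(0, dim = c(H + 2L * p1, W + 2L * p2, C, N))
    Xp[p1 + seq_len(H), p2 + seq_len(W), , ] <- X
    X <- Xp; d <- dim(X); H <- d[1]; W <- d[2]
  }
  if (H < k1 || W < k2)
    stop("convolution '", layer$name, "': kernel larger than input (",
         H, "x", W, " vs ", k1, "x", k2, ")")
  ix <- .im2colIndex(H, W, C, k1, k2, N)
  P <- ix$OH * ix$OW
  M <- X[ix$IDX]
  dim(M) <- dim(ix$IDX)
  Y <- M %*% layer$W
  Y <- sweep(Y, 2L, layer$b, `+`)
  Cout <- length(layer$b)
  Ya <- array(Y, dim = c(ix$OH, ix$OW, N, Cout))
  out <- aperm(Ya, c(1L, 2L, 4L, 3L))
  list(out = out,
       cache = if (cache) list(M = M, ix = ix, dimX = dim(X)) else NULL)
}

.convBackward <- function(layer, cache, dY) {
  dd <- dim(dY)  # (OH, OW, Cout, N)
  dYmat <- matrix(aperm(dY, c(1L, 2L, 4L, 3L)), ncol = dd[3])
  dW <- crossprod(cache$M, dYmat)
  db <- colSums(dYmat)
  dM <- tcrossprod(dYmat, layer$W)
  dX <- array(0, dim = cache$dimX)
  ## col2im: per kernel-offset scatter-add (indices within one column are
  ## distinct positions, so the vectorized add is safe)
  IDX <- cache$ix$IDX
  for (k in seq_len(ncol(IDX))) {
    idx <- IDX[, k]
    dX[idx] <- dX[idx] + dM[, k]
  }
  if (identical(layer$pad, "same")) {
    k1 <- layer$kernel[1]; k2 <- layer$kernel[2]
    p1 <- (k1 - 1L) %/% 2L; p2 <- (k2 - 1L) %/% 2L
    d <- dim(dX)
    dX <- dX[p1 + seq_len(d[1] - 2L * p1), p2 + seq_len(d[2] - 2L * p2), , ,
             drop = FALSE]
  }
  list(dX = dX, dW = dW, db = db)
}

.poolForward <- function(layer, X) {
  p1 <- layer$size[1]; p2 <- layer$size[2]
  if (p1 == 1L && p2 == 1L) return(list(out = X, cache = NULL))
  d <- dim(X)
  H2 <- d[1] %/% p1; W2 <- d[2] %/% p2
  Y <- array(-Inf, dim = c(H2, W2, d[3], d[4]))
  src <- array(0L, dim = dim(Y))  # winning sub-cell (1..p1*p2), ties first
  for (j in seq_len(p2)) for (i in seq_len(p1)) {
    S <- X[seq(i, by = p1, length.out = H2),
           seq(j, by = p2, length.out = W2), , , drop = FALSE]
    sel <- S > Y
    Y[sel] <- S[sel]
    src[sel] <- (j - 1L) * p1 + i
  }
  list(out = Y, cache = list(src = src, dimX = d))
}

.poolBackward <- function(layer, cache, dY) {
  p1 <- layer$size[1]; p2 <- layer$size[2]
  if (p1 == 1L && p2 == 1L) return(dY)
  dX <- array(0, dim = cache$dimX)
  d <- dim(dY)
  for (j in seq_len(p2)) for (i in seq_len(p1)) {
    sel <- cache$src == (j - 1L) * p1 + i
    tmp <- array(0, dim = d)
    tmp[sel] <- dY[sel]
    dX[seq(i, by = p1, length.out = d[1]),
       seq(j, by = p2, length.out = d[2]), , ] <- tmp
  }
  dX
}

.upsampleForward <- function(layer, X) {
  f <- layer$factor
  d <- dim(X)
  idx1 <- rep(seq_len(d[1]), each = f)
  idx2 <- rep(seq_len(d[2]), each = f)
  list(out = X[idx1, idx2, , , drop = FALSE], cache = list(dimX = d))
}

.upsampleBackward <- function(layer, cache, dY) {
  f <- layer$factor
  d <- cache$dimX
  dX <- array(0, dim = d)
  for (i in seq_len(f)) for (j in seq_len(f)) {
    dX <- dX + dY[seq(i, by = f, length.out = d[1]),
                  seq(j, by = f, length.out = d[2]), , , drop = FALSE]
  }
  dX
}

## forward through the layer list; X: (H, W, C, N) for conv stages.
## training=TRUE activates dropout (draws from the current RNG stream).
nnForward <- function(model, X, training = FALSE) {
  caches <- vector("list", length(model$layers))
  cur <- X
  for (li in seq_along(model$layers)) {
    l <- model$layers[[li]]
    r <- switch(l$type,
      conv = .convForward(l, cur),
      pool = .poolForward(l, cur),
      upsample = .upsampleForward(l, cur),
      relu = list(out = pmax(cur, 0), cache = list(mask = cur > 0)),
      dropout = {
        if (training && l$p > 0) {
          m <- (array(stats::runif(length(cur)), dim = dim(cur)) >= l$p) /
            (1 - l$p)
          list(out = cur * m, cache = list(mask = m))
        } else list(out = cur, cache = NULL)
      },
      flatten = {
        d <- dim(cur)
        b <- d[4] %/% model$z
        list(out = t(matrix(cur, prod(d[1:3]) * model$z, b)),
             cache = list(dimX = d))
      },
      fc = list(out = sweep(cur %*% l$W, 2L, l$b, `+`),
                cache = list(X = cur)),
      stop("unknown layer type ", l$type))
    caches[[li]] <- r$cache
    cur <- r$out
  }
  list(out = cur, caches = caches)
}

## backward pass; dOut matches the forward output. Returns per-layer grads.
nnBackward <- function(model, caches, dOut) {
  grads <- vector("list", length(model$layers))
  cur <- dOut
  for (li in rev(seq_along(model$layers))) {
    l <- model$layers[[li]]
    cur <- switch(l$type,
      conv = {
        g <- .convBackward(l, caches[[li]], cur)
        grads[[li]] <- list(dW = g$dW, db = g$db)
        g$dX
      },
      pool = .poolBackward(l, caches[[li]], cur),
      upsample = .upsampleBackward(l, caches[[li]], cur),
      relu = cur * caches[[li]]$mask,
      dropout = if (is.null(caches[[li]])) cur else cur * caches[[li]]$mask,
      flatten = {
        d <- caches[[li]]$dimX
        array(matrix(t(cur), prod(d[1:3]), d[4]), dim = d)
      },
      fc = {
        g <- list(dW = crossprod(caches[[li]]$X, cur), db = colSums(cur))
        grads[[li]] <- g
        tcrossprod(cur, l$W)
      })
  }
  list(grads = grads, dX = cur)
}

## He-initialized layer constructors
.convLayer <- function(name, inC, outC, kernel, pad = "valid") {
  fanIn <- inC * prod(kernel)
  list(type = "conv", name = name,
       W = matrix(stats::rnorm(fanIn * outC, sd = sqrt(2 / fanIn)),
                  fanIn, outC),
       b = numeric(outC), kernel = as.integer(kernel), pad = pad)
}

.fcLayer <- function(name, nIn, nOut) {
  list(type = "fc", name = name,
       W = matrix(stats::rnorm(nIn * nOut, sd = sqrt(2 / nIn)), nIn, nOut),
       b = numeric(nOut))
}

## Adam with decoupled-style weight decay on W (not biases)
.adamInit <- function(model) {
  lapply(model$layers, function(l)
    if (!is.null(l$W)) list(mW = l$W * 0, vW = l$W * 0,
                            mb = l$b * 0, vb = l$b * 0))
}

.adamStep <- function(model, grads, state, t, lr, beta1 = 0.9,
                      beta2 = 0.99, weightDecay = 5e-4, eps = 1e-8) {
  for (li in seq_along(model$layers)) {
    g <- grads[[li]]
    if (is.null(g)) next
    l <- model$layers[[li]]
    s <- state[[li]]
    gW <- g$dW + weightDecay * l$W
    s$mW <- beta1 * s$mW + (1 - beta1) * gW
    s$vW <- beta2 * s$vW + (1 - beta2) * gW^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$db
    s$vb <- beta2 * s$vb + (1 - beta2) * g$db^2
    c1 <- 1 - beta1^t; c2 <- 1 - beta2^t
    l$W <- l$W - lr * (s$mW / c1) / (sqrt(s$vW / c2) + eps)
    l$b <- l$b - lr * (s$mb / c1) / (sqrt(s$vb / c2) + eps)
    model$layers[[li]] <- l
    state[[li]] <- s
  }
  list(model = model, state = state)
}
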