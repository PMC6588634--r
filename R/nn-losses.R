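#' @include nn-core.R
NULL

## softmax over the last dimension of a (n x K) matrix
.softmax <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

## weighted softmax cross-entropy; labels 1-based. Returns loss and dZ.
.softmaxCE <- function(Z, labels, classWeights = NULL) {
  n <- nrow(Z); K <- ncol(Z)
  P <- .softmax(Z)
  w <- if (is.null(classWeights)) rep(1, n) else classWeights[labels]
  iy <- cbind(seq_len(n), labels)
  loss <- sum(w * -log(pmax(P[iy], 1e-12))) / sum(w)
  dZ <- P
  dZ[iy] <- dZ[iy] - 1
  dZ <- dZ * (w / sum(w))
  list(loss = loss, dZ = dZ, probs = P)
}

#' Triplet loss of the Neuron2vec objective
#'
#' For embeddings of a reference, a similar and a dissimilar view, with
#' r+ = |ref - plus|, r- = |ref - minus| (Euclidean), the margin term is
#' alpha = r+ - r- + lambda1. The loss is alpha + lambda2 when alpha > 0
#' and lambda2 otherwise, where lambda2 is the mean Euclidean norm of the
#' three embeddings (a regularizer keeping latent vectors small).
#'
#' @param ref,plus,minus numeric vectors of equal length (latent vectors).
#' @param lambda1 margin parameter (default 0.2).
#' @return numeric scalar loss (always >= 0).
#' @examples
#' tripletLoss(c(1, 0), c(1, 0), c(0, 1))  # alpha < 0: loss = lambda2 = 1
#' @export
tripletLoss <- function(ref, plus, minus, lambda1 = 0.2) {
  if (length(ref) != length(plus) || length(ref) != length(minus))
    stop("tripletLoss: embedding length mismatch")
  rp <- sqrt(sum((ref - plus)^2))
  rm <- sqrt(sum((ref - minus)^2))
  alpha <- rp - rm + lambda1
  lambda2 <- (sqrt(sum(ref^2)) + sqrt(sum(plus^2)) +
              sqrt(sum(minus^2))) / 3
  if (alpha > 0) alpha + lambda2 else lambda2
}

## batched triplet loss with gradients. E: (3B x d) rows = [ref; plus; minus]
## per triplet contiguously interleaved as blocks (refs 1..B, plus B+1..2B,
## minus 2B+1..3B). Returns mean loss + dE.
.tripletLossBatch <- function(E, lambda1 = 0.2) {
  B <- nrow(E) / 3L
  d <- ncol(E)
  iR <- seq_len(B); iP <- B + iR; iM <- 2L * B + iR
  dR <- E[iR, , drop = FALSE] - E[iP, , drop = FALSE]
  dMm <- E[iR, , drop = FALSE] - E[iM, , drop = FALSE]
  rp <- sqrt(rowSums(dR^2)); rm <- sqrt(rowSums(dMm^2))
  alpha <- rp - rm + lambda1
  nrm <- sqrt(rowSums(E^2))
  lambda2 <- (nrm[iR] + nrm[iP] + nrm[iM]) / 3
  loss <- mean(ifelse(alpha > 0, alpha + lambda2, lambda2))
  dE <- E * 0
  act <- alpha > 0
  ## d(rp)/dref = (ref-plus)/rp etc.; subgradient 0 at coincident points
  sp <- ifelse(rp > 1e-12, 1 / rp, 0) * act
  sm <- ifelse(rm > 1e-12, 1 / rm, 0) * act
  dE[iR, ] <- dR * sp - dMm * sm
  dE[iP, ] <- -dR * sp
  dE[iM, ] <- dMm * sm
  ## lambda2 term: d|x|/dx = x/|x| for each of the three
  sN <- ifelse(nrm > 1e-12, 1 / nrm, 0) / 3
  dE <- dE + E * sN
  dE / B
}

## Lovasz gradient of the Jaccard extension for sorted errors (desc)
.lovaszGrad <- function(gtSorted) {
  n <- length(gtSorted)
  inter <- sum(gtSorted) - cumsum(gtSorted)
  union <- sum(gtSorted) + cumsum(1 - gtSorted)
  jacc <- 1 - inter / union
  if (n > 1L) jacc[2:n] <- jacc[2:n] - jacc[1:(n - 1L)]
  jacc
}

## Lovasz-Softmax loss over flattened pixels.
## P: (n x K) softmax probabilities, labels 1-based. Returns loss and dP.
.lovaszSoftmax <- function(P, labels) {
  n <- nrow(P); K <- ncol(P)
  present <- sort(unique(labels))
  loss <- 0
  dP <- P * 0
  for (c_ in present) {
    fg <- as.numeric(labels == c_)
    err <- abs(fg - P[, c_])
    o <- order(err, decreasing = TRUE)
    g <- .lovaszGrad(fg[o])
    loss <- loss + sum(err[o] * g)
    ## d err/d p_c = -1 on foreground, +1 elsewhere
    sgn <- ifelse(fg == 1, -1, 1)
    dcol <- numeric(n)
    dcol[o] <- g
    dP[, c_] <- dP[, c_] + dcol * sgn
  }
  list(loss = loss / length(present), dP = dP / length(present))
}

## backprop Lovasz-Softmax (or pixel CE) through the softmax: Z (n x K)
.segLoss <- function(Z, labels, type = c("lovasz", "ce"),
                     classWeights = NULL) {
  type <- match.arg(type)
  if (type == "ce") return(.softmaxCE(Z, labels, classWeights))
  P <- .softmax(Z)
  lv <- .lovaszSoftmax(P, labels)
  ## dZ_k = p_k * (g_k - sum_j g_j p_j)
  s <- rowSums(lv$dP * P)
  dZ <- P * (lv$dP - s)
  list(loss = lv$loss, dZ = dZ, probs = P)
}
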