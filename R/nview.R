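#' @include cmn-arch.R
NULL

#' Assemble N-view sets from the 2-views of one cell
#'
#' The collection of all 2M single views of an SSV is split into
#' floor(2M / N) random sets of size N, drawn without replacement (no view
#' is reused across sets). When 2M < N, exactly one set is returned,
#' containing all views plus N - 2M redraws from the existing views. With
#' \code{shuffle = FALSE} the views keep their creation order, producing
#' spatially correlated sets.
#'
#' @param viewIds vector of view identifiers (the 2M single views, in
#'   creation order).
#' @param N views per set.
#' @param shuffle randomize the assignment (default TRUE).
#' @param seed RNG seed.
#' @return list of length-N vectors of view ids.
#' @export
assembleNviews <- function(viewIds, N, shuffle = TRUE, seed = 1L) {
  m <- length(viewIds)
  if (m < 1L) stop("assembleNviews: no views")
  stopifnot(N >= 1L)
  .withSeed(seed, {
    if (m < N) {
      pad <- viewIds[sample.int(m, N - m, replace = TRUE)]
      return(list(c(viewIds, pad)))
    }
    ord <- if (shuffle) sample.int(m) else seq_len(m)
    nSets <- m %/% N
    lapply(seq_len(nSets), function(s)
      viewIds[ord[(s - 1L) * N + seq_len(N)]])
  })
}

#' Majority vote over per-set predictions
#'
#' Most frequent label; ties are broken by the highest summed softmax
#' probability and then by the lowest class index.
#'
#' @param labels integer predicted labels (one per N-view set).
#' @param probs optional matrix (sets x classes) of softmax outputs used
#'   for tie breaking.
#' @return a single integer label.
#' @export
majorityVote <- function(labels, probs = NULL) {
  if (!length(labels)) stop("majorityVote: no predictions")
  tb <- table(labels)
  top <- as.integer(names(tb)[tb == max(tb)])
  if (length(top) == 1L) return(top)
  if (!is.null(probs)) {
    sums <- colSums(probs[, top, drop = FALSE])
    top <- top[sums == max(sums)]
  }
  min(top)
}
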