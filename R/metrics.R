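#' @include AllClasses.R
NULL

#' Precision / recall / F1 per class with optional weighting
#'
#' Standard one-vs-rest scores. \code{weights = "none"} averages classes
#' uniformly, \code{"support"} weights each class by its true count and
#' \code{"volume"} weights every sample by the supplied volume (both in the
#' per-class confusion sums and in the average). Classes absent from the
#' truth are reported with 0 support.
#'
#' @param truth,pred equal-length label vectors.
#' @param weights \code{"none"}, \code{"support"} or \code{"volume"}.
#' @param volume per-sample weights, required for \code{"volume"}.
#' @return a list with \code{perClass} (data.frame: class, support,
#'   precision, recall, f1) and \code{average} (weighted average F1).
#' @export
scoreClassification <- function(truth, pred,
                                weights = c("none", "support", "volume"),
                                volume = NULL) {
  weights <- match.arg(weights)
  stopifnot(length(truth) == length(pred))
  if (weights == "volume") {
    if (is.null(volume)) stop("scoreClassification: volume weights missing")
    stopifnot(length(volume) == length(truth))
    w <- as.numeric(volume)
  } else w <- rep(1, length(truth))
  classes <- sort(unique(c(truth, pred)))
  rows <- lapply(classes, function(cl) {
    tp <- sum(w[truth == cl & pred == cl])
    fp <- sum(w[truth != cl & pred == cl])
    fn <- sum(w[truth == cl & pred != cl])
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    data.frame(class = cl, support = sum(w[truth == cl]),
               precision = p, recall = r,
               f1 = if (p + r > 0) 2 * p * r / (p + r) else 0)
  })
  perClass <- do.call(rbind, rows)
  aw <- switch(weights,
               none = rep(1, nrow(perClass)),
               support = perClass$support,
               volume = perClass$support)
  avg <- if (sum(aw) > 0) sum(perClass$f1 * aw) / sum(aw) else 0
  list(perClass = perClass, average = avg)
}
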