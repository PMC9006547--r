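# Boundary-level accuracy against planted ground truth.

#' Match predicted boundaries to ground-truth boundaries
#'
#' Greedy one-to-one matching: truth boundaries are visited in ascending
#' order and each is matched to the nearest still-unmatched predicted
#' boundary within `tolerance` bins (ties broken toward the lower bin
#' index). The matching is deterministic.
#'
#' @param pred,truth `BoundarySet`s at the same resolution.
#' @param tolerance maximum |pred - truth| distance in bins (default 0 =
#'   exact bin).
#' @return A list of class `MatchCounts` with integer fields `tp`, `fp`,
#'   `fn`.
#' @export
match_boundaries <- function(pred, truth, tolerance = 0) {
  stopifnot(inherits(pred, "BoundarySet"), inherits(truth, "BoundarySet"))
  if (pred$resolution != truth$resolution)
    stop("boundary sets have different resolutions")
  if (tolerance < 0) stop("tolerance must be >= 0")
  pb <- pred$bins; tb <- truth$bins
  used <- rep(FALSE, length(pb))
  tp <- 0L
  for (t in tb) {
    cand <- which(!used & abs(pb - t) <= tolerance)
    if (length(cand)) {
      dist <- abs(pb[cand] - t)
      best <- cand[dist == min(dist)]
      best <- best[which.min(pb[best])]   # tie -> lower bin index
      used[best] <- TRUE
      tp <- tp + 1L
    }
  }
  structure(list(tp = tp, fp = sum(!used),
                 fn = length(tb) - tp),
            class = "MatchCounts")
}

#' True positive rate of boundary recovery
#'
#' `tp / (tp + fn)`: the fraction of ground-truth boundaries recovered.
#'
#' @param c a `MatchCounts` from [match_boundaries()].
#' @return A value in \[0, 1\].
#' @export
tpr <- function(c) {
  stopifnot(inherits(c, "MatchCounts"))
  if (c$tp + c$fn == 0) stop("tpr undefined: no positive samples")
  c$tp / (c$tp + c$fn)
}

#' False positive rate of boundary calls
#'
#' `fp / (tp + fp)`: the fraction of predicted boundaries that match no
#' ground-truth boundary. Note this quantity is a false-discovery
#' proportion; the field uses the labels FPR and FDR interchangeably for
#' it, and [fdr()] is provided as an alias.
#'
#' @param c a `MatchCounts`.
#' @return A value in \[0, 1\].
#' @export
fpr <- function(c) {
  stopifnot(inherits(c, "MatchCounts"))
  if (c$tp + c$fp == 0) stop("fpr undefined: no predicted positives")
  c$fp / (c$tp + c$fp)
}

#' @rdname fpr
#' @export
fdr <- fpr
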