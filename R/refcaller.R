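# Reference insulation-score TAD caller: (1) per-bin insulation score =
# mean contact frequency between the upstream and downstream windows,
# (2) local minima of the normalized score are candidate boundaries,
# (3) minima with boundary strength below a threshold are filtered out.

#' Insulation score profile of a contact matrix
#'
#' `raw[i]` is the mean of `values[u, v]` over `u` in `[i - window, i)` and
#' `v` in `(i, i + window]` (0-based bins): the average contact frequency
#' crossing bin `i` within the window. The normalized score is
#' `log2(raw / mean(raw over valid bins))`. Bins within `window` bins of a
#' chromosome end lack a full window and are invalid.
#'
#' @param m a `ContactMatrix` with `n > 2 * window` bins.
#' @param window window size in bins.
#' @return A list of class `InsulationProfile` with numeric vectors `raw`
#'   and `normalized` (length `n`, `NA` at invalid bins), logical `valid`,
#'   and the `window`.
#' @export
insulation_score <- function(m, window) {
  stopifnot(inherits(m, "ContactMatrix"))
  n <- nrow(m$values)
  if (window < 1) stop("window must be >= 1")
  if (n <= 2 * window) stop("matrix too small for this window (n <= 2w)")
  raw <- rep(NA_real_, n)
  for (i in window:(n - 1 - window)) {   # 0-based bin index
    u <- (i - window):(i - 1)
    v <- (i + 1):(i + window)
    raw[i + 1] <- mean(m$values[u + 1, v + 1])
  }
  valid <- !is.na(raw)
  mu <- mean(raw[valid])
  normalized <- rep(NA_real_, n)
  if (mu > 0) normalized[valid] <- log2(raw[valid] / mu)
  structure(list(raw = raw, normalized = normalized, valid = valid,
                 window = window),
            class = "InsulationProfile")
}

#' @export
print.InsulationProfile <- function(x, ...) {
  cat(sprintf("InsulationProfile: %d bins (%d valid), window %d\n",
              length(x$raw), sum(x$valid), x$window))
  invisible(x)
}

# Plateau-aware local extrema of a numeric vector (no NAs).
# Returns leftmost index (1-based within x) of each strict minimum/maximum.
.local_extrema <- function(x) {
  r <- rle(x)
  k <- length(r$values)
  starts <- cumsum(c(1, r$lengths[-k]))
  minima <- integer(0); maxima <- integer(0)
  if (k >= 3) for (j in 2:(k - 1)) {
    if (r$values[j] < r$values[j - 1] && r$values[j] < r$values[j + 1])
      minima <- c(minima, starts[j])
    if (r$values[j] > r$values[j - 1] && r$values[j] > r$values[j + 1])
      maxima <- c(maxima, starts[j])
  }
  list(minima = minima, maxima = maxima)
}

#' Call TADs from insulation-score minima
#'
#' Local minima of the normalized insulation curve (strictly lower than
#' both neighbours; plateaus resolve to their leftmost bin) are candidate
#' boundaries. Each minimum's boundary strength is the mean rise from the
#' minimum to the nearest flanking local maxima of the curve (the first and
#' last valid bins stand in where a side has no local maximum); minima with
#' strength below `strength_threshold` are dropped. Domains are the
#' intervals between consecutive retained boundaries, with the ends of the
#' valid bin range closing the outermost domains; fragments shorter than 2
#' bins are dropped.
#'
#' @param m a `ContactMatrix`.
#' @param window insulation window in bins.
#' @param strength_threshold minimum boundary strength on the log2 curve
#'   (default 0.1).
#' @return A `DomainSet` of the called domains.
#' @export
call_domains_insulation <- function(m, window, strength_threshold = 0.1) {
  prof <- insulation_score(m, window)
  vidx <- which(prof$valid)            # 1-based matrix indices
  x <- prof$normalized[vidx]
  if (!length(x) || anyNA(x)) stop("no valid insulation scores")
  ext <- .local_extrema(x)
  minima <- ext$minima
  if (length(minima)) {
    strength <- vapply(minima, function(mi) {
      left_max <- ext$maxima[ext$maxima < mi]
      right_max <- ext$maxima[ext$maxima > mi]
      lv <- if (length(left_max)) x[max(left_max)] else x[1]
      rv <- if (length(right_max)) x[min(right_max)] else x[length(x)]
      mean(c(lv - x[mi], rv - x[mi]))
    }, numeric(1))
    minima <- minima[strength >= strength_threshold]
  }
  # 0-based boundary bins; valid-range ends close the outermost domains
  bmins <- vidx[minima] - 1
  edges <- c(vidx[1] - 1, bmins, vidx[length(vidx)])
  s <- edges[-length(edges)]
  e <- edges[-1]
  keep <- (e - s) >= 2
  domain_set(s[keep], e[keep], m$resolution, nrow(m$values),
             chrom = m$chrom)
}
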