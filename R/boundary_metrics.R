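# Metrics for regulatory-element occurrence around TAD boundaries: the
# average peak, boundary tagged ratio, fold change, Gaussian p-value ratio,
# both Jaccard variants, and the per-offset enrichment/depletion profile.
#
# All windows are half-open [a, b) in bp. The bp anchor of a boundary bin is
# its left edge (bin * resolution) by default. Windows running past a
# chromosome end are clipped and denominators reduced to the covered extent.

# number of sorted positions in [a, b)
.count_in <- function(positions, a, b) {
  if (length(positions) == 0) return(rep(0L, length(a)))
  findInterval(b - 0.5, positions) - findInterval(a - 0.5, positions)
}

.boundary_bp <- function(b, anchor = c("left", "midpoint")) {
  anchor <- match.arg(anchor)
  pos <- b$bins * b$resolution
  if (anchor == "midpoint") pos <- pos + b$resolution / 2
  pos
}

.chrom_length <- function(b) {
  if (is.na(b$n_bins)) Inf else b$n_bins * b$resolution
}

#' Per-boundary occurrence statistics of a regulatory element
#'
#' For each unique boundary at bp position `b` this computes:
#' * `A`: occurrences per 1 kb in the 2 kb window `[b - 1000, b + 1000)`;
#' * `B`: occurrences per 1 kb in the bilateral background regions
#'   `[b - 500000, b - 200000)` and `[b + 200000, b + 500000)`;
#' * `C`: sample variance of the per-1 kb counts over those bilateral
#'   windows (600 of them on an interior boundary; fewer near a chromosome
#'   end, where only fully covered 1 kb windows enter).
#'
#' @param b a `BoundarySet`.
#' @param p a `PeakTrack`.
#' @param anchor bp anchor of a boundary bin: its left edge (default) or
#'   midpoint.
#' @return A list of class `BoundaryElementStats` with numeric vectors
#'   `A`, `B`, `C` and the boundary count `n`.
#' @export
compute_boundary_stats <- function(b, p, anchor = c("left", "midpoint")) {
  stopifnot(inherits(b, "BoundarySet"), inherits(p, "PeakTrack"))
  if (length(b$bins) == 0) stop("no boundaries")
  pos <- .boundary_bp(b, match.arg(anchor))
  L <- .chrom_length(b)
  n <- length(pos)

  # near window, clipped
  a0 <- pmax(pos - 1000, 0)
  b0 <- pmin(pos + 1000, L)
  kb <- (b0 - a0) / 1000
  A <- ifelse(kb > 0, .count_in(p$positions, a0, b0) / kb, 0)

  B <- numeric(n); C <- numeric(n)
  for (i in seq_len(n)) {
    starts <- c(seq(pos[i] - 500000, pos[i] - 200000 - 1000, by = 1000),
                seq(pos[i] + 200000, pos[i] + 500000 - 1000, by = 1000))
    keep <- starts >= 0 & (starts + 1000) <= L
    starts <- starts[keep]
    if (length(starts) == 0) { B[i] <- 0; C[i] <- 0; next }
    cnt <- .count_in(p$positions, starts, starts + 1000)
    B[i] <- mean(cnt)
    C[i] <- if (length(cnt) > 1) stats::var(cnt) else 0
  }
  structure(list(A = A, B = B, C = C, n = n),
            class = "BoundaryElementStats")
}

#' Average peak: mean near-boundary element density
#'
#' The mean over unique boundaries of the per-1 kb occurrence density in
#' the centred 2 kb window.
#'
#' @param stats a `BoundaryElementStats` from [compute_boundary_stats()].
#' @return A single real value.
#' @export
average_peak <- function(stats) {
  stopifnot(inherits(stats, "BoundaryElementStats"))
  if (stats$n == 0) stop("no boundaries")
  mean(stats$A)
}

#' Boundary tagged ratio
#'
#' Fraction of unique boundaries with at least one element occurrence in
#' the centred 2 kb window.
#'
#' @inheritParams compute_boundary_stats
#' @return A value in \[0, 1\].
#' @export
boundary_tagged_ratio <- function(b, p, anchor = c("left", "midpoint")) {
  stopifnot(inherits(b, "BoundarySet"), inherits(p, "PeakTrack"))
  if (length(b$bins) == 0) stop("no boundaries")
  pos <- .boundary_bp(b, match.arg(anchor))
  L <- .chrom_length(b)
  cnt <- .count_in(p$positions, pmax(pos - 1000, 0), pmin(pos + 1000, L))
  mean(cnt >= 1)
}

#' Fold change of near-boundary over background element density
#'
#' Mean over boundaries of `log2((A + pc) / (B + pc))` where `A` is the
#' near-boundary density, `B` the bilateral 200-500 kb background density
#' and `pc` a pseudocount guarding against zeros (default 1/600, one event
#' spread over the full bilateral span).
#'
#' @param stats a `BoundaryElementStats`.
#' @param pseudocount small positive stabiliser.
#' @return The mean log2 fold change; positive for enrichment, negative for
#'   depletion.
#' @export
fold_change <- function(stats, pseudocount = 1 / 600) {
  stopifnot(inherits(stats, "BoundaryElementStats"))
  if (stats$n == 0) stop("no boundaries")
  mean(log2((stats$A + pseudocount) / (stats$B + pseudocount)))
}

#' Fraction of boundaries with significant element density
#'
#' Each boundary's near density `A` is referred to a Gaussian with the
#' bilateral background mean `B` and variance `C`; the reported value is the
#' fraction of boundaries whose one-sided tail probability is at most
#' `alpha` (upper tail for `"enrichment"`, lower tail for `"depletion"`).
#' Degenerate `C = 0` backgrounds count as significant iff `A` lies strictly
#' on the tested side of `B`.
#'
#' @param stats a `BoundaryElementStats`.
#' @param alpha significance level (default 0.05).
#' @param direction test direction, `"enrichment"` or `"depletion"`.
#' @return A value in \[0, 1\].
#' @export
pvalue_ratio <- function(stats, alpha = 0.05,
                         direction = c("enrichment", "depletion")) {
  stopifnot(inherits(stats, "BoundaryElementStats"))
  direction <- match.arg(direction)
  if (stats$n == 0) stop("no boundaries")
  if (any(stats$C < 0)) stop("negative variance in boundary stats")
  sig <- logical(stats$n)
  for (i in seq_len(stats$n)) {
    if (stats$C[i] == 0) {
      sig[i] <- if (direction == "enrichment")
        stats$A[i] > stats$B[i] else stats$A[i] < stats$B[i]
    } else {
      pv <- stats::pnorm(stats$A[i], mean = stats$B[i],
                         sd = sqrt(stats$C[i]),
                         lower.tail = (direction == "depletion"))
      sig[i] <- pv <= alpha
    }
  }
  mean(sig)
}

#' Jaccard index between two boundary sets
#'
#' Exact-bin intersection over union, without shifting to neighbouring
#' bins. An empty union returns 0 by convention (with a message).
#'
#' @param a,b `BoundarySet`s at the same resolution.
#' @return A value in \[0, 1\].
#' @export
jaccard_boundaries <- function(a, b) {
  stopifnot(inherits(a, "BoundarySet"), inherits(b, "BoundarySet"))
  if (a$resolution != b$resolution)
    stop("boundary sets have different resolutions")
  u <- length(union(a$bins, b$bins))
  if (u == 0) {
    message("both boundary sets empty; Jaccard index defined as 0")
    return(0)
  }
  length(intersect(a$bins, b$bins)) / u
}

#' Jaccard-style overlap between boundaries and element occurrences
#'
#' Both variants share the denominator `n_boundaries + n_elements` (the
#' literal definition used for boundary-vs-element comparison, where the
#' two sets live on different position scales and a true union is not
#' defined). `ji_boundaries` counts boundaries with at least one element
#' within `±window` bp; `ji_elements` counts elements within `±window` bp
#' of at least one boundary. With `strict_union = TRUE` the denominator is
#' replaced by the union-style count
#' `n_boundaries + n_elements - matched_boundaries`.
#'
#' @param b a `BoundarySet`.
#' @param p a `PeakTrack`.
#' @param window half-width of the matching window in bp (default 10000).
#' @param anchor boundary bp anchor, see [compute_boundary_stats()].
#' @param strict_union use a union-style denominator instead of the size
#'   sum.
#' @return A list with `ji_boundaries` and `ji_elements`.
#' @export
jaccard_boundary_elements <- function(b, p, window = 10000,
                                      anchor = c("left", "midpoint"),
                                      strict_union = FALSE) {
  stopifnot(inherits(b, "BoundarySet"), inherits(p, "PeakTrack"))
  nb <- length(b$bins); ne <- length(p$positions)
  if (nb + ne == 0) stop("both boundary and element sets are empty")
  pos <- .boundary_bp(b, match.arg(anchor))
  hit_b <- .count_in(p$positions, pos - window, pos + window + 1) >= 1
  hit_e <- if (ne == 0) logical(0) else
    vapply(p$positions,
           function(x) any(abs(pos - x) <= window), logical(1))
  denom <- if (strict_union) nb + ne - sum(hit_b) else nb + ne
  list(ji_boundaries = sum(hit_b) / denom,
       ji_elements = sum(hit_e) / denom)
}

#' Element density profile around TAD boundaries
#'
#' For offsets `o = -span, -span + step, ..., span - step` the profile value
#' is the mean over boundaries of the occurrence count in
#' `[b + o, b + o + step)` scaled to events per 1 kb. Windows falling off
#' the chromosome are clipped (density over the covered part); boundaries
#' with no coverage at an offset do not contribute to that offset's mean.
#'
#' @param b a `BoundarySet`.
#' @param p a `PeakTrack`.
#' @param span profile half-width in bp (default 500000).
#' @param step window width in bp (default 1000); must divide `span`.
#' @param anchor boundary bp anchor.
#' @return A data.frame with columns `offset_bp` (window start offset) and
#'   `density` (occurrences per 1 kb).
#' @export
enrichment_profile <- function(b, p, span = 500000, step = 1000,
                               anchor = c("left", "midpoint")) {
  stopifnot(inherits(b, "BoundarySet"), inherits(p, "PeakTrack"))
  if (length(b$bins) == 0) stop("no boundaries")
  if (span %% step != 0) stop("step must divide span")
  pos <- .boundary_bp(b, match.arg(anchor))
  L <- .chrom_length(b)
  offsets <- seq(-span, span - step, by = step)
  dens <- vapply(offsets, function(o) {
    a <- pos + o
    bb <- a + step
    a_cl <- pmax(a, 0); b_cl <- pmin(bb, L)
    cover <- pmax(b_cl - a_cl, 0)
    use <- cover > 0
    if (!any(use)) return(NA_real_)
    cnt <- .count_in(p$positions, a_cl[use], b_cl[use])
    mean(cnt / (cover[use] / 1000))
  }, numeric(1))
  data.frame(offset_bp = offsets, density = dens)
}
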