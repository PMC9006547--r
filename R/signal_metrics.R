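# Distance-stratified adjusted-R2: the fraction of contact-signal variance
# at a fixed genomic distance explained by a TAD partition.

# Assign each distance-d entry (i, i+d) to a region: the smallest domain
# containing both endpoints, else the gap run containing both, else none.
# Returns an integer region id per entry (NA = excluded).
.assign_entries <- function(d, dist, level0_only = FALSE) {
  n <- d$n_bins
  i <- 0:(n - dist - 1)            # left endpoint of each entry
  region <- rep(NA_integer_, length(i))
  dom <- d$domains
  if (level0_only) dom <- dom[dom$level == 0, , drop = FALSE]
  if (nrow(dom)) {
    size <- dom$end_bin - dom$start_bin
    ord <- order(size)             # smallest containing domain wins
    for (k in rev(ord)) {          # assign largest first, overwrite smaller
      inside <- i >= dom$start_bin[k] & (i + dist) <= dom$end_bin[k] - 1
      region[inside] <- k
    }
  }
  top <- d$domains[d$domains$level == 0, , drop = FALSE]
  gaps <- .gap_runs(top$start_bin, top$end_bin, n)
  if (nrow(gaps)) {
    for (g in seq_len(nrow(gaps))) {
      inside <- is.na(region) & i >= gaps$start[g] &
        (i + dist) <= gaps$end[g] - 1
      region[inside] <- nrow(dom) + g
    }
  }
  list(i = i, region = region, n_domains = nrow(dom),
       dom_sizes = if (nrow(dom)) dom$end_bin - dom$start_bin else integer(0))
}

#' Adjusted R-squared of a TAD partition at one genomic distance
#'
#' At distance `d` (in bins) every matrix entry `(i, i + d)` whose two
#' endpoint bins lie in the same domain (the smallest containing domain for
#' hierarchical calls) or the same gap run is retained; entries straddling a
#' region edge are excluded. With `Y` the retained values, `Yhat` the
#' within-region means, `Ybar` the global mean, `q` the number of retained
#' entries and `p` the number of domains whose size (in bins) is at least
#' `d`, the statistic is
#' `1 - ((q - 1) * sum((Y - Yhat)^2)) / ((q - p - 1) * sum((Y - Ybar)^2))`.
#'
#' @param m a `ContactMatrix`.
#' @param d a `DomainSet` on the same chromosome/resolution.
#' @param distance genomic distance in bins, `1 <= distance < n`.
#' @param level0_only if `TRUE`, only top-level domains define regions and
#'   count toward `p`; by default all nesting levels do.
#' @return The adjusted R-squared, or `NA` when undefined
#'   (`q - p - 1 <= 0` or zero total sum of squares).
#' @export
tad_adj_r2 <- function(m, d, distance, level0_only = FALSE) {
  stopifnot(inherits(m, "ContactMatrix"), inherits(d, "DomainSet"))
  n <- nrow(m$values)
  if (n != d$n_bins)
    stop("matrix and domain set disagree on the number of bins")
  if (distance < 1 || distance >= n)
    stop("distance must lie in [1, n - 1]")
  asg <- .assign_entries(d, distance, level0_only)
  keep <- !is.na(asg$region)
  if (!any(keep)) return(NA_real_)
  i <- asg$i[keep]
  Y <- m$values[cbind(i + 1, i + distance + 1)]
  region <- asg$region[keep]
  q <- length(Y)
  p <- sum(asg$dom_sizes >= distance)
  if (q - p - 1 <= 0) return(NA_real_)
  Yhat <- stats::ave(Y, region)
  Ybar <- mean(Y)
  sst <- sum((Y - Ybar)^2)
  if (sst == 0) return(NA_real_)
  sse <- sum((Y - Yhat)^2)
  1 - ((q - 1) * sse) / ((q - p - 1) * sst)
}

#' Adjusted R-squared profile over a distance range
#'
#' Evaluates [tad_adj_r2()] at every distance in `d_min:d_max`; undefined
#' distances are skipped in the summary statistics.
#'
#' @inheritParams tad_adj_r2
#' @param d_min,d_max distance range in bins.
#' @return A list with `mean`, `max`, `min` over defined distances and the
#'   full `profile` data.frame (`distance_bins`, `distance_bp`, `adj_r2`).
#' @export
tad_adj_r2_profile <- function(m, d, d_min = 1, d_max = NULL,
                               level0_only = FALSE) {
  stopifnot(inherits(m, "ContactMatrix"))
  n <- nrow(m$values)
  if (is.null(d_max)) d_max <- n - 1
  if (d_min < 1 || d_max >= n || d_min > d_max)
    stop("invalid distance range")
  dists <- d_min:d_max
  vals <- vapply(dists, function(dd) tad_adj_r2(m, d, dd, level0_only),
                 numeric(1))
  if (all(is.na(vals)))
    stop("adjusted R-squared undefined at every distance in the range")
  list(mean = mean(vals, na.rm = TRUE),
       max = max(vals, na.rm = TRUE),
       min = min(vals, na.rm = TRUE),
       profile = data.frame(distance_bins = dists,
                            distance_bp = dists * m$resolution,
                            adj_r2 = vals))
}
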