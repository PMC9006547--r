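# Quartile ranking of callers per metric column and the summed-rank
# aggregation used to order callers across regulatory elements.

#' Quartile ranking levels of a metric column
#'
#' The range between the minimum and maximum value is divided into four
#' equal half-open intervals in ascending order; values map to levels 1-4
#' (`1 + floor((v - lo) / w)` with `w = (hi - lo)/4`, the maximum folded
#' into level 4). Missing values yield missing levels. If all finite
#' values are equal the range is degenerate and every value is assigned
#' level 1 with a warning.
#'
#' @param values numeric vector of a metric across callers (at least two
#'   finite values to define a range).
#' @param direction `"ascending"` (higher value, higher level; default) or
#'   `"descending"` for metrics where lower is better.
#' @return Integer vector of levels in 1..4 (NA where `values` is NA).
#' @examples
#' rank_levels(c(0.1, 0.2, 0.5, 0.9))  # 1 1 3 4
#' @export
rank_levels <- function(values, direction = c("ascending", "descending")) {
  direction <- match.arg(direction)
  fin <- is.finite(values)
  if (sum(fin) < 2) stop("need at least 2 finite values to rank")
  lo <- min(values[fin]); hi <- max(values[fin])
  out <- rep(NA_integer_, length(values))
  if (lo == hi) {
    warning("degenerate range (all values equal); assigning level 1")
    out[fin] <- 1L
    return(out)
  }
  w <- (hi - lo) / 4
  lev <- pmin(1L + as.integer(floor((values[fin] - lo) / w)), 4L)
  if (direction == "descending") lev <- 5L - lev
  out[fin] <- lev
  out
}

#' Summed ranking levels per caller across metric columns
#'
#' Applies [rank_levels()] to each column of a caller-by-metric table and
#' sums the levels per caller over the non-excluded columns. Missing
#' values contribute 0 to the sum; the `n_ranked` column reports how many
#' columns each caller's sum actually covers.
#'
#' @param tbl numeric matrix or data.frame: rows = callers (rownames used
#'   as caller names), columns = (element, metric) combinations.
#' @param exclude character vector of column names to leave out (e.g. the
#'   columns of a depletion-direction element such as H3K9me3).
#' @param direction single direction for all columns or a named character
#'   vector per column (`"ascending"`/`"descending"`).
#' @return A data.frame with `caller`, `rank_sum`, `n_ranked`, sorted in
#'   the input row order.
#' @export
aggregate_rank <- function(tbl, exclude = character(0),
                           direction = "ascending") {
  tbl <- as.matrix(tbl)
  if (is.null(rownames(tbl))) rownames(tbl) <- paste0("caller", seq_len(nrow(tbl)))
  if (nrow(tbl) < 2) stop("need at least 2 callers")
  keep <- setdiff(colnames(tbl), exclude)
  if (length(keep) == 0) stop("no rankable columns after exclusion")
  tbl <- tbl[, keep, drop = FALSE]
  levels <- matrix(NA_integer_, nrow(tbl), ncol(tbl),
                   dimnames = dimnames(tbl))
  for (j in seq_len(ncol(tbl))) {
    dir_j <- if (length(direction) == 1) direction
             else direction[[colnames(tbl)[j]]]
    levels[, j] <- rank_levels(tbl[, j], direction = dir_j)
  }
  data.frame(caller = rownames(tbl),
             rank_sum = rowSums(levels, na.rm = TRUE),
             n_ranked = rowSums(!is.na(levels)),
             row.names = NULL)
}
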