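# Batch evaluation: run every metric for every caller against one dataset
# and collect the long-form MetricReport consumed by the ranking stage.

#' Evaluate many callers' domain sets against one dataset
#'
#' For each caller this computes the domain/gap summary; per regulatory
#' element the average peak, boundary tagged ratio, fold change, p-value
#' ratio and both Jaccard variants; the adjusted-R-squared profile summary
#' when a matrix is supplied; the corner-dot summary; and boundary-level
#' TPR/FPR when ground truth is supplied. Results are returned long-form,
#' one row per (caller, element, metric), with a parameter fingerprint so
#' every value can be reproduced by calling the underlying operation
#' directly.
#'
#' @param domains_by_caller named list of `DomainSet`s, one per caller.
#' @param matrix optional `ContactMatrix` shared by all callers.
#' @param tracks named list of `PeakTrack`s, one per regulatory element.
#' @param truth optional ground-truth `DomainSet`.
#' @param params list of evaluation parameters: `ji_window` (bp, default
#'   10000), `pseudocount` (default 1/600), `alpha` (default 0.05),
#'   `direction` (`"enrichment"`), `tolerance` (bins, default 0),
#'   `d_min`/`d_max` (adjusted-R2 distance range in bins),
#'   `dot_threshold` (default 1.5), `dot_halo` (default 2).
#' @return A data.frame of class `MetricReport` with columns `caller`,
#'   `element`, `metric`, `value`, `params`.
#' @export
evaluate_all <- function(domains_by_caller, matrix = NULL,
                         tracks = list(), truth = NULL, params = list()) {
  stopifnot(is.list(domains_by_caller), length(domains_by_caller) >= 1)
  if (is.null(names(domains_by_caller)) ||
      any(!nzchar(names(domains_by_caller))))
    stop("domains_by_caller must be a named list")
  p <- utils::modifyList(list(
    ji_window = 10000, pseudocount = 1 / 600, alpha = 0.05,
    direction = "enrichment", tolerance = 0,
    d_min = 1, d_max = NULL, dot_threshold = 1.5, dot_halo = 2), params)

  resolutions <- vapply(domains_by_caller, function(d) d$resolution,
                        numeric(1))
  if (!is.null(matrix)) resolutions <- c(resolutions, matrix$resolution)
  if (!is.null(truth)) resolutions <- c(resolutions, truth$resolution)
  if (length(unique(resolutions)) > 1)
    stop("resolution mismatch across inputs: ",
         paste(unique(resolutions), collapse = ", "))

  fingerprint <- paste(names(p), vapply(p, function(v)
    paste(format(v), collapse = ","), character(1)),
    sep = "=", collapse = ";")
  rows <- list()
  add <- function(caller, element, metric, value) {
    rows[[length(rows) + 1]] <<- data.frame(
      caller = caller, element = element, metric = metric,
      value = as.numeric(value), params = fingerprint)
  }

  truth_b <- if (!is.null(truth)) domains_to_boundaries(truth)

  for (caller in names(domains_by_caller)) {
    d <- domains_by_caller[[caller]]
    b <- domains_to_boundaries(d)
    sm <- domain_summary(d)
    for (k in names(sm)) add(caller, "summary", k, sm[[k]])

    for (el in names(tracks)) {
      tr <- tracks[[el]]
      if (length(b$bins) == 0) next
      st <- compute_boundary_stats(b, tr)
      add(caller, el, "average_peak", average_peak(st))
      add(caller, el, "boundary_tagged_ratio",
          boundary_tagged_ratio(b, tr))
      add(caller, el, "fold_change", fold_change(st, p$pseudocount))
      add(caller, el, "pvalue_ratio",
          pvalue_ratio(st, p$alpha, p$direction))
      ji <- jaccard_boundary_elements(b, tr, window = p$ji_window)
      add(caller, el, "ji_boundaries", ji$ji_boundaries)
      add(caller, el, "ji_elements", ji$ji_elements)
    }

    if (!is.null(matrix)) {
      d_max <- if (is.null(p$d_max)) nrow(matrix$values) - 1 else p$d_max
      pr <- tryCatch(
        tad_adj_r2_profile(matrix, d, p$d_min, d_max),
        error = function(e) NULL)
      if (!is.null(pr)) {
        add(caller, "signal", "adj_r2_mean", pr$mean)
        add(caller, "signal", "adj_r2_max", pr$max)
        add(caller, "signal", "adj_r2_min", pr$min)
      }
      if (nrow(d$domains)) {
        cd <- classify_corner_dots(matrix, d, p$dot_threshold, p$dot_halo)
        add(caller, "signal", "fraction_with_dot",
            cd$summary$fraction_with_dot)
        add(caller, "signal", "mean_size_with_dot_bp",
            cd$summary$mean_size_with_bp)
        add(caller, "signal", "mean_size_without_dot_bp",
            cd$summary$mean_size_without_bp)
      }
    }

    if (!is.null(truth)) {
      mc <- match_boundaries(b, truth_b, p$tolerance)
      add(caller, "truth", "tp", mc$tp)
      add(caller, "truth", "fp", mc$fp)
      add(caller, "truth", "fn", mc$fn)
      if (mc$tp + mc$fn > 0) add(caller, "truth", "tpr", tpr(mc))
      if (mc$tp + mc$fp > 0) add(caller, "truth", "fpr", fpr(mc))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("MetricReport", "data.frame")
  out
}

#' Write a MetricReport as tab-separated text
#' @param report a `MetricReport`.
#' @param path output file path.
#' @export
write_metric_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Pivot a MetricReport into a caller-by-column table for ranking
#'
#' Selects one metric across elements (or any subset of (element, metric)
#' pairs) and returns a caller-by-column numeric matrix whose columns are
#' named `element.metric`, ready for [aggregate_rank()].
#'
#' @param report a `MetricReport` from [evaluate_all()].
#' @param metrics character vector of metric names to include.
#' @param elements optional character vector of elements to include
#'   (default: all elements present for the chosen metrics).
#' @return A numeric matrix, rows = callers, columns = element.metric.
#' @export
metric_table <- function(report, metrics, elements = NULL) {
  stopifnot(inherits(report, "data.frame"))
  sub <- report[report$metric %in% metrics, , drop = FALSE]
  if (!is.null(elements))
    sub <- sub[sub$element %in% elements, , drop = FALSE]
  if (nrow(sub) == 0) stop("no matching rows in report")
  callers <- unique(report$caller)
  cols <- unique(paste(sub$element, sub$metric, sep = "."))
  M <- matrix(NA_real_, length(callers), length(cols),
              dimnames = list(callers, cols))
  key <- paste(sub$element, sub$metric, sep = ".")
  for (r in seq_len(nrow(sub)))
    M[sub$caller[r], key[r]] <- sub$value[r]
  M
}
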