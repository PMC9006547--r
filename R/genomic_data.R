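#' Construct a set of TAD domains for one chromosome
#'
#' A `DomainSet` holds the topologically associating domains (TADs) called on
#' a single chromosome, in 0-based half-open bin coordinates. Domains may be
#' nested (subTADs strictly contained in TADs) but partial overlap is
#' rejected: any two domains must be disjoint or one must strictly contain
#' the other. Nesting depth is recomputed from containment, so a supplied
#' `level` column is ignored.
#'
#' @param start_bin integer vector of domain start bins (0-based, inclusive).
#' @param end_bin integer vector of domain end bins (0-based, exclusive).
#' @param resolution bin width in base pairs.
#' @param n_bins total number of bins on the chromosome.
#' @param chrom chromosome name.
#' @param corner_dot optional logical vector labelling each domain as a
#'   corner-dot (extrusion-loop) domain; `NA` when unknown.
#' @return An object of class `DomainSet`: a list with elements `chrom`,
#'   `resolution`, `n_bins` and `domains` (a data.frame with columns
#'   `start_bin`, `end_bin`, `level`, `corner_dot`, sorted by start then by
#'   decreasing size so parents precede their subdomains).
#' @examples
#' d <- domain_set(c(0, 4), c(20, 12), resolution = 5000, n_bins = 30)
#' d$domains$level   # 0 (top) and 1 (nested)
#' @export
domain_set <- function(start_bin, end_bin, resolution, n_bins,
                       chrom = "chr1", corner_dot = NULL) {
  start_bin <- as.integer(start_bin)
  end_bin <- as.integer(end_bin)
  stopifnot(length(start_bin) == length(end_bin),
            is.numeric(resolution), resolution > 0,
            is.numeric(n_bins), n_bins >= 1)
  k <- length(start_bin)
  if (is.null(corner_dot)) corner_dot <- rep(NA, k)
  corner_dot <- as.logical(corner_dot)
  if (length(corner_dot) != k)
    stop("corner_dot must have one entry per domain")
  if (k > 0) {
    if (any(start_bin < 0) || any(end_bin > n_bins))
      stop("domain bin indices must lie in [0, n_bins]")
    bad <- which(end_bin - start_bin < 2L)
    if (length(bad))
      stop("domain size must be at least 2 bins (violated at row ",
           bad[1], ")")
    .check_nesting(start_bin, end_bin)
  }
  level <- .nesting_levels(start_bin, end_bin)
  dom <- data.frame(start_bin = start_bin, end_bin = end_bin,
                    level = level, corner_dot = corner_dot)
  # parents before children, left to right
  ord <- order(dom$start_bin, -(dom$end_bin - dom$start_bin))
  dom <- dom[ord, , drop = FALSE]
  rownames(dom) <- NULL
  structure(list(chrom = chrom, resolution = as.numeric(resolution),
                 n_bins = as.integer(n_bins), domains = dom),
            class = "DomainSet")
}

# Nesting-only invariant: every pair disjoint or strictly nested.
.check_nesting <- function(s, e) {
  k <- length(s)
  if (k < 2) return(invisible(TRUE))
  ord <- order(s, -e)
  ss <- s[ord]; ee <- e[ord]
  for (i in 2:k) {
    for (j in (i - 1):1) {
      if (ee[j] <= ss[i]) next      # disjoint, earlier
      # overlap exists; must be containment within j
      if (ss[i] == ss[j] && ee[i] == ee[j])
        stop(sprintf("duplicate domains [%d,%d) not allowed", ss[i], ee[i]))
      if (!(ss[j] <= ss[i] && ee[i] <= ee[j]))
        stop(sprintf(
          "domains [%d,%d) and [%d,%d) partially overlap; only nesting is allowed",
          ss[j], ee[j], ss[i], ee[i]))
    }
  }
  invisible(TRUE)
}

.nesting_levels <- function(s, e) {
  k <- length(s)
  if (k == 0) return(integer(0))
  lev <- integer(k)
  for (i in seq_len(k)) {
    lev[i] <- sum(s <= s[i] & e[i] <= e & !(s == s[i] & e == e[i]))
  }
  lev
}

#' @export
print.DomainSet <- function(x, ...) {
  cat(sprintf("DomainSet: %d domains on %s (%d bins at %g bp)\n",
              nrow(x$domains), x$chrom, x$n_bins, x$resolution))
  if (nrow(x$domains)) {
    cat(sprintf("  levels: %s; corner-dot labels: %d\n",
                paste(sort(unique(x$domains$level)), collapse = ","),
                sum(!is.na(x$domains$corner_dot))))
  }
  invisible(x)
}

#' Construct a set of unique TAD boundary bins
#'
#' @param bins integer vector of boundary bin indices; deduplicated and
#'   sorted.
#' @param resolution bin width in bp.
#' @param chrom chromosome name.
#' @param n_bins optional chromosome length in bins; used to clip
#'   boundary-centred windows at the right chromosome end (`NA` disables
#'   right clipping).
#' @return An object of class `BoundarySet`.
#' @export
boundary_set <- function(bins, resolution, chrom = "chr1", n_bins = NA) {
  bins <- sort(unique(as.integer(bins)))
  if (length(bins) && any(bins < 0)) stop("boundary bins must be >= 0")
  structure(list(chrom = chrom, resolution = as.numeric(resolution),
                 bins = bins, n_bins = as.integer(n_bins)),
            class = "BoundarySet")
}

#' @export
print.BoundarySet <- function(x, ...) {
  cat(sprintf("BoundarySet: %d unique boundaries on %s at %g bp/bin\n",
              length(x$bins), x$chrom, x$resolution))
  invisible(x)
}

#' Construct a track of regulatory-element occurrences
#'
#' Each occurrence is a single bp position (typically a peak midpoint).
#'
#' @param positions numeric vector of occurrence positions in bp; sorted.
#' @param chrom chromosome name.
#' @return An object of class `PeakTrack`.
#' @export
peak_track <- function(positions, chrom = "chr1") {
  positions <- sort(as.numeric(positions))
  if (length(positions) && any(positions < 0))
    stop("positions must be >= 0")
  structure(list(chrom = chrom, positions = positions), class = "PeakTrack")
}

#' @export
print.PeakTrack <- function(x, ...) {
  cat(sprintf("PeakTrack: %d occurrences on %s\n",
              length(x$positions), x$chrom))
  invisible(x)
}

#' Read TAD domains from a BED-like 3-column file
#'
#' Rows are `chrom  start-bp  end-bp` (tab- or whitespace-separated, no
#' header), 0-based half-open bp coordinates. Coordinates not aligned to the
#' bin grid are snapped outward (floor for starts, ceiling for ends) with a
#' warning. All rows must belong to a single chromosome.
#'
#' @param path file path.
#' @param resolution bin width in bp.
#' @param n_bins chromosome length in bins.
#' @return A [domain_set()].
#' @export
read_domains <- function(path, resolution, n_bins) {
  tab <- .read_bed3(path)
  if (nrow(tab) == 0)
    return(domain_set(integer(0), integer(0), resolution, n_bins))
  if (length(unique(tab$chrom)) > 1)
    stop("multiple chromosomes in ", path,
         "; one chromosome per file is required")
  sb <- tab$start / resolution
  eb <- tab$end / resolution
  if (any(sb != floor(sb)) || any(eb != ceiling(eb)))
    warning("coordinates not aligned to the bin grid; snapping outward")
  domain_set(floor(sb), ceiling(eb), resolution, n_bins,
             chrom = tab$chrom[1])
}

.read_bed3 <- function(path) {
  tab <- tryCatch(
    utils::read.table(path, header = FALSE, fill = TRUE,
                      stringsAsFactors = FALSE),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e)))
        return(data.frame(V1 = character(0), V2 = numeric(0),
                          V3 = numeric(0)))
      stop("cannot parse ", path, ": ", conditionMessage(e), call. = FALSE)
    })
  if (nrow(tab) == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0)))
  if (ncol(tab) < 3)
    stop("expected at least 3 columns (chrom, start, end) in ", path)
  start <- suppressWarnings(as.numeric(tab[[2]]))
  end <- suppressWarnings(as.numeric(tab[[3]]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("malformed row at line ", bad[1], " of ", path)
  bad <- which(start > end)
  if (length(bad))
    stop("start > end at line ", bad[1], " of ", path)
  data.frame(chrom = as.character(tab[[1]]), start = start, end = end)
}

#' Write TAD domains as BED3
#'
#' Inverse of [read_domains()]: bin coordinates are converted back to bp as
#' `start_bin * resolution` / `end_bin * resolution`, so a read/write cycle
#' reproduces bin coordinates exactly.
#'
#' @param d a `DomainSet`.
#' @param path output file path.
#' @export
write_domains <- function(d, path) {
  stopifnot(inherits(d, "DomainSet"))
  tab <- data.frame(chrom = d$chrom,
                    start = d$domains$start_bin * d$resolution,
                    end = d$domains$end_bin * d$resolution)
  utils::write.table(format(tab, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Extract the unique TAD boundaries of a domain set
#'
#' Boundaries are the deduplicated, sorted union of all domain start and end
#' bins. A boundary shared by two adjacent TADs counts once.
#'
#' @param d a `DomainSet`.
#' @param levels optional integer vector of nesting levels to include
#'   (default: all levels).
#' @return A [boundary_set()] carrying the chromosome's `n_bins`.
#' @export
domains_to_boundaries <- function(d, levels = NULL) {
  stopifnot(inherits(d, "DomainSet"))
  dom <- d$domains
  if (!is.null(levels)) dom <- dom[dom$level %in% levels, , drop = FALSE]
  boundary_set(c(dom$start_bin, dom$end_bin), d$resolution,
               chrom = d$chrom, n_bins = d$n_bins)
}

#' Read regulatory-element occurrences from a BED/narrowPeak file
#'
#' Each interval contributes one occurrence at its midpoint
#' `floor((start + end) / 2)`. Extra columns beyond the first three are
#' ignored.
#'
#' @param path file path.
#' @return A [peak_track()].
#' @export
read_peaks <- function(path) {
  tab <- .read_bed3(path)
  if (nrow(tab) == 0) return(peak_track(numeric(0)))
  peak_track(floor((tab$start + tab$end) / 2), chrom = tab$chrom[1])
}

#' Summarise TAD and gap structure of a domain set
#'
#' Gaps are maximal runs of bins in `[0, n_bins)` covered by no level-0
#' domain.
#'
#' @param d a `DomainSet`.
#' @return A list with `tad_count`, `mean_tad_size_bp`, `gap_count`,
#'   `mean_gap_size_bp` (the mean sizes are `NA` when the respective count
#'   is zero).
#' @examples
#' d <- domain_set(c(2), c(6), resolution = 1000, n_bins = 10)
#' domain_summary(d)  # 1 TAD of 4000 bp, gaps [0,2) and [6,10)
#' @export
domain_summary <- function(d) {
  stopifnot(inherits(d, "DomainSet"))
  top <- d$domains[d$domains$level == 0, , drop = FALSE]
  gaps <- .gap_runs(top$start_bin, top$end_bin, d$n_bins)
  tad_sizes <- (top$end_bin - top$start_bin) * d$resolution
  gap_sizes <- (gaps$end - gaps$start) * d$resolution
  list(tad_count = nrow(top),
       mean_tad_size_bp = if (nrow(top)) mean(tad_sizes) else NA_real_,
       gap_count = nrow(gaps),
       mean_gap_size_bp = if (nrow(gaps)) mean(gap_sizes) else NA_real_)
}

# Maximal uncovered runs of [0, n_bins) given level-0 intervals.
.gap_runs <- function(s, e, n_bins) {
  if (length(s) == 0) {
    if (n_bins == 0) return(data.frame(start = integer(0), end = integer(0)))
    return(data.frame(start = 0L, end = as.integer(n_bins)))
  }
  ord <- order(s)
  s <- s[ord]; e <- e[ord]
  gs <- integer(0); ge <- integer(0)
  cursor <- 0L
  for (i in seq_along(s)) {
    if (s[i] > cursor) { gs <- c(gs, cursor); ge <- c(ge, s[i]) }
    cursor <- max(cursor, e[i])
  }
  if (cursor < n_bins) { gs <- c(gs, cursor); ge <- c(ge, as.integer(n_bins)) }
  data.frame(start = gs, end = ge)
}

#' Shift a domain partition circularly along the chromosome
#'
#' Utility for null comparisons: every domain is translated by `offset`
#' bins modulo `n_bins`; a domain straddling the wrap point is split in two,
#' and fragments shorter than 2 bins are dropped.
#'
#' @param d a `DomainSet`.
#' @param offset shift in bins.
#' @return A `DomainSet` with the shifted partition.
#' @export
shift_domains <- function(d, offset) {
  stopifnot(inherits(d, "DomainSet"))
  n <- d$n_bins
  s <- (d$domains$start_bin + offset) %% n
  e <- s + (d$domains$end_bin - d$domains$start_bin)
  ns <- integer(0); ne <- integer(0)
  for (i in seq_along(s)) {
    if (e[i] <= n) { ns <- c(ns, s[i]); ne <- c(ne, e[i]) }
    else {
      ns <- c(ns, s[i], 0L); ne <- c(ne, n, e[i] - n)
    }
  }
  keep <- (ne - ns) >= 2
  domain_set(ns[keep], ne[keep], d$resolution, n, chrom = d$chrom)
}
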