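#' Construct a binned contact matrix
#'
#' @param values symmetric nonnegative n-by-n numeric matrix of interaction
#'   counts/frequencies.
#' @param resolution bin width in bp.
#' @param chrom chromosome name.
#' @return An object of class `ContactMatrix`.
#' @export
contact_matrix <- function(values, resolution, chrom = "chr1") {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values) || nrow(values) < 2)
    stop("values must be a square matrix with n >= 2")
  if (any(values < 0)) stop("contact values must be nonnegative")
  if (!isTRUE(all.equal(values, t(values), tolerance = 1e-8,
                        check.attributes = FALSE)))
    stop("values must be symmetric (use read_contact_matrix to symmetrize)")
  dimnames(values) <- NULL
  structure(list(chrom = chrom, resolution = as.numeric(resolution),
                 values = values), class = "ContactMatrix")
}

#' @export
print.ContactMatrix <- function(x, ...) {
  cat(sprintf(
    "ContactMatrix: %d x %d bins on %s at %g bp/bin (total count %.4g)\n",
    nrow(x$values), ncol(x$values), x$chrom, x$resolution, sum(x$values)))
  invisible(x)
}

#' Number of bins of a contact matrix
#' @param m a `ContactMatrix`.
#' @return Integer matrix dimension.
#' @export
n_bins <- function(m) {
  stopifnot(inherits(m, "ContactMatrix"))
  nrow(m$values)
}

#' Read a contact matrix from dense or sparse 3-column text
#'
#' Dense format: whitespace-delimited n rows by n columns. Sparse format:
#' rows `i j value` with 0-based bin indices; entries are mirrored and
#' unlisted cells are 0. Asymmetric dense input is symmetrized as
#' `(M + t(M)) / 2` with a warning.
#'
#' @param path file path.
#' @param format `"dense"` or `"sparse3"`.
#' @param resolution bin width in bp.
#' @param n_bins required for `"sparse3"`; ignored for `"dense"`.
#' @param chrom chromosome name.
#' @param bp_coords if `TRUE`, sparse3 first two columns are bp coordinates
#'   and are divided by `resolution`.
#' @return A [contact_matrix()].
#' @export
read_contact_matrix <- function(path, format = c("dense", "sparse3"),
                                resolution, n_bins = NULL, chrom = "chr1",
                                bp_coords = FALSE) {
  format <- match.arg(format)
  if (format == "dense") {
    rows <- readLines(path)
    rows <- rows[nzchar(trimws(rows))]
    vals <- lapply(rows, function(r) as.numeric(strsplit(trimws(r),
                                                         "\\s+")[[1]]))
    lens <- lengths(vals)
    if (length(unique(lens)) != 1)
      stop("ragged dense matrix rows in ", path)
    M <- do.call(rbind, vals)
    if (nrow(M) != ncol(M)) stop("dense matrix in ", path, " is not square")
    if (!isTRUE(all.equal(M, t(M), tolerance = 1e-8,
                          check.attributes = FALSE))) {
      warning("asymmetric dense matrix; symmetrizing as (M + t(M))/2")
      M <- (M + t(M)) / 2
    }
  } else {
    if (is.null(n_bins)) stop("n_bins is required for sparse3 format")
    tab <- utils::read.table(path, header = FALSE)
    if (ncol(tab) < 3) stop("sparse3 format needs 3 columns in ", path)
    i <- as.numeric(tab[[1]]); j <- as.numeric(tab[[2]])
    v <- as.numeric(tab[[3]])
    if (bp_coords) { i <- floor(i / resolution); j <- floor(j / resolution) }
    if (any(i != round(i)) || any(j != round(j)))
      stop("non-integer bin indices in ", path)
    if (any(i < 0) || any(j < 0) || any(i >= n_bins) || any(j >= n_bins))
      stop("sparse index out of range [0, n_bins) in ", path)
    M <- matrix(0, n_bins, n_bins)
    for (k in seq_along(v)) {
      M[i[k] + 1, j[k] + 1] <- M[i[k] + 1, j[k] + 1] + v[k]
      if (i[k] != j[k]) M[j[k] + 1, i[k] + 1] <- M[j[k] + 1, i[k] + 1] + v[k]
    }
  }
  contact_matrix(M, resolution, chrom = chrom)
}

#' Write a contact matrix as dense or sparse 3-column text
#'
#' Sparse output lists the nonzero upper triangle (including the diagonal)
#' with 0-based bin indices.
#'
#' @param m a `ContactMatrix`.
#' @param path output file path.
#' @param format `"dense"` or `"sparse3"`.
#' @export
write_contact_matrix <- function(m, path, format = c("dense", "sparse3")) {
  format <- match.arg(format)
  stopifnot(inherits(m, "ContactMatrix"))
  if (format == "dense") {
    utils::write.table(m$values, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    idx <- which(upper.tri(m$values, diag = TRUE) & m$values != 0,
                 arr.ind = TRUE)
    tab <- data.frame(i = idx[, 1] - 1, j = idx[, 2] - 1,
                      v = m$values[idx])
    tab <- tab[order(tab$i, tab$j), ]
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Mean contact frequency at each genomic distance
#'
#' Element `d + 1` of the result is the mean of `values[i, i + d]` over all
#' valid `i`, for distances `d = 0 .. n - 1` — the distance-decay profile
#' used as the expected background for corner-dot scoring.
#'
#' @param m a `ContactMatrix`.
#' @return Numeric vector of length `n` of per-distance means.
#' @export
expected_by_distance <- function(m) {
  stopifnot(inherits(m, "ContactMatrix"))
  V <- m$values
  n <- nrow(V)
  vapply(0:(n - 1), function(d) {
    i <- seq_len(n - d)
    mean(V[cbind(i, i + d)])
  }, numeric(1))
}

#' Downsample a count matrix to a fraction of its sequencing depth
#'
#' Models reduced sequencing depth by binomial thinning: each upper-triangle
#' count `c` is replaced by a Binomial(`c`, `ratio`) draw and mirrored.
#' Non-integer entries are rounded first with a warning.
#'
#' @param m a `ContactMatrix` of counts.
#' @param ratio retention fraction in (0, 1].
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return A `ContactMatrix` of thinned counts.
#' @export
downsample <- function(m, ratio, seed = 1L) {
  stopifnot(inherits(m, "ContactMatrix"))
  if (!is.numeric(ratio) || length(ratio) != 1 || ratio <= 0 || ratio > 1)
    stop("ratio must lie in (0, 1]")
  V <- m$values
  if (any(V != round(V))) {
    warning("non-integer counts; rounding before thinning")
    V <- round(V)
  }
  if (ratio == 1) return(contact_matrix(V, m$resolution, m$chrom))
  n <- nrow(V)
  ut <- upper.tri(V, diag = TRUE)
  counts <- V[ut]
  thinned <- .with_seed(seed, stats::rbinom(length(counts),
                                            size = counts, prob = ratio))
  W <- matrix(0, n, n)
  W[ut] <- thinned
  W <- W + t(W) - diag(diag(W))
  contact_matrix(W, m$resolution, m$chrom)
}

#' Mean interaction frequency within a domain
#'
#' Mean over the upper triangle (including the diagonal) of the square
#' block spanned by the domain.
#'
#' @param m a `ContactMatrix`.
#' @param start_bin,end_bin domain bin range (0-based half-open).
#' @return Mean contact frequency (a real number).
#' @export
mean_domain_frequency <- function(m, start_bin, end_bin) {
  stopifnot(inherits(m, "ContactMatrix"))
  n <- nrow(m$values)
  if (start_bin < 0 || end_bin > n || end_bin - start_bin < 2)
    stop("domain out of matrix bounds or too small")
  idx <- (start_bin + 1):end_bin
  block <- m$values[idx, idx, drop = FALSE]
  mean(block[upper.tri(block, diag = TRUE)])
}

# Run expr with a temporary RNG state seeded by `seed`, restoring the
# caller's stream afterwards.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
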