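# Replicate concordance: pairwise boundary Jaccard similarity,
# reproducibility levels of identical TADs, and level-stratified summaries.

#' Pairwise Jaccard similarity of replicate boundary sets
#'
#' @param sets a list of two or more `BoundarySet`s at the same resolution.
#' @return A symmetric numeric matrix of exact-bin Jaccard indices with
#'   unit diagonal.
#' @export
replicate_jaccard <- function(sets) {
  if (length(sets) < 2) stop("need at least 2 replicate boundary sets")
  stopifnot(all(vapply(sets, inherits, logical(1), "BoundarySet")))
  res <- unique(vapply(sets, function(s) s$resolution, numeric(1)))
  if (length(res) > 1) stop("replicates have different resolutions")
  R <- length(sets)
  M <- diag(1, R)
  for (i in seq_len(R - 1)) for (j in (i + 1):R) {
    M[i, j] <- M[j, i] <-
      suppressMessages(jaccard_boundaries(sets[[i]], sets[[j]]))
  }
  nm <- names(sets)
  if (is.null(nm)) nm <- paste0("rep", seq_len(R))
  dimnames(M) <- list(nm, nm)
  M
}

#' Reproducibility level of every distinct TAD across replicates
#'
#' Two TADs are "the same" iff their start and end bins are identical
#' (absolute concordance). The reproducibility level of a distinct TAD is
#' the number of replicates containing it.
#'
#' @param sets a list of two or more replicate `DomainSet`s.
#' @param matrix optional `ContactMatrix`; when supplied, each distinct
#'   TAD's mean interaction frequency is computed on it.
#' @return A data.frame of class `ReproducibilityTable` with columns
#'   `start_bin`, `end_bin`, `level` (replicate count), `size_bp`,
#'   `mean_frequency` (`NA` without a matrix). Attributes: `R` (number of
#'   replicates), `membership` (distinct-TAD x replicate logical matrix),
#'   `chrom`, `resolution`.
#' @export
reproducibility_levels <- function(sets, matrix = NULL) {
  if (length(sets) < 2) stop("need at least 2 replicate domain sets")
  stopifnot(all(vapply(sets, inherits, logical(1), "DomainSet")))
  res <- unique(vapply(sets, function(s) s$resolution, numeric(1)))
  if (length(res) > 1) stop("replicates have different resolutions")
  R <- length(sets)
  keys <- lapply(sets, function(s)
    unique(paste(s$domains$start_bin, s$domains$end_bin)))
  all_keys <- unique(unlist(keys))
  member <- vapply(keys, function(k) all_keys %in% k,
                   logical(length(all_keys)))
  member <- matrix(member, nrow = length(all_keys), ncol = R)
  parts <- do.call(rbind, strsplit(all_keys, " "))
  sb <- as.integer(parts[, 1]); eb <- as.integer(parts[, 2])
  freq <- rep(NA_real_, length(all_keys))
  if (!is.null(matrix)) {
    stopifnot(inherits(matrix, "ContactMatrix"))
    freq <- vapply(seq_along(sb), function(i)
      mean_domain_frequency(matrix, sb[i], eb[i]), numeric(1))
  }
  tab <- data.frame(start_bin = sb, end_bin = eb,
                    level = rowSums(member),
                    size_bp = (eb - sb) * res,
                    mean_frequency = freq)
  ord <- order(tab$start_bin, tab$end_bin)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, R = R, membership = member[ord, , drop = FALSE],
            chrom = sets[[1]]$chrom, resolution = res,
            class = c("ReproducibilityTable", "data.frame"))
}

#' Stratify TADs by reproducibility level
#'
#' Aggregates distinct TADs per level (count, mean size, mean interaction
#' frequency), and contrasts high- versus low-reproducibility TADs
#' (high = level above half the replicate count) with a Wilcoxon
#' signed-rank test. The pairing unit is the replicate: for each replicate
#' the mean frequency of its high-level and of its low-level TADs forms
#' one pair. The exact test is used below 25 pairs, the normal
#' approximation above.
#'
#' @param t a `ReproducibilityTable` from [reproducibility_levels()].
#' @param alpha significance threshold for the reported flag (default
#'   0.05).
#' @return A list with `per_level` (data.frame: `level`, `tad_count`,
#'   `mean_size_bp`, `mean_frequency`), and `comparison` (list with
#'   per-replicate group means, the one-sided p-value for
#'   frequency(high) > frequency(low) and a `significant` flag), or
#'   `comparison = NULL` with a warning when a group is empty or
#'   frequencies are unavailable.
#' @export
stratify_levels <- function(t, alpha = 0.05) {
  stopifnot(inherits(t, "ReproducibilityTable"))
  if (nrow(t) == 0) stop("empty reproducibility table")
  R <- attr(t, "R")
  per_level <- do.call(rbind, lapply(sort(unique(t$level)), function(l) {
    sub <- t[t$level == l, , drop = FALSE]
    data.frame(level = l, tad_count = nrow(sub),
               mean_size_bp = mean(sub$size_bp),
               mean_frequency = mean(sub$mean_frequency))
  }))
  high <- t$level > R / 2
  member <- attr(t, "membership")
  comparison <- NULL
  if (!any(high) || all(high)) {
    warning("high or low reproducibility group is empty; comparison skipped")
  } else if (all(is.na(t$mean_frequency))) {
    warning("no interaction frequencies available; comparison skipped")
  } else {
    hi <- lo <- rep(NA_real_, R)
    for (r in seq_len(R)) {
      in_r <- member[, r]
      if (any(in_r & high)) hi[r] <- mean(t$mean_frequency[in_r & high])
      if (any(in_r & !high)) lo[r] <- mean(t$mean_frequency[in_r & !high])
    }
    ok <- !is.na(hi) & !is.na(lo)
    if (sum(ok) < 1) {
      warning("no replicate has TADs in both groups; comparison skipped")
    } else {
      # exact test below 25 pairs; ties fall back to the normal
      # approximation (suppressed wilcox.test warning)
      pv <- tryCatch(
        suppressWarnings(
          stats::wilcox.test(hi[ok], lo[ok], paired = TRUE,
                             alternative = "greater",
                             exact = sum(ok) < 25)$p.value),
        error = function(e) NA_real_)
      comparison <- list(high_means = hi, low_means = lo,
                         p_value = pv,
                         significant = !is.na(pv) && pv < alpha)
    }
  }
  list(per_level = per_level, comparison = comparison)
}
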