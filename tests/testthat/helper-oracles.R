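# Independent brute-force oracles used to cross-check every metric: plain
# double loops and literal set arithmetic, sharing no code with the package
# internals.

# events in [a, b) by direct comparison
o_count <- function(positions, a, b) sum(positions >= a & positions < b)

# per-boundary A/B/C by looping every 1 kb window explicitly
o_boundary_stats <- function(bins, resolution, n_bins_chrom, positions) {
  L <- if (is.na(n_bins_chrom)) Inf else n_bins_chrom * resolution
  A <- B <- C <- numeric(length(bins))
  for (i in seq_along(bins)) {
    b <- bins[i] * resolution
    lo <- max(b - 1000, 0); hi <- min(b + 1000, L)
    A[i] <- if (hi > lo) o_count(positions, lo, hi) / ((hi - lo) / 1000) else 0
    counts <- c()
    for (w0 in c(seq(b - 500000, b - 201000, by = 1000),
                 seq(b + 200000, b + 499000, by = 1000))) {
      if (w0 >= 0 && w0 + 1000 <= L)
        counts <- c(counts, o_count(positions, w0, w0 + 1000))
    }
    B[i] <- if (length(counts)) mean(counts) else 0
    C[i] <- if (length(counts) > 1) var(counts) else 0
  }
  list(A = A, B = B, C = C)
}

o_average_peak <- function(st) mean(st$A)

o_tagged_ratio <- function(bins, resolution, n_bins_chrom, positions) {
  L <- if (is.na(n_bins_chrom)) Inf else n_bins_chrom * resolution
  tagged <- 0
  for (bb in bins) {
    b <- bb * resolution
    if (o_count(positions, max(b - 1000, 0), min(b + 1000, L)) >= 1)
      tagged <- tagged + 1
  }
  tagged / length(bins)
}

o_fold_change <- function(st, pc = 1 / 600)
  mean(log2((st$A + pc) / (st$B + pc)))

o_pvalue_ratio <- function(st, alpha = 0.05, enrich = TRUE) {
  sig <- 0
  for (i in seq_along(st$A)) {
    if (st$C[i] == 0) {
      hit <- if (enrich) st$A[i] > st$B[i] else st$A[i] < st$B[i]
    } else {
      p <- if (enrich)
        1 - pnorm((st$A[i] - st$B[i]) / sqrt(st$C[i]))
      else pnorm((st$A[i] - st$B[i]) / sqrt(st$C[i]))
      hit <- p <= alpha
    }
    sig <- sig + hit
  }
  sig / length(st$A)
}

o_jaccard <- function(a, b) {
  u <- unique(c(a, b))
  if (length(u) == 0) return(0)
  sum(u %in% a & u %in% b) / length(u)
}

o_ji_elements <- function(bins, resolution, positions, window = 10000) {
  bp <- bins * resolution
  nb <- length(bp); ne <- length(positions)
  hit_b <- 0
  for (b in bp) if (any(abs(positions - b) <= window)) hit_b <- hit_b + 1
  hit_e <- 0
  for (x in positions) if (any(abs(bp - x) <= window)) hit_e <- hit_e + 1
  c(hit_b / (nb + ne), hit_e / (nb + ne))
}

# literal Eq.-1 computation: scan every cell at the distance, assign by
# explicit smallest-containing-domain / same-gap search
o_adj_r2 <- function(V, dom, n_bins_chrom, dist) {
  covered <- rep(FALSE, n_bins_chrom)
  for (r in seq_len(nrow(dom)))
    if (dom$level[r] == 0)
      covered[(dom$start_bin[r] + 1):dom$end_bin[r]] <- TRUE
  gap_id <- cumsum(c(TRUE, diff(!covered) != 0))  # run ids over bins
  Y <- c(); region <- c()
  for (i in 0:(n_bins_chrom - dist - 1)) {
    j <- i + dist
    cand <- which(dom$start_bin <= i & j <= dom$end_bin - 1)
    if (length(cand)) {
      sizes <- dom$end_bin[cand] - dom$start_bin[cand]
      r <- cand[which.min(sizes)]
      Y <- c(Y, V[i + 1, j + 1]); region <- c(region, paste0("d", r))
    } else if (!covered[i + 1] && !covered[j + 1] &&
               gap_id[i + 1] == gap_id[j + 1]) {
      Y <- c(Y, V[i + 1, j + 1])
      region <- c(region, paste0("g", gap_id[i + 1]))
    }
  }
  q <- length(Y)
  p <- sum(dom$end_bin - dom$start_bin >= dist)
  if (q == 0 || q - p - 1 <= 0) return(NA_real_)
  Ybar <- mean(Y)
  sst <- sum((Y - Ybar)^2)
  if (sst == 0) return(NA_real_)
  sse <- 0
  for (g in unique(region)) {
    yy <- Y[region == g]
    sse <- sse + sum((yy - mean(yy))^2)
  }
  1 - ((q - 1) * sse) / ((q - p - 1) * sst)
}

# random non-overlapping (level-0 only) domain tiling for small fixtures
r_domains <- function(n_bins_chrom, max_doms = 5) {
  s <- c(); e <- c(); pos <- 0
  while (pos + 2 <= n_bins_chrom && length(s) < max_doms) {
    pos <- pos + sample(0:2, 1)                  # maybe a gap
    size <- sample(2:6, 1)
    if (pos + size > n_bins_chrom) break
    s <- c(s, pos); e <- c(e, pos + size)
    pos <- pos + size
  }
  list(start = s, end = e)
}
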