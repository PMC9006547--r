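# Labeled synthetic contact matrices: power-law distance decay, planted
# (optionally nested) TADs with within-TAD enrichment, corner-dot loops,
# convex noise mixing, and matched synthetic peak tracks.

#' Simulation configuration
#'
#' Defaults emulate a 500 kb stretch of a 1 kb-resolution Micro-C map:
#' Poisson counts around a power-law decay `base_scale * (d + 1)^-alpha`,
#' TADs of 10-50 bins enriched by `tad_enrichment`, occasional inter-TAD
#' gaps, optional single nested subTADs, corner dots of strength
#' `dot_strength` on a fraction `dot_prob` of domains, and noise mixing
#' with a TAD-free background on the grid 0.05-0.2.
#'
#' @param n_bins chromosome length in bins (default 500).
#' @param resolution bin width in bp (default 1000).
#' @param decay_exponent power-law decay exponent alpha > 0 (default 1).
#' @param base_scale expected count at distance 0 (default 100).
#' @param tad_enrichment within-TAD multiplier beta > 1 (default 3).
#' @param tad_size_range integer (min, max) TAD size in bins (default
#'   c(10, 50)).
#' @param gap_prob probability of a gap between consecutive TADs (default
#'   0.2).
#' @param gap_size_range integer (min, max) gap size in bins (default
#'   c(2, 5)).
#' @param nested plant nested subTADs? (default FALSE).
#' @param nest_prob fraction of top TADs given one subTAD (default 0.5).
#' @param sub_enrichment extra multiplier inside a subTAD (default 1.5).
#' @param dot_prob fraction of domains given a corner dot (default 0.5).
#' @param dot_strength corner multiplier delta (default 4).
#' @param dot_halo corner neighbourhood half-width in bins (default 2).
#' @param noise_level mixing weight nu in \[0, 1\] of a TAD-free background
#'   (default 0).
#' @param seed integer seed.
#' @return A list of class `SimulationConfig`.
#' @export
simulation_config <- function(n_bins = 500, resolution = 1000,
                              decay_exponent = 1.0, base_scale = 100,
                              tad_enrichment = 3.0,
                              tad_size_range = c(10, 50),
                              gap_prob = 0.2, gap_size_range = c(2, 5),
                              nested = FALSE, nest_prob = 0.5,
                              sub_enrichment = 1.5,
                              dot_prob = 0.5, dot_strength = 4.0,
                              dot_halo = 2,
                              noise_level = 0, seed = 1L) {
  cfg <- list(n_bins = as.integer(n_bins), resolution = resolution,
              decay_exponent = decay_exponent, base_scale = base_scale,
              tad_enrichment = tad_enrichment,
              tad_size_range = as.integer(tad_size_range),
              gap_prob = gap_prob,
              gap_size_range = as.integer(gap_size_range),
              nested = isTRUE(nested), nest_prob = nest_prob,
              sub_enrichment = sub_enrichment,
              dot_prob = dot_prob, dot_strength = dot_strength,
              dot_halo = as.integer(dot_halo),
              noise_level = noise_level, seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_bins >= 4, resolution > 0, decay_exponent > 0,
              base_scale > 0, tad_enrichment > 0,
              length(tad_size_range) == 2, tad_size_range[1] >= 2,
              tad_size_range[1] <= tad_size_range[2],
              gap_prob >= 0, gap_prob <= 1,
              length(gap_size_range) == 2, gap_size_range[1] >= 1,
              nest_prob >= 0, nest_prob <= 1, sub_enrichment > 0,
              dot_prob >= 0, dot_prob <= 1, dot_strength > 0,
              noise_level >= 0, noise_level <= 1)
    if (tad_size_range[2] > n_bins)
      stop("tad_size_range exceeds n_bins")
  })
  structure(cfg, class = "SimulationConfig")
}

# sample one element of x (safe for length-1 x, unlike sample())
.sample1 <- function(x) x[sample.int(length(x), 1)]

# Tile [0, n_bins) with TADs and gaps; returns data.frame(start, end, level)
.tile_domains <- function(cfg) {
  s <- integer(0); e <- integer(0); lev <- integer(0)
  pos <- 0L
  repeat {
    if (pos + cfg$tad_size_range[1] > cfg$n_bins) break
    size <- .sample1(cfg$tad_size_range[1]:cfg$tad_size_range[2])
    size <- min(size, cfg$n_bins - pos)
    s <- c(s, pos); e <- c(e, pos + size); lev <- c(lev, 0L)
    pos <- pos + size
    if (stats::runif(1) < cfg$gap_prob) {
      gap <- .sample1(cfg$gap_size_range[1]:cfg$gap_size_range[2])
      pos <- pos + gap
    }
  }
  top_idx <- seq_along(s)
  if (cfg$nested) {
    for (i in top_idx) {
      size <- e[i] - s[i]
      if (size >= 4 && stats::runif(1) < cfg$nest_prob) {
        sub_max <- size - 2
        sub_size <- .sample1(2:sub_max)
        sub_start <- s[i] + .sample1(1:(size - sub_size - 1))
        s <- c(s, sub_start); e <- c(e, sub_start + sub_size)
        lev <- c(lev, 1L)
      }
    }
  }
  data.frame(start = s, end = e, level = lev)
}

#' Simulate a labeled contact matrix with planted TADs
#'
#' Generation steps, deterministic given `cfg$seed`:
#' 1. tile the chromosome with TADs drawn from `tad_size_range`, inserting
#'    gaps with probability `gap_prob`; optionally plant one strictly
#'    interior subTAD per selected top TAD;
#' 2. set the Poisson intensity
#'    `lambda(i, j) = base_scale * (|i - j| + 1)^-decay_exponent`,
#'    multiplied by `tad_enrichment` when a top TAD contains both bins
#'    (times `sub_enrichment` inside a subTAD) and by `dot_strength` over
#'    the corner neighbourhood of dot-labeled domains;
#' 3. draw Poisson counts on the upper triangle and mirror;
#' 4. mix with a TAD-free background: `round((1 - nu) * M + nu * P)` where
#'    `P` is an independent Poisson matrix from the bare decay.
#'
#' @param cfg a [simulation_config()].
#' @return A list with `matrix` (a `ContactMatrix`) and `truth` (a
#'   `DomainSet` whose `corner_dot` column labels planted loops).
#' @export
simulate_matrix <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  .with_seed(cfg$seed, {
    doms <- .tile_domains(cfg)
    k <- nrow(doms)
    dots <- if (k) stats::runif(k) < cfg$dot_prob else logical(0)
    n <- cfg$n_bins
    D <- abs(outer(0:(n - 1), 0:(n - 1), "-"))
    lambda0 <- cfg$base_scale * (D + 1)^(-cfg$decay_exponent)
    lambda <- lambda0
    if (k) for (i in seq_len(k)) {
      idx <- (doms$start[i] + 1):doms$end[i]
      mult <- if (doms$level[i] == 0) cfg$tad_enrichment
              else cfg$sub_enrichment
      lambda[idx, idx] <- lambda[idx, idx] * mult
    }
    if (k) for (i in seq_len(k)) {
      if (!dots[i]) next
      h <- cfg$dot_halo
      rows <- max(0, doms$start[i] - h):min(n - 1, doms$start[i] + h)
      cols <- max(0, doms$end[i] - 1 - h):min(n - 1, doms$end[i] - 1 + h)
      lambda[rows + 1, cols + 1] <- lambda[rows + 1, cols + 1] *
        cfg$dot_strength
      lambda[cols + 1, rows + 1] <- t(lambda[rows + 1, cols + 1])
    }
    M <- .sym_rpois(lambda)
    if (cfg$noise_level > 0) {
      P <- .sym_rpois(lambda0)
      M <- round((1 - cfg$noise_level) * M + cfg$noise_level * P)
    }
    truth <- domain_set(doms$start, doms$end, cfg$resolution, n,
                        corner_dot = dots)
    list(matrix = contact_matrix(M, cfg$resolution), truth = truth)
  })
}

# Poisson draw on the upper triangle, mirrored to a symmetric matrix.
.sym_rpois <- function(lambda) {
  n <- nrow(lambda)
  ut <- upper.tri(lambda, diag = TRUE)
  M <- matrix(0, n, n)
  M[ut] <- stats::rpois(sum(ut), lambda[ut])
  M + t(M) - diag(diag(M))
}

#' Simulate a peak track enriched or depleted at true boundaries
#'
#' Events are a homogeneous Poisson process at `background_rate` per kb
#' over the chromosome. In `"enrichment"` mode, additional events at rate
#' `max(0, boundary_rate - background_rate)` per kb are added within
#' `±near_window` bp of every boundary, so the near-boundary total rate is
#' `boundary_rate`. In `"depletion"` mode, background events within
#' `±near_window` of a boundary are retained with probability
#' `boundary_rate / background_rate`.
#'
#' @param truth a `BoundarySet` with known `n_bins` (defines the
#'   chromosome length).
#' @param mode `"enrichment"` or `"depletion"`.
#' @param boundary_rate events per kb near boundaries.
#' @param background_rate events per kb elsewhere.
#' @param near_window half-width in bp of the near-boundary zone (default
#'   1000).
#' @param seed integer seed.
#' @return A [peak_track()].
#' @export
simulate_peak_track <- function(truth, mode = c("enrichment", "depletion"),
                                boundary_rate, background_rate,
                                near_window = 1000, seed = 1L) {
  stopifnot(inherits(truth, "BoundarySet"))
  mode <- match.arg(mode)
  if (is.na(truth$n_bins))
    stop("truth boundary set must carry n_bins to define chromosome length")
  if (boundary_rate < 0 || background_rate < 0) stop("rates must be >= 0")
  L <- truth$n_bins * truth$resolution
  bpos <- truth$bins * truth$resolution
  .with_seed(seed, {
    n_bg <- stats::rpois(1, background_rate * L / 1000)
    ev <- stats::runif(n_bg, 0, L)
    if (mode == "enrichment") {
      extra_rate <- max(0, boundary_rate - background_rate)
      if (extra_rate > 0 && length(bpos)) {
        for (b in bpos) {
          a <- max(0, b - near_window); z <- min(L, b + near_window)
          n_ex <- stats::rpois(1, extra_rate * (z - a) / 1000)
          ev <- c(ev, stats::runif(n_ex, a, z))
        }
      }
    } else {
      if (background_rate > 0 && length(bpos)) {
        near <- vapply(ev, function(x) any(abs(bpos - x) <= near_window),
                       logical(1))
        keep_p <- min(1, boundary_rate / background_rate)
        drop <- near & stats::runif(length(ev)) >= keep_p
        ev <- ev[!drop]
      }
    }
    peak_track(floor(ev), chrom = truth$chrom)
  })
}
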