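test_that("simulation is deterministic given the seed and respects labels", {
  cfg <- simulation_config(seed = 4, nested = TRUE, noise_level = 0.1)
  s1 <- simulate_matrix(cfg)
  s2 <- simulate_matrix(cfg)
  expect_identical(s1$matrix$values, s2$matrix$values)
  expect_identical(s1$truth$domains, s2$truth$domains)
  s3 <- simulate_matrix(simulation_config(seed = 5, nested = TRUE))
  expect_false(identical(s1$matrix$values, s3$matrix$values))

  expect_true(all(s1$matrix$values == round(s1$matrix$values)))
  expect_true(isSymmetric(s1$matrix$values))
  expect_true(all(!is.na(s1$truth$domains$corner_dot)))
  # nested subTADs sit strictly inside their parents
  sub <- s1$truth$domains[s1$truth$domains$level == 1, ]
  top <- s1$truth$domains[s1$truth$domains$level == 0, ]
  for (r in seq_len(nrow(sub))) {
    parent <- top[top$start_bin < sub$start_bin[r] &
                    top$end_bin > sub$end_bin[r], ]
    expect_gte(nrow(parent), 1)
  }
  expect_error(simulation_config(tad_size_range = c(10, 900)),
               "exceeds n_bins")
})

test_that("a beta=1 simulation follows the bare power-law decay", {
  cfg <- simulation_config(seed = 6, tad_enrichment = 1, dot_strength = 1)
  sim <- simulate_matrix(cfg)
  e <- expected_by_distance(sim$matrix)
  for (d in c(0, 1, 2, 5, 10, 20)) {
    lam <- cfg$base_scale * (d + 1)^(-cfg$decay_exponent)
    n_at_d <- cfg$n_bins - d
    se <- sqrt(lam / n_at_d)
    expect_lt(abs(e[d + 1] - lam), 4 * se)
  }
  # and explains essentially nothing of the partition
  pr <- tad_adj_r2_profile(sim$matrix, sim$truth, 2, 50)
  expect_lt(abs(pr$mean), 0.1)
})

test_that("heavy background mixing erodes the explainable TAD signal", {
  r2 <- sapply(c(0, 0.8), function(nu) {
    mean(sapply(0:2, function(s) {
      sim <- simulate_matrix(simulation_config(seed = s, noise_level = nu))
      tad_adj_r2_profile(sim$matrix, sim$truth, 2, 50)$mean
    }))
  })
  expect_gt(r2[1], r2[2] + 0.05)
})

test_that("synthetic peak tracks hit their target rates near boundaries", {
  sim <- simulate_matrix(simulation_config(seed = 30))
  tb <- domains_to_boundaries(sim$truth)
  # enrichment: near-boundary total rate ~ boundary_rate
  pk <- simulate_peak_track(tb, "enrichment", boundary_rate = 5,
                            background_rate = 0.5, seed = 7)
  st <- compute_boundary_stats(tb, pk)
  expect_gt(mean(st$A), 3)         # ~5/kb near boundaries
  expect_lt(mean(st$B), 1.5)       # ~0.5/kb background
  expect_identical(
    simulate_peak_track(tb, "enrichment", 5, 0.5, seed = 7)$positions,
    pk$positions)

  # depletion with near rate 0 removes all near-boundary events
  pk0 <- simulate_peak_track(tb, "depletion", boundary_rate = 0,
                             background_rate = 2, seed = 8)
  expect_equal(boundary_tagged_ratio(tb, pk0), 0)

  # matched rates give a flat track
  pk1 <- simulate_peak_track(tb, "enrichment", boundary_rate = 2,
                             background_rate = 2, seed = 9)
  st1 <- compute_boundary_stats(tb, pk1)
  expect_lt(abs(mean(st1$A) - mean(st1$B)), 0.75)
})
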