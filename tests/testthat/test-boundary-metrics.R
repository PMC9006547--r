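test_that("near-boundary density counts events in the centred 2 kb window", {
  b <- boundary_set(10, resolution = 1000, n_bins = 1000)
  p <- peak_track(c(9500, 10200, 10900))
  st <- compute_boundary_stats(b, p)
  expect_equal(st$A, 1.5)          # 3 events in [9000, 11000) over 2 kb
  expect_equal(average_peak(st), 1.5)

  # no events anywhere
  st0 <- compute_boundary_stats(b, peak_track(numeric(0)))
  expect_equal(c(st0$A, st0$B, st0$C), c(0, 0, 0))

  # exactly one event per kb everywhere: A = B = 1, C = 0
  bu <- boundary_set(600, resolution = 1000, n_bins = 1200)
  pu <- peak_track(seq(500, 1200 * 1000 - 500, by = 1000))
  stu <- compute_boundary_stats(bu, pu)
  expect_equal(stu$A, 1)
  expect_equal(stu$B, 1)
  expect_equal(stu$C, 0)
  expect_equal(fold_change(stu, pseudocount = 0), 0)
})

test_that("tagged ratio and p-value ratio behave at their extremes", {
  b <- boundary_set(c(10, 50, 100, 200), resolution = 1000, n_bins = 1000)
  expect_equal(boundary_tagged_ratio(b, peak_track(numeric(0))), 0)
  expect_equal(boundary_tagged_ratio(
    b, peak_track(c(10100, 50100, 100100, 200100))), 1)
  expect_equal(boundary_tagged_ratio(b, peak_track(10100)), 0.25)

  # A at the background mean is never significant; 10 sigma always is
  st <- structure(list(A = c(1, 1), B = c(1, 1), C = c(0.5, 0.5), n = 2),
                  class = "BoundaryElementStats")
  expect_equal(pvalue_ratio(st), 0)
  st2 <- structure(list(A = 1 + 10 * sqrt(0.5) * c(1, 1), B = c(1, 1),
                        C = c(0.5, 0.5), n = 2),
                   class = "BoundaryElementStats")
  expect_equal(pvalue_ratio(st2), 1)
  # depletion direction flips the tail
  st3 <- structure(list(A = c(0), B = c(1), C = c(0.01), n = 1),
                   class = "BoundaryElementStats")
  expect_equal(pvalue_ratio(st3, direction = "depletion"), 1)
  expect_equal(pvalue_ratio(st3, direction = "enrichment"), 0)
})

test_that("fold change matches its closed form on single boundaries", {
  st <- structure(list(A = 2, B = 0.5, C = 0, n = 1),
                  class = "BoundaryElementStats")
  expect_equal(fold_change(st, pseudocount = 1e-12), 2, tolerance = 1e-6)
  st2 <- structure(list(A = 0.25, B = 1, C = 0, n = 1),
                   class = "BoundaryElementStats")
  expect_equal(fold_change(st2, pseudocount = 1e-12), -2, tolerance = 1e-6)
})

test_that("boundary Jaccard is exact-bin intersection over union", {
  a <- boundary_set(c(2, 10, 20), 1000)
  b <- boundary_set(c(10, 20, 30), 1000)
  expect_equal(jaccard_boundaries(a, b), 0.5)
  expect_equal(jaccard_boundaries(a, a), 1)
  expect_equal(jaccard_boundaries(a, boundary_set(c(1, 3), 1000)), 0)
  expect_error(jaccard_boundaries(a, boundary_set(10, 5000)),
               "resolution")
  expect_message(
    expect_equal(jaccard_boundaries(boundary_set(integer(0), 1000),
                                    boundary_set(integer(0), 1000)), 0),
    "empty")
})

test_that("element Jaccard variants use the size-sum denominator", {
  b <- boundary_set(100, resolution = 1000)   # boundary at 100 kb
  p <- peak_track(105000)                     # 5 kb away
  ji <- jaccard_boundary_elements(b, p, window = 10000)
  expect_equal(ji$ji_boundaries, 0.5)
  expect_equal(ji$ji_elements, 0.5)

  # all elements out of range
  ji0 <- jaccard_boundary_elements(b, peak_track(c(200000, 300000)))
  expect_equal(ji0$ji_boundaries, 0)
  expect_equal(ji0$ji_elements, 0)

  # 2 boundaries, 4 elements all near the first
  b2 <- boundary_set(c(100, 500), resolution = 1000)
  p2 <- peak_track(c(99000, 100500, 101000, 105000))
  ji2 <- jaccard_boundary_elements(b2, p2, window = 10000)
  expect_equal(ji2$ji_boundaries, 1 / 6)
  expect_equal(ji2$ji_elements, 4 / 6)
})

test_that("enrichment profile is flat on homogeneous tracks and spikes on planted ones", {
  b <- boundary_set(c(600, 700), resolution = 1000, n_bins = 1300)
  # 2 events per kb, everywhere
  p <- peak_track(sort(c(seq(250, 1300000, by = 1000),
                         seq(750, 1300000, by = 1000))))
  pr <- enrichment_profile(b, p, span = 50000, step = 1000)
  expect_equal(nrow(pr), 100)
  expect_true(all(abs(pr$density - 2) < 1e-9))

  # all events exactly at the boundary positions
  p2 <- peak_track(c(600000, 700000))
  pr2 <- enrichment_profile(b, p2, span = 10000, step = 1000)
  expect_equal(pr2$density[pr2$offset_bp == 0], 1)
  expect_true(all(pr2$density[pr2$offset_bp != 0] == 0))
  expect_error(enrichment_profile(b, p2, span = 10000, step = 3000),
               "divide")

  # consistency: average peak equals the mean of the two central kb bins
  set.seed(11)
  p3 <- peak_track(sort(runif(400, 0, 1300000)))
  pr3 <- enrichment_profile(b, p3, span = 500000, step = 1000)
  central <- pr3$density[pr3$offset_bp %in% c(-1000, 0)]
  st <- compute_boundary_stats(b, p3)
  expect_equal(average_peak(st), mean(central), tolerance = 1e-9)
})

test_that("boundary-element metrics agree with brute-force oracles on random instances", {
  set.seed(202)
  for (rep in 1:60) {
    res <- sample(c(1000, 5000), 1)
    nb_chrom <- sample(20:50, 1)
    bins <- sort(sample(0:(nb_chrom - 1), sample(2:6, 1)))
    L <- nb_chrom * res
    positions <- sort(floor(runif(sample(5:200, 1), 0, L)))
    b <- boundary_set(bins, res, n_bins = nb_chrom)
    p <- peak_track(positions)

    st <- compute_boundary_stats(b, p)
    o <- o_boundary_stats(bins, res, nb_chrom, positions)
    expect_equal(st$A, o$A, tolerance = 1e-9)
    expect_equal(st$B, o$B, tolerance = 1e-9)
    expect_equal(st$C, o$C, tolerance = 1e-9)
    expect_equal(average_peak(st), o_average_peak(o), tolerance = 1e-9)
    expect_equal(fold_change(st), o_fold_change(o), tolerance = 1e-9)
    expect_equal(pvalue_ratio(st), o_pvalue_ratio(o), tolerance = 1e-9)
    expect_equal(boundary_tagged_ratio(b, p),
                 o_tagged_ratio(bins, res, nb_chrom, positions),
                 tolerance = 1e-9)
    ji <- jaccard_boundary_elements(b, p)
    oji <- o_ji_elements(bins, res, positions)
    expect_equal(ji$ji_boundaries, oji[1], tolerance = 1e-9)
    expect_equal(ji$ji_elements, oji[2], tolerance = 1e-9)

    bins2 <- sort(sample(0:(nb_chrom - 1), sample(2:6, 1)))
    expect_equal(jaccard_boundaries(b, boundary_set(bins2, res)),
                 o_jaccard(bins, bins2), tolerance = 1e-12)
    # bounds
    expect_true(boundary_tagged_ratio(b, p) >= 0 &&
                  boundary_tagged_ratio(b, p) <= 1)
    expect_true(pvalue_ratio(st) >= 0 && pvalue_ratio(st) <= 1)
  }
})
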