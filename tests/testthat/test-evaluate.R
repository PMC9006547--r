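test_that("the batch report carries the expected record set", {
  sim <- simulate_matrix(simulation_config(seed = 50, n_bins = 200))
  tb <- domains_to_boundaries(sim$truth)
  trk <- simulate_peak_track(tb, "enrichment", 5, 0.5, seed = 1)
  rep1 <- evaluate_all(
    list(truthcopy = sim$truth),
    matrix = sim$matrix,
    tracks = list(CTCF = trk),
    truth = sim$truth,
    params = list(tolerance = 1, d_max = 50))

  expect_s3_class(rep1, "MetricReport")
  expect_equal(sum(rep1$element == "CTCF"), 6)
  expect_equal(sum(rep1$element == "summary"), 4)
  expect_equal(sum(rep1$metric %in% c("adj_r2_mean", "adj_r2_max",
                                      "adj_r2_min")), 3)
  expect_true(all(c("tpr", "fpr") %in% rep1$metric))
  # self-evaluation against own truth is perfect
  expect_equal(rep1$value[rep1$metric == "tpr"], 1)
  expect_equal(rep1$value[rep1$metric == "fpr"], 0)
  # (caller, element, metric) unique
  expect_false(any(duplicated(
    rep1[, c("caller", "element", "metric")])))

  # no truth -> no accuracy records
  rep2 <- evaluate_all(list(a = sim$truth), matrix = sim$matrix,
                       params = list(d_max = 50))
  expect_false(any(rep2$element == "truth"))

  # identical callers give identical rows; reruns are byte-identical
  rep3 <- evaluate_all(list(x = sim$truth, y = sim$truth),
                       tracks = list(CTCF = trk))
  vx <- rep3[rep3$caller == "x", c("element", "metric", "value")]
  vy <- rep3[rep3$caller == "y", c("element", "metric", "value")]
  rownames(vx) <- rownames(vy) <- NULL
  expect_equal(vx, vy)
  rep1b <- evaluate_all(
    list(truthcopy = sim$truth), matrix = sim$matrix,
    tracks = list(CTCF = trk), truth = sim$truth,
    params = list(tolerance = 1, d_max = 50))
  expect_identical(rep1, rep1b)

  # resolution mismatch aborts
  bad <- domain_set(0, 10, resolution = 5000, n_bins = 200)
  expect_error(evaluate_all(list(a = sim$truth, b = bad)),
               "resolution mismatch")
})

test_that("report values are reproducible by direct metric calls", {
  sim <- simulate_matrix(simulation_config(seed = 51, n_bins = 200))
  tb <- domains_to_boundaries(sim$truth)
  trk <- simulate_peak_track(tb, "enrichment", 5, 0.5, seed = 2)
  rep1 <- evaluate_all(list(c1 = sim$truth), tracks = list(CTCF = trk))
  st <- compute_boundary_stats(tb, trk)
  expect_equal(
    rep1$value[rep1$metric == "average_peak"], average_peak(st))
  expect_equal(
    rep1$value[rep1$metric == "fold_change"], fold_change(st))
  expect_equal(
    rep1$value[rep1$metric == "boundary_tagged_ratio"],
    boundary_tagged_ratio(tb, trk))
})

test_that("report pivots into a rankable caller-by-metric table", {
  sim1 <- simulate_matrix(simulation_config(seed = 52, n_bins = 200))
  sim2 <- simulate_matrix(simulation_config(seed = 53, n_bins = 200))
  d2 <- sim2$truth
  tb <- domains_to_boundaries(sim1$truth)
  trk <- simulate_peak_track(tb, "enrichment", 5, 0.5, seed = 3)
  rep1 <- evaluate_all(list(a = sim1$truth, b = d2),
                       tracks = list(CTCF = trk, H3K9me3 = trk))
  M <- metric_table(rep1, metrics = "average_peak")
  expect_equal(dim(M), c(2, 2))
  expect_equal(sort(colnames(M)),
               c("CTCF.average_peak", "H3K9me3.average_peak"))
  ag <- aggregate_rank(M, exclude = "H3K9me3.average_peak")
  expect_equal(ag$n_ranked, c(1, 1))

  f <- withr::local_tempfile()
  write_metric_report(rep1, f)
  back <- utils::read.delim(f)
  expect_equal(nrow(back), nrow(rep1))
})
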