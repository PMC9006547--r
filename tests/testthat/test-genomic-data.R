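test_that("domain files round-trip through bin coordinates", {
  f <- withr::local_tempfile()
  writeLines(c("chr1\t10000\t50000", "chr1\t50000\t100000"), f)
  d <- read_domains(f, resolution = 5000, n_bins = 30)
  expect_equal(d$domains$start_bin, c(2L, 10L))
  expect_equal(d$domains$end_bin, c(10L, 20L))
  f2 <- withr::local_tempfile()
  write_domains(d, f2)
  d2 <- read_domains(f2, resolution = 5000, n_bins = 30)
  expect_equal(d2$domains, d$domains)
})

test_that("nesting levels come from containment and partial overlap is rejected", {
  f <- withr::local_tempfile()
  writeLines(c("chr1\t0\t100000", "chr1\t20000\t60000"), f)
  d <- read_domains(f, resolution = 5000, n_bins = 20)
  expect_equal(d$domains$level, c(0L, 1L))

  expect_error(
    domain_set(c(0, 6), c(10, 16), resolution = 5000, n_bins = 20),
    "partially overlap")
  expect_error(
    domain_set(0, 1, resolution = 5000, n_bins = 20), "at least 2 bins")
  expect_error(
    domain_set(c(0, 0), c(10, 10), resolution = 5000, n_bins = 20),
    "duplicate")
})

test_that("boundary extraction deduplicates shared and nested boundaries", {
  d <- domain_set(c(2, 10), c(10, 20), resolution = 1000, n_bins = 25)
  expect_equal(domains_to_boundaries(d)$bins, c(2L, 10L, 20L))

  d2 <- domain_set(c(0, 4), c(20, 12), resolution = 1000, n_bins = 25)
  expect_equal(domains_to_boundaries(d2)$bins, c(0L, 4L, 12L, 20L))
  # level filter drops subTAD boundaries
  expect_equal(domains_to_boundaries(d2, levels = 0)$bins, c(0L, 20L))

  empty <- domain_set(integer(0), integer(0), resolution = 1000, n_bins = 25)
  expect_length(domains_to_boundaries(empty)$bins, 0)
  expect_lte(length(domains_to_boundaries(d)$bins), 2 * nrow(d$domains))
})

test_that("peak reading takes interval midpoints and sorts", {
  f <- withr::local_tempfile()
  writeLines(c("chr1\t100\t300\textra", "chr1\t50\t150"), f)
  p <- read_peaks(f)
  expect_equal(p$positions, c(100, 200))

  f2 <- withr::local_tempfile()
  writeLines(character(0), f2)
  expect_length(read_peaks(f2)$positions, 0)

  f3 <- withr::local_tempfile()
  writeLines("chr1\t300\t100", f3)
  expect_error(read_peaks(f3), "start > end")
})

test_that("domain summary accounts for every bin when TADs tile", {
  d <- domain_set(c(0, 10), c(10, 20), resolution = 5000, n_bins = 20)
  s <- domain_summary(d)
  expect_equal(s$tad_count, 2)
  expect_equal(s$mean_tad_size_bp, 50000)
  expect_equal(s$gap_count, 0)

  d2 <- domain_set(2, 6, resolution = 1000, n_bins = 10)
  s2 <- domain_summary(d2)
  expect_equal(s2$gap_count, 2)
  expect_equal(s2$mean_gap_size_bp, 3 * 1000)

  empty <- domain_set(integer(0), integer(0), resolution = 1000, n_bins = 10)
  s3 <- domain_summary(empty)
  expect_equal(s3$tad_count, 0)
  expect_equal(s3$gap_count, 1)
  expect_equal(s3$mean_gap_size_bp, 10000)

  # conservation: TAD bp + gap bp = chromosome bp for tiling partitions
  set.seed(7)
  for (rep in 1:20) {
    rd <- r_domains(30)
    if (!length(rd$start)) next
    dd <- domain_set(rd$start, rd$end, resolution = 1000, n_bins = 30)
    ss <- domain_summary(dd)
    total <- ss$tad_count * ss$mean_tad_size_bp +
      ifelse(ss$gap_count, ss$gap_count * ss$mean_gap_size_bp, 0)
    expect_equal(total, 30 * 1000)
  }
})

test_that("circular shifting preserves total domain extent away from the wrap", {
  d <- domain_set(c(0, 10, 25), c(10, 20, 40), resolution = 1000, n_bins = 50)
  sh <- shift_domains(d, 5)
  expect_equal(sh$domains$start_bin, c(5L, 15L, 30L))
  # wrap splits the last domain
  sh2 <- shift_domains(d, 15)
  expect_true(all(sh2$domains$end_bin <= 50))
  expect_equal(sum(sh2$domains$end_bin - sh2$domains$start_bin),
               sum(d$domains$end_bin - d$domains$start_bin))
})
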