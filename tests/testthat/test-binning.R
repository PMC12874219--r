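test_that("pool_candidates merges within the adaptive radius and preserves isolated peaks", {
  peaks <- peak_tbl(c(200.0000, 200.0001, 300.0))
  cand <- pool_candidates(peaks, curve = qe_curve)
  expect_identical(nrow(cand), 2L)
  expect_equal(cand$mz[1], 200.00005, tolerance = 1e-9)
  expect_equal(cand$mz[2], 300.0)

  # single peak: identity
  one <- pool_candidates(peak_tbl(123.4567), curve = qe_curve)
  expect_equal(one$mz, 123.4567)

  # equal-intensity pair symmetric about 250: candidate exactly 250
  sym <- pool_candidates(peak_tbl(c(250 - 2e-4, 250 + 2e-4)), curve = qe_curve)
  expect_identical(nrow(sym), 1L)
  expect_equal(sym$mz, 250)

  expect_identical(nrow(pool_candidates(peak_tbl(numeric()), curve = qe_curve)), 0L)
})

test_that("pool_candidates support filter drops sporadic peaks", {
  # a feature present in all 10 scans and one singleton noise peak
  feat <- peak_tbl(rep(200, 10), intensity = rep(100, 10),
                   obs = sprintf("s%02d", 1:10))
  noise <- peak_tbl(350.123, intensity = 500, obs = "s01")
  cand <- pool_candidates(dplyr::bind_rows(feat, noise), curve = qe_curve,
                          min_scan_frac = 0.5)
  expect_equal(cand$mz, 200)
  # with the filter disabled the noise candidate survives
  cand0 <- pool_candidates(dplyr::bind_rows(feat, noise), curve = qe_curve,
                           min_scan_frac = 0)
  expect_identical(nrow(cand0), 2L)
})

test_that("adaptive buckets follow the three-stage protocol", {
  b <- build_adaptive_buckets(200.0, qe_curve)
  w <- 200 / 70000
  expect_equal(b$lower, 200 - w / 2, tolerance = 1e-12)
  expect_equal(b$upper, 200 + w / 2, tolerance = 1e-12)
  expect_equal(b$apex, 200)
  expect_identical(b$n_members, 1L)

  # two candidates half a width apart fuse into one bucket
  fused <- build_adaptive_buckets(c(200, 200 + 0.5 * w), qe_curve)
  expect_identical(nrow(fused), 1L)
  expect_identical(fused$n_members, 2L)

  # ten widths apart: disjoint
  apart <- build_adaptive_buckets(c(200, 200 + 10 * w), qe_curve)
  expect_identical(nrow(apart), 2L)

  # half-width reading of the bin size doubles the bucket
  bh <- build_adaptive_buckets(200.0, qe_curve, as_halfwidth = TRUE)
  expect_equal(bh$upper - bh$lower, 2 * w, tolerance = 1e-9)

  expect_error(build_adaptive_buckets(c(300, 200), qe_curve),
               class = "mzadapt_error_validation")
})

test_that("ppm buckets have the stated boundaries and reject bad tolerances", {
  b <- build_ppm_buckets(500.0, 5)
  expect_equal(b$lower, 499.9975, tolerance = 1e-12)
  expect_equal(b$upper, 500.0025, tolerance = 1e-12)
  b10 <- build_ppm_buckets(100.0, 10)
  expect_equal(b10$lower, 99.999, tolerance = 1e-12)
  expect_equal(b10$upper, 100.001, tolerance = 1e-12)
  expect_error(build_ppm_buckets(500, 0), class = "mzadapt_error_validation")
  expect_error(build_ppm_buckets(500, -5), class = "mzadapt_error_validation")
})

test_that("constant grids are zero-anchored with half-open bins", {
  g <- build_constant_grid(0.1, 100.0, 100.3)
  expect_identical(nrow(g), 4L)
  expect_equal(g$lower, c(100.0, 100.1, 100.2, 100.3))
  expect_equal(g$upper, c(100.1, 100.2, 100.3, 100.4))

  # a peak exactly on a boundary belongs to the upper bin
  v <- bin_spectrum(peak_tbl(100.1, 7), g)
  expect_equal(v, c(0, 7, 0, 0))

  expect_error(build_constant_grid(0, 100, 200), class = "mzadapt_error_validation")
  expect_error(build_constant_grid(0.1, 200, 100), class = "mzadapt_error_validation")
})

test_that("fuse_overlapping merges transitively, weights apexes, and is idempotent", {
  b <- tibble::tibble(lower = c(1.0, 1.5), upper = c(2.0, 2.5),
                      apex = c(1.5, 2.0), n_members = c(1L, 1L))
  f <- fuse_overlapping(b)
  expect_equal(f$lower, 1.0)
  expect_equal(f$upper, 2.5)
  expect_equal(f$apex, 1.75)
  expect_identical(f$n_members, 2L)

  disjoint <- tibble::tibble(lower = c(1, 3), upper = c(2, 4),
                             apex = c(1.5, 3.5), n_members = c(1L, 1L))
  expect_equal(as.data.frame(fuse_overlapping(disjoint)), as.data.frame(disjoint))

  chain <- tibble::tibble(lower = c(1, 1.9, 2.9), upper = c(2, 3, 4),
                          apex = c(1.5, 2.5, 3.5), n_members = c(1L, 1L, 1L))
  expect_identical(nrow(fuse_overlapping(chain)), 1L)
  expect_equal(fuse_overlapping(chain)$upper, 4)

  # touching at a boundary is NOT an overlap under the half-open convention
  touching <- tibble::tibble(lower = c(1, 2), upper = c(2, 3),
                             apex = c(1.5, 2.5), n_members = c(1L, 1L))
  expect_identical(nrow(fuse_overlapping(touching)), 2L)

  # idempotence on random overlapping sets
  withr::with_seed(11, {
    for (i in 1:20) {
      lower <- sort(runif(15, 0, 100))
      width <- runif(15, 0.1, 12)
      raw <- tibble::tibble(lower = lower, upper = lower + width,
                            apex = lower + width / 2, n_members = 1L)
      once <- fuse_overlapping(raw)
      twice <- fuse_overlapping(once)
      expect_equal(as.data.frame(twice), as.data.frame(once))
      validate_buckets(once)
    }
  })
})

test_that("all three builders produce disjoint sorted sets across 100-1500 Th", {
  withr::with_seed(2, {
    cand <- sort(runif(300, 100, 1500))
    cand <- cand[c(TRUE, diff(cand) > 1e-4)]
  })
  adaptive <- build_adaptive_buckets(cand, qe_curve)
  ppm <- build_ppm_buckets(cand, 5)
  const <- build_constant_grid(0.01, 100, 1500)
  for (b in list(adaptive, ppm, const)) {
    expect_silent(validate_buckets(b))
    expect_true(all(diff(b$lower) > 0))
    expect_true(all(utils::head(b$upper, -1) <= utils::tail(b$lower, -1)))
  }
  # adaptive absolute width increases; ppm relative width constant; constant
  # grid absolute width constant
  aw <- adaptive$upper - adaptive$lower
  single <- adaptive$n_members == 1L  # fused buckets are legitimately wider
  expect_true(all(diff(aw[single][order(adaptive$apex[single])]) > 0))
  pw <- (ppm$upper - ppm$lower) / ppm$apex
  expect_equal(max(pw[ppm$n_members == 1L]), min(pw[ppm$n_members == 1L]),
               tolerance = 1e-9)
  cw <- const$upper - const$lower
  expect_equal(max(cw), min(cw), tolerance = 1e-6)
})

test_that("bin_spectrum assigns by half-open interval and is additive", {
  buckets <- tibble::tibble(lower = c(100, 200), upper = c(101, 201),
                            apex = c(100.5, 200.5), n_members = c(1L, 1L))
  expect_equal(bin_spectrum(peak_tbl(100.5, 3), buckets), c(3, 0))
  expect_equal(bin_spectrum(peak_tbl(150, 3), buckets), c(0, 0))
  expect_equal(bin_spectrum(peak_tbl(c(200.1, 200.9), c(3, 4)), buckets), c(0, 7))

  overlapping <- tibble::tibble(lower = c(100, 100.5), upper = c(101, 101.5),
                                apex = c(100.5, 101), n_members = c(1L, 1L))
  expect_error(bin_spectrum(peak_tbl(100.5, 1), overlapping),
               class = "mzadapt_error_validation")
})

test_that("bin_spectrum agrees with a brute-force interval scan", {
  withr::with_seed(23, {
    for (i in 1:25) {
      buckets <- random_buckets(sample(1:12, 1))
      n <- sample(1:30, 1)
      spec <- peak_tbl(runif(n, 90, 510), intensity = runif(n))
      expect_equal(bin_spectrum(spec, buckets), brute_bin(spec, buckets))
      # conservation: binned total <= peak total, equal iff all peaks inside
      total_in <- sum(bin_spectrum(spec, buckets))
      expect_lte(total_in, sum(spec$intensity) + 1e-12)
    }
  })
})

test_that("binned intensity equals total intensity iff every peak is covered", {
  buckets <- tibble::tibble(lower = 100, upper = 200, apex = 150, n_members = 1L)
  inside <- peak_tbl(c(110, 150, 199.999), c(1, 2, 3))
  expect_equal(sum(bin_spectrum(inside, buckets)), sum(inside$intensity))
  mixed <- peak_tbl(c(110, 250), c(1, 5))
  expect_lt(sum(bin_spectrum(mixed, buckets)), sum(mixed$intensity))
})
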