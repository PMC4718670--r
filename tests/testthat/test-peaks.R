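test_that("greedy clustering separates by m/z tolerance and enforces the minimum size", {
  sig <- make_signals(
    scan_index = c(0:4, 2),
    mz = c(100.000, 100.003, 99.997, 100.005, 99.995, 100.50),
    intensity = c(50, 80, 100, 60, 40, 30)
  )
  cl <- cluster_signals(sig, mzWidth = 0.02)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n, 5L) # stray at 100.50 consumed alone, discarded
  expect_equal(cl$mz_center, 99.997) # seed = most intense signal

  # fewer than three signals never form a cluster
  two <- make_signals(0:1, mz = c(100, 100.001), intensity = c(10, 20))
  expect_equal(nrow(cluster_signals(two, 0.02)), 0L)

  # co-m/z compounds at RT 2 and 8 gather into ONE cluster at this stage
  a <- gaussian_signals(100, 2, 0.05, 1000, 0.02)
  b <- gaussian_signals(100, 8, 0.05, 800, 0.02)
  both <- dplyr::bind_rows(a, b)
  expect_equal(nrow(cluster_signals(both, 0.02)), 1L)
})

test_that("one member per scan: the closest in m/z to the seed wins", {
  sig <- make_signals(
    scan_index = c(0, 1, 1, 2),
    mz = c(100.000, 100.010, 100.002, 100.001),
    intensity = c(100, 90, 50, 60)
  )
  cl <- cluster_signals(sig, mzWidth = 0.02)
  expect_equal(cl$n, 3L)
  expect_equal(sort(cl$members[[1]]$mz), c(100.000, 100.001, 100.002))
})

test_that("FWHM matches the symmetric triangle and the Gaussian closed form", {
  tri <- tibble::tibble(rt = 8:12, intensity = c(0, 50, 100, 50, 0))
  expect_equal(compute_fwhm(tri), 2)

  for (sigma in c(0.05, 0.1, 0.2)) {
    tr <- gaussian_signals(100, 5, sigma, 1000, dt = sigma / 10)
    est <- compute_fwhm(tr)
    expect_lt(abs(est - 2.3548 * sigma) / (2.3548 * sigma), 0.03)
  }

  # one-sided monotone trace: fallback to the outermost member on the left
  mono <- tibble::tibble(rt = 0:4 / 10, intensity = c(100, 80, 60, 30, 10))
  w <- compute_fwhm(mono)
  # left crossing = outermost member (rt 0); right interpolated between 60 and 30
  expect_equal(w, (0.2 + 0.1 * (60 - 50) / (60 - 30)) - 0)

  degen <- tibble::tibble(rt = c(1, 1), intensity = c(5, 5))
  expect_error(compute_fwhm(degen), "degenerate")
})

test_that("boundary determination follows valley-first, then farthest-in-zone", {
  w <- 1
  # local minimum inside (t+w, t+1.5w]: becomes the boundary
  tr <- tibble::tibble(
    rt = c(4, 4.5, 5, 5.5, 6, 6.2, 6.3, 6.4),
    intensity = c(10, 50, 100, 50, 12, 8, 11, 9)
  )
  b <- determine_boundaries(tr, w, rt_apex = 5)
  expect_equal(b[["rt_right"]], 6.2) # first local-minimum member beyond t+w
  expect_equal(b[["rt_left"]], 4)

  # no members beyond t+w: outermost member within t+w
  tr2 <- tibble::tibble(rt = c(4.2, 5, 5.8), intensity = c(40, 100, 35))
  b2 <- determine_boundaries(tr2, w, rt_apex = 5)
  expect_equal(unname(b2), c(4.2, 5.8))

  # tailing, monotone decreasing in the zone: farthest member in zone
  tr3 <- tibble::tibble(
    rt = c(4, 5, 6.1, 6.4), intensity = c(50, 100, 30, 20)
  )
  b3 <- determine_boundaries(tr3, w, rt_apex = 5)
  expect_equal(b3[["rt_right"]], 6.4)
  # members beyond t + 1.5w are never boundaries
  tr4 <- tibble::tibble(
    rt = c(4, 5, 6.4, 7.5), intensity = c(50, 100, 30, 20)
  )
  expect_equal(determine_boundaries(tr4, w, rt_apex = 5)[["rt_right"]], 6.4)
})

test_that("trapezoidal abundance matches hand values and the brute-force oracle", {
  expect_equal(
    integrate_abundance(tibble::tibble(rt = 0:2, intensity = c(0, 100, 0))),
    100
  )
  expect_equal(
    integrate_abundance(tibble::tibble(rt = 0:1, intensity = c(100, 100))),
    100
  )
  set.seed(21)
  for (i in 1:25) {
    n <- sample(2:50, 1)
    rt <- sort(runif(n, 0, 10))
    int <- runif(n, 0, 1e6)
    tr <- tibble::tibble(rt = rt, intensity = int)
    expect_equal(integrate_abundance(tr), trapezoid_oracle(rt, int),
      tolerance = 1e-12)
  }
})

test_that("detection recovers disjoint compounds and splits shared-m/z pairs", {
  set.seed(31)
  mzs <- seq(150, 800, length.out = 10)
  rts <- seq(2, 11, length.out = 10)
  cmp <- compound_table(mono_mz = mzs, rt_center = rts,
    height = runif(10, 1e5, 1e6), n_isotopes = 1L)
  run <- simulate_run(cmp, rt_range = c(0, 13), scan_interval = 0.02,
    seed = 9)$run
  pk <- detect_peaks(run, mzWidth = 0.02)
  expect_equal(nrow(pk), 10L)
  expect_true(all(vapply(mzs, function(m) any(abs(pk$mz - m) <= 0.01),
    logical(1))))

  # shared m/z, separated RT: boundary release yields two peaks
  a <- gaussian_signals(100, 2, 0.05, 1000, 0.02)
  b <- gaussian_signals(100, 8, 0.05, 800, 0.02)
  pk2 <- detect_peaks(dplyr::bind_rows(a, b), mzWidth = 0.02)
  expect_equal(nrow(pk2), 2L)
  expect_equal(sort(pk2$rt), c(2, 8), tolerance = 1e-6)

  empty <- make_signals(integer(0), numeric(0), numeric(0))
  expect_equal(nrow(detect_peaks(empty)), 0L)
})

test_that("every signal is consumed at most once and detection is deterministic", {
  set.seed(41)
  cmp <- compound_table(
    mono_mz = c(200, 200.015, 420, 555), rt_center = c(3, 6, 3, 4),
    height = c(9e5, 5e5, 7e5, 3e5), n_isotopes = 1L
  )
  run <- simulate_run(cmp, rt_range = c(0, 8), scan_interval = 0.02,
    seed = 13)$run
  pk1 <- detect_peaks(run, 0.02)
  pk2 <- detect_peaks(run, 0.02)
  expect_identical(tidy(pk1), tidy(pk2))
  # conservation: integrated trace points never exceed input signals and
  # no signal appears in two peaks
  all_pts <- dplyr::bind_rows(pk1$trace)
  expect_lte(nrow(all_pts), nrow(run))
  expect_equal(anyDuplicated(all_pts[, c("scan_index", "mz")]), 0L)
})

test_that("recovered abundance stays within [0.9, 1] of the analytic area", {
  cmp <- compound_table(
    mono_mz = c(250, 480), rt_center = c(4, 9), height = c(1e6, 4e5),
    rt_sigma = c(0.05, 0.12), n_isotopes = 1L
  )
  run <- simulate_run(cmp, rt_range = c(0, 12), scan_interval = 0.01,
    seed = 17)
  pk <- detect_peaks(run$run, 0.02)
  man <- run$manifest
  for (i in seq_len(nrow(man))) {
    j <- which.min(abs(pk$mz - man$mz[i]))
    ratio <- pk$abundance[j] / man$area_true[i]
    expect_gte(ratio, 0.9)
    expect_lte(ratio, 1.0)
  }
})
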