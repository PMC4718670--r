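test_that("centroiding collapses regions to weighted-mean m/z and apex intensity", {
  scan <- tibble::tibble(
    mz = c(100.00, 100.01, 100.02), intensity = c(10, 20, 10)
  )
  out <- centroid_scan(scan)
  expect_equal(nrow(out), 1L)
  expect_equal(out$mz, 100.01)
  expect_equal(out$intensity, 20)

  # region with two maxima splits at the interior minimum
  scan2 <- tibble::tibble(
    mz = 100 + 0:5 / 100, intensity = c(10, 30, 10, 5, 25, 10)
  )
  out2 <- centroid_scan(scan2)
  expect_equal(nrow(out2), 2L)
  expect_equal(out2$mz[1], (100.00 * 10 + 100.01 * 30 + 100.02 * 10) / 50)
  expect_equal(out2$mz[2], (100.03 * 5 + 100.04 * 25 + 100.05 * 10) / 40)
  expect_equal(out2$intensity, c(30, 25))

  expect_equal(nrow(centroid_scan(scan[0, ])), 0L)
})

test_that("zero-intensity points and large m/z gaps delimit regions", {
  scan <- tibble::tibble(
    mz = c(100.00, 100.01, 100.02, 100.03, 100.04),
    intensity = c(10, 20, 0, 15, 5)
  )
  out <- centroid_scan(scan)
  expect_equal(nrow(out), 2L)
  expect_equal(out$intensity, c(20, 15))

  gap <- tibble::tibble(
    mz = c(100.00, 100.01, 100.02, 100.50, 100.51, 100.52),
    intensity = c(10, 20, 10, 5, 25, 10)
  )
  expect_equal(nrow(centroid_scan(gap, mzWidth = 0.02)), 2L)
})

test_that("centroid_run skips centroid scans and conserves region counts", {
  cmp <- compound_table(mono_mz = c(250, 400), rt_center = c(1, 1.5),
    height = c(1e5, 2e5), n_isotopes = 1L)
  cen <- simulate_run(cmp, rt_range = c(0.5, 2), scan_interval = 0.05,
    mode = "centroid", seed = 5)$run
  expect_identical(
    tibble::as_tibble(centroid_run(cen)), tibble::as_tibble(cen)
  )

  prof <- simulate_run(cmp, rt_range = c(0.5, 2), scan_interval = 0.05,
    mode = "profile", seed = 5)$run
  centroided <- centroid_run(prof)
  expect_identical(run_mode(centroided), "centroid")
  expect_lte(nrow(centroided), nrow(prof))
  # each isolated compound trace yields one centroid signal per scan,
  # recovered near its true m/z
  sig <- tibble::as_tibble(centroided)
  expect_true(all(abs(sort(unique(round(sig$mz, 3))) - c(250, 400)) < 0.001))
})

test_that("segmented S/N filter keeps hand-derived signal sets", {
  # single window: N = mean(1,1,1,1,97) = 20.2; only 97/20.2 = 4.80 >= 3
  scan <- make_signals(0:4, mz = 100:104, intensity = c(1, 1, 1, 1, 97))
  kept <- remove_noise(scan, n_segments = 1)
  expect_equal(kept$intensity, 97)

  # uniform scan: S/N = 1 everywhere -> everything removed
  flat <- make_signals(0:9, mz = 100 + 0:9, intensity = rep(7, 10))
  expect_equal(nrow(remove_noise(flat)), 0L)

  expect_equal(nrow(remove_noise(flat[0, ])), 0L)

  # two segments, no overlap: verdicts are window-local
  two <- make_signals(0:5,
    mz = c(100, 101, 102, 200, 201, 202),
    intensity = c(10, 10, 100, 5, 5, 50)
  )
  kept2 <- remove_noise(two, n_segments = 2, overlap_fraction = 0)
  # window 1 mean 40 -> 100/40 = 2.5 < 3; window 2 mean 20 -> 50/20 = 2.5 < 3
  expect_equal(nrow(kept2), 0L)
  kept3 <- remove_noise(two, n_segments = 2, overlap_fraction = 0,
    snr_threshold = 2)
  expect_equal(kept3$intensity, c(100, 50))
})

test_that("kept signals are a subset with S/N above threshold in some window", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(5:80, 1)
    scan <- make_signals(seq_len(n) - 1,
      mz = sort(runif(n, 100, 900)),
      intensity = rexp(n, 1 / 100) + 1
    )
    kept <- remove_noise(scan)
    expect_true(all(kept$mz %in% scan$mz)) # subset, no mutation
    expect_true(all(diff(match(kept$mz, scan$mz)) > 0)) # order preserved
    if (nrow(kept) > 0) {
      # every kept signal beats 3x the mean of at least one widened window
      width <- (max(scan$mz) - min(scan$mz)) / 10
      ok <- vapply(seq_len(nrow(kept)), function(j) {
        any(vapply(1:10, function(w) {
          lo <- min(scan$mz) + (w - 1) * width - 0.1 * width
          hi <- min(scan$mz) + w * width + 0.1 * width
          inw <- scan$mz >= lo & scan$mz <= hi
          kept$mz[j] >= lo && kept$mz[j] <= hi &&
            kept$intensity[j] / mean(scan$intensity[inw]) >= 3
        }, logical(1)))
      }, logical(1))
      expect_true(all(ok))
    }
  }
})
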