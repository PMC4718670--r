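# helper: a deisotoped peak table with synthetic ids
toy_peaks <- function(mz, rt, height = NULL, abundance = NULL) {
  n <- length(mz)
  tibble::tibble(
    peak_id = paste0("P", seq_len(n)), mz = mz, rt = rt,
    height = height %||% rep(100, n),
    abundance = abundance %||% rep(10, n),
    charge = rep(0L, n), isotope_ratio = rep(0, n)
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("reference selection takes the largest list, first on ties", {
  mk <- function(n) toy_peaks(seq_len(n) + 100, seq_len(n) / 10)
  expect_equal(select_reference(list(mk(120), mk(300), mk(250))), 2L)
  expect_equal(select_reference(list(mk(5))), 1L)
  expect_equal(select_reference(list(mk(100), mk(100))), 1L)
  expect_error(select_reference(list(mk(0), mk(0))), "empty")
})

test_that("landmark matching is one-to-one within tolerances", {
  set.seed(5)
  mz <- sort(runif(50, 100, 900))
  rt <- sort(runif(50, 1, 14))
  ref <- toy_peaks(mz, rt, height = runif(50, 1e4, 1e6))
  # identical lists: every peak is a landmark with zero offset
  lm <- find_landmarks(ref, ref)
  expect_equal(nrow(lm), 50L)
  expect_equal(lm$target_rt - lm$ref_rt, rep(0, 50))
  expect_false(attr(lm, "fallback"))

  # constant +0.1 min shift within rtTol 0.2
  target <- ref
  target$rt <- target$rt + 0.1
  lm2 <- find_landmarks(ref, target)
  expect_equal(nrow(lm2), 50L)
  expect_equal(unique(round(lm2$target_rt - lm2$ref_rt, 9)), 0.1)

  # disjoint m/z: no landmarks, fallback flagged
  far <- toy_peaks(mz + 5, rt)
  lm3 <- find_landmarks(ref, far)
  expect_equal(nrow(lm3), 0L)
  expect_true(attr(lm3, "fallback"))
  expect_identical(fit_rt_mapping(lm3)$adjust, identity)
})

test_that("LOESS RT mapping recovers constant and smooth drifts", {
  set.seed(8)
  rt <- sort(runif(200, 0.5, 14.5))
  mz <- runif(200, 100, 900)
  base <- tibble::tibble(ref_id = "x", target_id = "y", mz = mz)

  zero <- dplyr::bind_cols(base, ref_rt = rt, target_rt = rt)
  m0 <- fit_rt_mapping(zero)
  expect_lt(max(abs(m0$adjust(rt) - rt)), 1e-9)

  const <- dplyr::bind_cols(base, ref_rt = rt + 0.1, target_rt = rt)
  m1 <- fit_rt_mapping(const)
  expect_lt(max(abs(m1$adjust(rt) - (rt + 0.1))), 1e-6)

  # sinusoidal drift, amplitude 0.1 min: median landmark residual < 0.01
  drift <- 0.1 * sin(2 * pi * rt / 14)
  sine <- dplyr::bind_cols(base, ref_rt = rt + drift, target_rt = rt)
  m2 <- fit_rt_mapping(sine)
  resid <- abs(m2$adjust(rt) - (rt + drift))
  expect_lt(median(resid), 0.01)
  # tidiers expose landmarks and fit quality
  expect_equal(nrow(tidy(m2)), 200L)
  expect_lt(glance(m2)$rmse, 0.02)
  expect_false(glance(m2)$fallback)
})

test_that("pair alignment matches drifted replicates and keeps singletons", {
  set.seed(12)
  n <- 120
  mz <- sort(runif(n, 100, 900))
  rt <- sort(runif(n, 1, 14))
  ref <- toy_peaks(mz, rt, height = runif(n, 1e4, 1e6))
  self <- align_pair(ref, ref)
  expect_equal(nrow(self$pairs), n)
  expect_identical(self$pairs$ref_id, self$pairs$target_id)

  target <- ref
  target$rt <- target$rt + 0.15 * sin(pi * rt / 14) # smooth drift <= 0.15 min
  res <- align_pair(ref, target)
  matched_true <- mean(res$pairs$ref_id == res$pairs$target_id)
  expect_gte(matched_true, 0.95)

  # a peak present only in the target surfaces as unmatched
  extra <- toy_peaks(c(mz, 950), c(rt, 7))
  extra$peak_id <- paste0("Q", seq_len(n + 1))
  res2 <- align_pair(ref, extra)
  expect_true(paste0("Q", n + 1) %in% res2$unmatched_target)
})

test_that("replicate alignment uses medians and tolerates missing peaks", {
  r1 <- toy_peaks(c(100.01, 200), c(5.0, 7), abundance = c(10, 50))
  r2 <- toy_peaks(c(100.02, 200), c(5.1, 7), abundance = c(12, 55))
  r3 <- toy_peaks(c(100.03, 200, 300), c(5.05, 7, 9), abundance = c(20, 60, 5))
  reps <- align_replicates(list(R1 = r1, R2 = r2, R3 = r3))
  expect_equal(nrow(reps), 3L)
  f1 <- reps[which.min(abs(reps$mz - 100.02)), ]
  expect_equal(f1$mz, 100.02) # odd-count median
  f3 <- reps[which.min(abs(reps$mz - 300)), ]
  expect_equal(nrow(f3$constituents[[1]]), 1L) # kept though in one replicate

  # even-count median is the mean of the central values
  r4 <- toy_peaks(100.01, 5.0)
  r5 <- toy_peaks(100.02, 5.1)
  reps2 <- align_replicates(list(R1 = r4, R2 = r5))
  expect_equal(reps2$rt, 5.05)
  expect_equal(reps2$mz, 100.015)
})

test_that("feature assembly is stable under replicate permutation", {
  set.seed(23)
  n <- 60
  mk <- function(jit) {
    toy_peaks(
      sort(runif(n, 100, 900)) + runif(n, -0.005, 0.005),
      sort(runif(n, 1, 14)) + jit,
      height = runif(n, 1e4, 1e6), abundance = runif(n, 1e3, 1e5)
    )
  }
  base_mz <- sort(runif(n, 100, 900))
  base_rt <- sort(runif(n, 1, 14))
  mk2 <- function(jit, drop = integer(0)) {
    keep <- setdiff(seq_len(n), drop)
    toy_peaks(base_mz[keep], base_rt[keep] + jit,
      height = seq_len(n)[keep] * 100, abundance = seq_len(n)[keep] * 10)
  }
  lists <- list(R1 = mk2(0), R2 = mk2(0.05, drop = 3), R3 = mk2(-0.04, drop = 8))
  a <- align_replicates(lists)
  b <- align_replicates(rev(lists))
  key <- function(x) dplyr::arrange(
    tibble::tibble(mz = round(x$mz, 6), rt = round(x$rt, 3)), mz
  )
  expect_equal(key(a), key(b))
  # no feature contains two peaks from the same replicate
  for (cc in a$constituents) {
    expect_equal(anyDuplicated(cc$origin), 0L)
  }
})

test_that("sample-level alignment carries per-replicate abundance maps", {
  r <- function(ab) toy_peaks(c(150, 300), c(4, 8), abundance = ab)
  s1 <- align_replicates(list(R1 = r(c(10, 100)), R2 = r(c(12, 110))))
  s2 <- align_replicates(list(R1 = r(c(20, 200)), R2 = r(c(22, 210))))
  feats <- align_samples(list(S1 = s1, S2 = s2))
  expect_equal(nrow(feats), 2L)
  cc <- feats$constituents[[which.min(abs(feats$mz - 150))]]
  expect_equal(sort(unique(cc$sample)), c("S1", "S2"))
  expect_equal(nrow(cc), 4L)
  expect_equal(sort(cc$abundance), c(10, 12, 20, 22))
})
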