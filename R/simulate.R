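#' Specify compounds for a synthetic LC-MS1 run
#'
#' Builds the compound table consumed by [simulate_run()] and
#' [simulate_experiment()]. Each compound elutes as a Gaussian profile and
#' carries an isotope envelope at m/z spacings of `1/charge`. The second
#' isotope has `isotope_ratio` times the monoisotope abundance; isotopes
#' beyond the second decay geometrically with the same ratio (a simulator
#' convenience — only the mono/second ratio is asserted anywhere).
#'
#' @param mono_mz Monoisotopic m/z values (Th).
#' @param charge Charge states (1-4).
#' @param isotope_ratio Second-isotope / monoisotope abundance ratios.
#' @param rt_center Elution apex times (minutes).
#' @param rt_sigma Gaussian elution widths (minutes).
#' @param height Apex intensities (counts).
#' @param n_isotopes Number of isotope traces to render (>= 1).
#'
#' @return A tibble with one row per compound.
#' @export
compound_table <- function(mono_mz, charge = 1L, isotope_ratio = 0.1,
                           rt_center, rt_sigma = 0.05, height = 1e6,
                           n_isotopes = 2L) {
  tb <- tibble::tibble(
    compound_id = paste0("C", seq_along(mono_mz)),
    mono_mz = mono_mz, charge = as.integer(charge),
    isotope_ratio = isotope_ratio, rt_center = rt_center,
    rt_sigma = rt_sigma, height = height, n_isotopes = as.integer(n_isotopes)
  )
  stopifnot(all(tb$charge %in% 1:4), all(tb$rt_sigma > 0), all(tb$height > 0),
    all(tb$n_isotopes >= 1))
  tb
}

#' Simulate one LC-MS1 run with a ground-truth manifest
#'
#' Renders each compound's isotope traces as Gaussian elution profiles
#' sampled at a fixed scan rate, optionally warps retention time with a
#' smooth drift function, adds a uniform low-intensity noise floor, and (in
#' profile mode) renders every signal as a narrow Gaussian in m/z. The
#' manifest records the exact apex m/z and RT, analytic trace areas
#' (`height * sigma * sqrt(2*pi)` per isotope), charges and isotope ratios.
#'
#' @param compounds Compound table from [compound_table()].
#' @param rt_range Run retention-time range in minutes, `c(min, max)`.
#' @param scan_interval Time between scans (minutes).
#' @param mode `"centroid"` or `"profile"`.
#' @param mz_sampling Profile-mode m/z grid spacing (Th).
#' @param mz_sigma Profile-mode Gaussian peak width in m/z (Th).
#' @param noise_floor Mean intensity of noise signals; 0 disables noise.
#' @param noise_per_scan Number of noise signals per scan.
#' @param noise_mz_range m/z range over which noise signals scatter.
#' @param drift Optional monotone warp applied to elution apexes: a function
#'   of RT (minutes) returning warped RT.
#' @param scale Multiplier applied to all compound heights (per-sample
#'   amount factor).
#' @param seed Integer seed; the run is fully reproducible from it.
#' @param run_id Run identifier.
#'
#' @return A list with elements `run` (an [ms_run]) and `manifest` (tibble:
#'   `compound_id`, `isotope`, `mz`, `rt_true`, `height`, `area_true`,
#'   `charge`, `isotope_ratio`).
#' @export
simulate_run <- function(compounds, rt_range = c(0, 15), scan_interval = 0.02,
                         mode = c("centroid", "profile"), mz_sampling = 0.002,
                         mz_sigma = 0.004, noise_floor = 0, noise_per_scan = 300,
                         noise_mz_range = c(100, 1000), drift = NULL,
                         scale = 1, seed = 1, run_id = "sim") {
  mode <- match.arg(mode)
  stopifnot(scan_interval > 0, scale > 0)
  with_local_seed(seed, {
    rts <- seq(rt_range[1], rt_range[2], by = scan_interval)
    scans <- tibble::tibble(
      scan_index = seq_along(rts) - 1L, rt = rts,
      centroided = (mode == "centroid")
    )
    iso <- tidyr::uncount(compounds, weights = .data$n_isotopes, .id = "isotope")
    iso$isotope <- iso$isotope - 1L
    iso$mz <- iso$mono_mz + iso$isotope / iso$charge
    iso$h <- scale * iso$height * iso$isotope_ratio^iso$isotope
    iso$rt_true <- if (is.null(drift)) iso$rt_center else drift(iso$rt_center)

    empty_sig <- tibble::tibble(
      scan_index = integer(0), rt = numeric(0), mz = numeric(0),
      intensity = numeric(0)
    )
    sig <- purrr::pmap_dfr(
      iso[, c("mz", "h", "rt_true", "rt_sigma")],
      function(mz, h, rt_true, rt_sigma) {
        keep <- abs(rts - rt_true) <= 3 * rt_sigma
        tibble::tibble(
          scan_index = scans$scan_index[keep], rt = rts[keep], mz = mz,
          intensity = h * exp(-(rts[keep] - rt_true)^2 / (2 * rt_sigma^2))
        )
      }
    )
    sig <- dplyr::bind_rows(empty_sig, sig)
    if (noise_floor > 0 && noise_per_scan > 0) {
      n <- noise_per_scan * length(rts)
      sig <- dplyr::bind_rows(sig, tibble::tibble(
        scan_index = rep(scans$scan_index, each = noise_per_scan),
        rt = rep(rts, each = noise_per_scan),
        mz = stats::runif(n, noise_mz_range[1], noise_mz_range[2]),
        intensity = stats::runif(n, 0.5, 1.5) * noise_floor
      ))
    }
    if (mode == "profile") sig <- render_profile(sig, mz_sampling, mz_sigma)
    sig <- sig[sig$intensity > 0 | mode == "profile", ]
    manifest <- tibble::tibble(
      compound_id = iso$compound_id, isotope = iso$isotope, mz = iso$mz,
      rt_true = iso$rt_true, height = iso$h,
      area_true = iso$h * iso$rt_sigma * sqrt(2 * pi),
      charge = iso$charge, isotope_ratio = iso$isotope_ratio
    )
    list(
      run = ms_run(sig, scans = scans, run_id = run_id, mode = mode),
      manifest = manifest
    )
  })
}

# expand centroid sticks into Gaussian m/z profiles on a fixed grid,
# with explicit zero points closing each region
render_profile <- function(sig, mz_sampling, mz_sigma) {
  prof <- purrr::pmap_dfr(
    sig[, c("scan_index", "rt", "mz", "intensity")],
    function(scan_index, rt, mz, intensity) {
      half <- ceiling(4 * mz_sigma / mz_sampling)
      grid <- mz + (-half:half) * mz_sampling
      ints <- intensity * exp(-(grid - mz)^2 / (2 * mz_sigma^2))
      ints[c(1, length(ints))] <- 0
      tibble::tibble(scan_index = scan_index, rt = rt, mz = grid, intensity = ints)
    }
  )
  prof <- dplyr::arrange(prof, .data$scan_index, .data$mz)
  # merge coincident grid points from overlapping envelopes
  dplyr::summarise(
    dplyr::group_by(prof, .data$scan_index, .data$rt, .data$mz),
    intensity = max(.data$intensity), .groups = "drop"
  )
}

#' Simulate a multi-sample, multi-replicate experiment
#'
#' Draws one run per technical replicate of each sample. Per-sample amounts
#' are set through `sample_scales`; each non-first replicate receives a
#' smooth monotone RT drift `t + A * sin(pi * t / T)` with its own amplitude
#' `A` bounded by `drift_max` (minutes), plus small log-normal replicate
#' variation of compound heights.
#'
#' @param compounds Compound table from [compound_table()].
#' @param sample_scales Named list or vector: per-sample height multiplier,
#'   either one scalar per sample or one value per compound (the
#'   standard-mixture design, where each compound has its own sample
#'   ratio).
#' @param n_replicates Technical replicates per sample.
#' @param drift_max Maximum |drift| in minutes (0 disables drift).
#' @param rep_cv Log-normal coefficient of variation of replicate heights.
#' @param seed Integer seed.
#' @param ... Passed to [simulate_run()] (`rt_range`, `scan_interval`,
#'   `mode`, `noise_floor`, ...).
#'
#' @return List with `runs` (named list `sample -> replicate -> ms_run`) and
#'   `manifest` (tibble with `sample` and `replicate` columns; the
#'   `compound_id` keys pairings across runs).
#' @export
simulate_experiment <- function(compounds, sample_scales = c(S1 = 1, S2 = 1),
                                n_replicates = 3, drift_max = 0.1,
                                rep_cv = 0, seed = 1, ...) {
  rt_max <- list(...)$rt_range
  rt_max <- if (is.null(rt_max)) 15 else rt_max[2]
  with_local_seed(seed, {
    runs <- list()
    manifest <- list()
    for (s in names(sample_scales)) {
      runs[[s]] <- list()
      for (r in seq_len(n_replicates)) {
        amp <- if (r == 1 || drift_max == 0) 0 else stats::runif(1, -drift_max, drift_max)
        drift <- if (amp == 0) NULL else local({
          a <- amp
          function(t) t + a * sin(pi * t / rt_max)
        })
        cmp <- compounds
        cmp$height <- cmp$height * sample_scales[[s]]
        if (rep_cv > 0) {
          cmp$height <- cmp$height * stats::rlnorm(nrow(cmp), 0, rep_cv)
        }
        rep_id <- paste0("R", r)
        sim <- simulate_run(cmp,
          drift = drift,
          seed = sample.int(2^31 - 1, 1), run_id = paste(s, rep_id, sep = "/"),
          ...
        )
        runs[[s]][[rep_id]] <- sim$run
        m <- sim$manifest
        m$sample <- s
        m$replicate <- rep_id
        manifest[[length(manifest) + 1L]] <- m
      }
    }
    list(runs = runs, manifest = dplyr::bind_rows(manifest))
  })
}

#' Write an [ms_run] to a minimal mzML file
#'
#' Emits mzML 1.1.0 (via the proteowizard-backed writer) that [read_run()]
#' reads back losslessly up to float round-trip. The per-spectrum centroided
#' flag follows the run's mode.
#'
#' @param run An [ms_run].
#' @param path Output path (should end in `.mzML`).
#' @return `path`, invisibly.
#' @export
write_mzml <- function(run, path) {
  scans <- run_scans(run)
  sig <- tibble::as_tibble(run)
  pks <- lapply(seq_len(nrow(scans)), function(i) {
    pts <- sig[sig$scan_index == scans$scan_index[i], ]
    pts <- pts[order(pts$mz), ]
    cbind(mz = pts$mz, intensity = pts$intensity)
  })
  centroided <- ifelse(is.na(scans$centroided),
    identical(attr(run, "mode"), "centroid"), scans$centroided
  )
  n <- nrow(scans)
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = scans$scan_index, msLevel = 1L,
    polarity = 1L, peaksCount = vapply(pks, nrow, integer(1)),
    totIonCurrent = vapply(pks, function(m) sum(m[, 2]), numeric(1)),
    retentionTime = scans$rt * 60,
    basePeakMZ = vapply(pks, function(m) if (nrow(m)) m[which.max(m[, 2]), 1] else 0, numeric(1)),
    basePeakIntensity = vapply(pks, function(m) if (nrow(m)) max(m[, 2]) else 0, numeric(1)),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = vapply(pks, function(m) if (nrow(m)) min(m[, 1]) else 0, numeric(1)),
    highMZ = vapply(pks, function(m) if (nrow(m)) max(m[, 1]) else 0, numeric(1)),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", scans$scan_index),
    centroided = centroided, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_, scanWindowLowerLimit = NA_real_,
    scanWindowUpperLimit = NA_real_
  )
  suppressWarnings(mzR::writeMSData(pks, file = path, header = hdr))
  invisible(path)
}

# evaluate expr under a local RNG state seeded with `seed`
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}
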