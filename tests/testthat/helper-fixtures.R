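# fixtures built in code; no binary files

# signals tibble from parallel vectors, rt = scan_index * dt minutes
make_signals <- function(scan_index, mz, intensity, dt = 0.02) {
  tibble::tibble(
    scan_index = as.integer(scan_index), rt = scan_index * dt,
    mz = mz, intensity = intensity
  )
}

# one Gaussian EIC trace as a signals tibble
gaussian_signals <- function(mz, rt_center, sigma, height, dt,
                             rt_range = c(0, 15)) {
  rts <- seq(rt_range[1], rt_range[2], by = dt)
  keep <- abs(rts - rt_center) <= 3 * sigma
  tibble::tibble(
    scan_index = which(keep) - 1L, rt = rts[keep], mz = mz,
    intensity = height * exp(-(rts[keep] - rt_center)^2 / (2 * sigma^2))
  )
}

# noise-free centroid run with isotope envelopes of known charge/ratio:
# identical co-eluting Gaussian shapes per envelope
envelope_run <- function(mono_mz, charge, ratio, rt_center, height = 1e6,
                         sigma = 0.05, dt = 0.01, n_isotopes = 2,
                         rt_range = c(0, max(rt_center) + 1)) {
  cmp <- compound_table(
    mono_mz = mono_mz, charge = charge, isotope_ratio = ratio,
    rt_center = rt_center, rt_sigma = sigma, height = height,
    n_isotopes = n_isotopes
  )
  simulate_run(cmp,
    rt_range = rt_range, scan_interval = dt, mode = "centroid",
    noise_floor = 0, seed = 42
  )
}

# full mzR header frame for writing mixed-level test files
ms2_test_header <- function(msLevel, rt_sec, npts) {
  n <- length(msLevel)
  data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = msLevel,
    polarity = 1L, peaksCount = npts, totIonCurrent = 1,
    retentionTime = rt_sec, basePeakMZ = 0, basePeakIntensity = 0,
    collisionEnergy = 0, ionisationEnergy = 0, lowMZ = 0, highMZ = 0,
    precursorScanNum = ifelse(msLevel > 1, 1L, 0L),
    precursorMZ = ifelse(msLevel > 1, 100, 0),
    precursorCharge = ifelse(msLevel > 1, 1L, 0L), precursorIntensity = 0,
    mergedScan = 0L, mergedResultScanNum = 0L, mergedResultStartScanNum = 0L,
    mergedResultEndScanNum = 0L, injectionTime = 0,
    filterString = NA_character_, spectrumId = paste0("scan=", seq_len(n)),
    centroided = TRUE, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_, scanWindowLowerLimit = NA_real_,
    scanWindowUpperLimit = NA_real_
  )
}

# brute-force trapezoid oracle, written independently of the implementation
trapezoid_oracle <- function(rt, intensity) {
  total <- 0
  for (k in seq_len(length(rt) - 1)) {
    total <- total + (intensity[k] + intensity[k + 1]) / 2 * (rt[k + 1] - rt[k])
  }
  total
}
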