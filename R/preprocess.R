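#' Centroid one profile-mode scan
#'
#' Collapses each contiguous above-zero profile region into centroid
#' signals. A region containing exactly one local maximum yields one
#' signal; regions with several local maxima are split at their interior
#' local minima (the minimum point starts the next sub-region). The
#' centroid m/z is the intensity-weighted mean of the region's points and
#' the centroid intensity is the region's maximum point intensity, so that
#' chromatographic apex heights are preserved for downstream FWHM and
#' shape-similarity computations. Regions are additionally cut at m/z gaps
#' larger than `mzWidth`, which delimits profile islands in files that omit
#' explicit zero-intensity points.
#'
#' @param scan Data frame with columns `mz` and `intensity`, sorted by
#'   m/z (one scan).
#' @param mzWidth m/z clustering tolerance (Th) used for the gap cut.
#'
#' @return Tibble of centroided `mz`, `intensity`, sorted by m/z.
#' @export
centroid_scan <- function(scan, mzWidth = 0.02) {
  mz <- scan$mz
  int <- scan$intensity
  if (length(mz) == 0L) {
    return(tibble::tibble(mz = numeric(0), intensity = numeric(0)))
  }
  nz <- int > 0
  gap <- c(FALSE, diff(mz) > mzWidth)
  region <- cumsum(c(TRUE, diff(nz) != 0) | gap)
  out_mz <- numeric(0)
  out_int <- numeric(0)
  for (idx in split(seq_along(mz), region)) {
    if (!nz[idx[1]]) next
    for (seg in split_at_minima(int[idx])) {
      pts <- idx[seg]
      out_mz <- c(out_mz, sum(mz[pts] * int[pts]) / sum(int[pts]))
      out_int <- c(out_int, max(int[pts]))
    }
  }
  ord <- order(out_mz)
  tibble::tibble(mz = out_mz[ord], intensity = out_int[ord])
}

# split 1..n into sub-ranges cut before each interior strict local minimum
split_at_minima <- function(int) {
  n <- length(int)
  if (n < 3L) return(list(seq_len(n)))
  interior <- 2:(n - 1)
  is_min <- int[interior] < int[interior - 1] & int[interior] < int[interior + 1]
  cuts <- interior[is_min]
  starts <- c(1L, cuts)
  ends <- c(cuts - 1L, n)
  purrr::map2(starts, ends, seq)
}

#' Centroid every profile scan of a run
#'
#' Scans already in centroid mode pass through unchanged; the returned run
#' is centroid mode throughout.
#'
#' @param run An [ms_run].
#' @param mzWidth m/z tolerance forwarded to [centroid_scan()].
#' @return A centroid-mode [ms_run].
#' @export
centroid_run <- function(run, mzWidth = 0.02) {
  scans <- run_scans(run)
  sig <- tibble::as_tibble(run)
  decl <- scans$centroided
  if (any(is.na(decl))) {
    decl[is.na(decl)] <- identical(run_mode(run), "centroid")
  }
  pieces <- lapply(seq_len(nrow(scans)), function(i) {
    pts <- sig[sig$scan_index == scans$scan_index[i], ]
    if (nrow(pts) == 0L) return(NULL)
    if (decl[i]) {
      pts[pts$intensity > 0, ]
    } else {
      cen <- centroid_scan(pts, mzWidth)
      tibble::tibble(
        scan_index = scans$scan_index[i], rt = scans$rt[i],
        mz = cen$mz, intensity = cen$intensity
      )
    }
  })
  scans$centroided <- TRUE
  out <- dplyr::bind_rows(pieces)
  ms_run(out,
    scans = scans, run_id = attr(run, "run_id"), mode = "centroid",
    source_path = attr(run, "source_path")
  )
}

#' Remove noise signals from one scan by segmented S/N filtering
#'
#' The scan's m/z range is divided into `n_segments` equal-width windows,
#' each widened on both sides by `overlap_fraction / 2` of the window width
#' so that adjacent windows overlap by `overlap_fraction` of their width.
#' The noise level N of a window is the arithmetic mean intensity of the
#' signals inside the widened window (the candidate signal included). A
#' signal is kept iff `intensity / N >= snr_threshold` in at least one
#' window containing it; windows holding no signal impose no verdict.
#'
#' @param signals Data frame with `mz` and `intensity` for one scan,
#'   sorted by m/z.
#' @param n_segments Number of windows (default 10).
#' @param overlap_fraction Fraction of window width shared by neighbours
#'   (default 0.2).
#' @param snr_threshold Minimum signal-to-noise ratio (default 3).
#'
#' @return The kept subset of `signals`, order preserved.
#' @export
remove_noise <- function(signals, n_segments = 10, overlap_fraction = 0.2,
                         snr_threshold = 3) {
  stopifnot(n_segments >= 1, overlap_fraction >= 0, overlap_fraction < 1,
    snr_threshold > 0)
  n <- nrow(signals)
  if (n == 0L) return(signals)
  mz <- signals$mz
  int <- signals$intensity
  width <- (max(mz) - min(mz)) / n_segments
  if (width == 0) { # all signals at one m/z: a single window
    keep <- int / mean(int) >= snr_threshold
    return(signals[keep, , drop = FALSE])
  }
  pad <- overlap_fraction / 2 * width
  keep <- rep(FALSE, n)
  for (i in seq_len(n_segments)) {
    lo <- min(mz) + (i - 1) * width - pad
    hi <- min(mz) + i * width + pad
    inside <- mz >= lo & mz <= hi
    if (!any(inside)) next
    noise <- mean(int[inside])
    keep <- keep | (inside & int / noise >= snr_threshold)
  }
  signals[keep, , drop = FALSE]
}

#' Remove noise from every scan of a run
#'
#' @param run A centroid-mode [ms_run].
#' @inheritParams remove_noise
#' @return An [ms_run] containing only signals passing the S/N filter.
#' @export
denoise_run <- function(run, n_segments = 10, overlap_fraction = 0.2,
                        snr_threshold = 3) {
  sig <- tibble::as_tibble(run)
  kept <- dplyr::group_modify(
    dplyr::group_by(sig, .data$scan_index),
    ~ remove_noise(.x, n_segments, overlap_fraction, snr_threshold)
  )
  replace_signals(run, dplyr::ungroup(kept))
}
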