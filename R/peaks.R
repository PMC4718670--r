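#' Greedy m/z clustering of signals into candidate EICs
#'
#' Starting from the globally most intense unclustered signal (ties broken
#' by lowest scan index, then lowest m/z), gathers every unclustered signal
#' whose m/z lies within `mzWidth` of the seed. When several signals of one
#' scan fall inside the tolerance, only the one closest in m/z to the seed
#' joins the cluster (an EIC has one intensity per time point); the others
#' stay available. Clusters with at least `min_members` signals are
#' emitted; smaller gatherings are consumed and discarded. The procedure
#' iterates until no signal is left unclustered.
#'
#' @param signals Data frame of denoised signals with columns `scan_index`,
#'   `rt`, `mz`, `intensity`.
#' @param mzWidth m/z tolerance (Th).
#' @param min_members Minimum cluster size (default 3).
#'
#' @return Tibble with one row per emitted cluster: `cluster_id`,
#'   `mz_center` (seed m/z), `n`, and a `members` list-column of signal
#'   tibbles ordered by scan index.
#' @export
cluster_signals <- function(signals, mzWidth = 0.02, min_members = 3) {
  state <- cluster_state(signals)
  out <- list()
  while (TRUE) {
    cl <- next_cluster(state, mzWidth)
    if (is.null(cl)) break
    state$available[cl$members] <- FALSE
    if (length(cl$members) >= min_members) out[[length(out) + 1L]] <- cl
  }
  tibble::tibble(
    cluster_id = seq_along(out),
    mz_center = vapply(out, function(cl) state$mz[cl$seed], numeric(1)),
    n = vapply(out, function(cl) length(cl$members), integer(1)),
    members = lapply(out, function(cl) member_trace(state, cl$members))
  )
}

cluster_state <- function(signals) {
  list(
    scan_index = signals$scan_index, rt = signals$rt, mz = signals$mz,
    intensity = signals$intensity, available = rep(TRUE, nrow(signals))
  )
}

member_trace <- function(state, idx) {
  idx <- idx[order(state$scan_index[idx])]
  tibble::tibble(
    scan_index = state$scan_index[idx], rt = state$rt[idx],
    mz = state$mz[idx], intensity = state$intensity[idx]
  )
}

# one gather step: seed + at most one member per scan; NULL when exhausted
next_cluster <- function(state, mzWidth) {
  avail <- which(state$available)
  if (length(avail) == 0L) return(NULL)
  ints <- state$intensity[avail]
  top <- avail[ints == max(ints)]
  top <- top[order(state$scan_index[top], state$mz[top])][1]
  near <- avail[abs(state$mz[avail] - state$mz[top]) <= mzWidth]
  dist <- abs(state$mz[near] - state$mz[top])
  near <- near[order(state$scan_index[near], dist, state$mz[near])]
  members <- near[!duplicated(state$scan_index[near])]
  list(seed = top, members = members)
}

#' Full width at half maximum of an EIC trace
#'
#' With apex intensity I at retention time t, the FWHM is the RT distance
#' between the points where the trace crosses I/2 on either side of the
#' apex, found by linear interpolation between the bracketing trace
#' members. When a side never falls below I/2 the outermost member's RT is
#' used for that side (fallback).
#'
#' @param trace Data frame with `rt` and `intensity`, one point per scan,
#'   sorted by rt; at least 2 distinct RTs.
#' @return FWHM in minutes.
#' @export
compute_fwhm <- function(trace) {
  rt <- trace$rt
  int <- trace$intensity
  if (length(unique(rt)) < 2L) {
    stop("degenerate cluster: trace spans fewer than 2 distinct retention times")
  }
  a <- apex_index(int, rt)
  half <- int[a] / 2
  rt_lo <- half_crossing(rt, int, a, half, -1L)
  rt_hi <- half_crossing(rt, int, a, half, +1L)
  rt_hi - rt_lo
}

apex_index <- function(int, rt) {
  cand <- which(int == max(int))
  cand[which.min(rt[cand])]
}

# interpolated RT of the first crossing below `half` walking from the apex
# in direction `dir`; outermost member RT when no crossing exists
half_crossing <- function(rt, int, a, half, dir) {
  n <- length(rt)
  j <- a + dir
  while (j >= 1 && j <= n) {
    if (int[j] <= half) {
      if (int[j] == half || int[j - dir] == int[j]) return(rt[j])
      frac <- (int[j - dir] - half) / (int[j - dir] - int[j])
      return(rt[j - dir] + frac * (rt[j] - rt[j - dir]))
    }
    j <- j + dir
  }
  rt[if (dir < 0) 1 else n]
}

#' Dynamic EIC boundary determination from the FWHM
#'
#' Initial boundaries are `t - w` and `t + w` for apex time t and FWHM w.
#' To absorb fronting/tailing, each side is extended independently into the
#' zone `(t + w, t + 1.5 w]` (mirrored on the left): the boundary becomes
#' the first trace member, scanning outward, whose intensity is a strict
#' local minimum within the trace, else the farthest member inside the
#' zone. A side whose zone holds no member keeps the outermost member RT
#' within `t + w` (or `t - w`).
#'
#' @param trace Data frame with `rt` and `intensity` sorted by rt.
#' @param w FWHM in minutes (from [compute_fwhm()]).
#' @param rt_apex Apex RT; computed from the trace when omitted.
#' @return Named numeric `c(rt_left, rt_right)`.
#' @export
determine_boundaries <- function(trace, w, rt_apex = NULL) {
  rt <- trace$rt
  int <- trace$intensity
  if (is.null(rt_apex)) rt_apex <- rt[apex_index(int, rt)]
  n <- length(rt)
  is_local_min <- rep(FALSE, n)
  if (n >= 3) {
    interior <- 2:(n - 1)
    is_local_min[interior] <- int[interior] < int[interior - 1] &
      int[interior] < int[interior + 1]
  }
  side <- function(dir) {
    zone <- if (dir > 0) {
      which(rt > rt_apex + w & rt <= rt_apex + 1.5 * w)
    } else {
      which(rt < rt_apex - w & rt >= rt_apex - 1.5 * w)
    }
    if (length(zone) == 0L) {
      inside <- if (dir > 0) rt[rt <= rt_apex + w] else rt[rt >= rt_apex - w]
      return(if (dir > 0) max(inside) else min(inside))
    }
    zone <- zone[order(abs(rt[zone] - rt_apex))] # scan outward from t +/- w
    mins <- zone[is_local_min[zone]]
    if (length(mins) > 0) rt[mins[1]] else rt[zone[length(zone)]]
  }
  c(rt_left = side(-1L), rt_right = side(+1L))
}

#' Trapezoidal abundance of an EIC trace
#'
#' Sums the trapezoid areas between every two adjacent trace points:
#' `sum(0.5 * (I_k + I_(k+1)) * (rt_(k+1) - rt_k))`, in counts * minutes.
#'
#' @param trace Data frame with `rt` and `intensity` sorted by rt, at
#'   least 2 points.
#' @return Abundance (area units).
#' @export
integrate_abundance <- function(trace) {
  rt <- trace$rt
  int <- trace$intensity
  if (length(rt) < 2L) return(0)
  sum(0.5 * (int[-length(int)] + int[-1]) * diff(rt))
}

#' Detect chromatographic peaks in a run's signals
#'
#' Two-stage EIC construction iterated to exhaustion: greedy m/z clustering
#' from the most intense remaining signal, then FWHM-driven boundary
#' determination and trapezoidal integration. Cluster members falling
#' outside the final boundaries are released back to the unclustered pool,
#' so two compounds sharing an m/z but separated in RT are recovered on
#' later iterations. Gatherings below `min_members` signals, clusters
#' spanning fewer than 2 distinct RTs, and boundary-trimmed traces with
#' fewer than 2 points are consumed without producing a peak.
#'
#' @param signals An [ms_run] or data frame of denoised centroid signals
#'   (`scan_index`, `rt`, `mz`, `intensity`).
#' @param mzWidth m/z clustering tolerance in Th (default 0.02).
#' @param min_members Minimum cluster size (default 3).
#'
#' @return A `peak_list` tibble sorted by descending apex intensity with
#'   columns `peak_id`, `mz` (apex), `rt` (apex, minutes), `height`,
#'   `fwhm`, `rt_left`, `rt_right`, `abundance`, `n_points`, `charge`,
#'   `isotope_ratio` (charge/ratio 0 until [annotate_charges()]), and a
#'   `trace` list-column of the integrated (scan, rt, mz, intensity)
#'   points.
#' @export
detect_peaks <- function(signals, mzWidth = 0.02, min_members = 3) {
  rid <- if (inherits(signals, "ms_run")) attr(signals, "run_id") else NA_character_
  signals <- tibble::as_tibble(signals)
  state <- cluster_state(signals)
  peaks <- list()
  while (TRUE) {
    cl <- next_cluster(state, mzWidth)
    if (is.null(cl)) break
    if (length(cl$members) < min_members) {
      state$available[cl$members] <- FALSE
      next
    }
    trace <- member_trace(state, cl$members)
    if (length(unique(trace$rt)) < 2L) {
      state$available[cl$members] <- FALSE
      next
    }
    w <- compute_fwhm(trace)
    rt_apex <- state$rt[cl$seed]
    bounds <- determine_boundaries(trace, w, rt_apex)
    inside <- trace$rt >= bounds[1] & trace$rt <= bounds[2]
    member_ids <- cl$members[order(state$scan_index[cl$members])]
    state$available[member_ids[inside]] <- FALSE # outside members released
    trace <- trace[inside, ]
    if (nrow(trace) < 2L) next
    peaks[[length(peaks) + 1L]] <- tibble::tibble(
      mz = state$mz[cl$seed], rt = rt_apex,
      height = state$intensity[cl$seed], fwhm = w,
      rt_left = bounds[[1]], rt_right = bounds[[2]],
      abundance = integrate_abundance(trace), n_points = nrow(trace),
      trace = list(trace)
    )
  }
  res <- dplyr::bind_rows(peaks)
  if (nrow(res) == 0L) {
    res <- tibble::tibble(
      mz = numeric(0), rt = numeric(0), height = numeric(0), fwhm = numeric(0),
      rt_left = numeric(0), rt_right = numeric(0), abundance = numeric(0),
      n_points = integer(0), trace = list()
    )
  }
  res <- dplyr::arrange(res, dplyr::desc(.data$height), .data$mz)
  res <- tibble::add_column(res,
    peak_id = paste0("P", seq_len(nrow(res))), .before = 1
  )
  res$charge <- rep(0L, nrow(res))
  res$isotope_ratio <- rep(0, nrow(res))
  structure(res,
    class = c("peak_list", class(tibble::tibble())), run_id = rid
  )
}
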