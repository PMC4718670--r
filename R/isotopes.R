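#' Peak-shape similarity (normalized dot product)
#'
#' `sum(x*y) / (sqrt(sum(x^2)) * sqrt(sum(y^2)))` over the scans where two
#' peaks co-occur. Lies in \[0, 1\] for non-negative intensities and is
#' invariant to intensity scaling. Fewer than 2 paired scans, or a zero
#' vector, yields 0 (no envelope evidence).
#'
#' @param x,y Paired intensity vectors over the co-occurring scans.
#' @return Similarity in \[0, 1\].
#' @export
shape_similarity <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2L) return(0)
  nx <- sqrt(sum(x^2))
  ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) return(0)
  sum(x * y) / (nx * ny)
}

# similarity of two peak traces joined on scan index
trace_similarity <- function(t1, t2) {
  shared <- intersect(t1$scan_index, t2$scan_index)
  if (length(shared) < 2L) return(0)
  shape_similarity(
    t1$intensity[match(shared, t1$scan_index)],
    t2$intensity[match(shared, t2$scan_index)]
  )
}

#' Parameters for charge-state and isotope-ratio annotation
#'
#' @param similarity_threshold Minimum peak-shape similarity between the
#'   monoisotope and second isotope to confirm an envelope (default 0.8).
#' @param iso_mz_tol Tolerance (Th) on the 1/z isotope spacing; defaults to
#'   the mzWidth clustering tolerance (0.02).
#' @param rt_cooccurrence_tol Maximum apex RT difference (minutes) for a
#'   peak to count as a neighbouring isotope candidate (default 0.2).
#' @param max_charge Largest charge state considered (fixed 4).
#' @param max_isotopes Cap on the follower chain length (default 5).
#' @return A list of class `annotation_params`.
#' @export
annotation_params <- function(similarity_threshold = 0.8, iso_mz_tol = 0.02,
                              rt_cooccurrence_tol = 0.2, max_charge = 4L,
                              max_isotopes = 5L) {
  stopifnot(similarity_threshold > 0, similarity_threshold <= 1,
    iso_mz_tol > 0, rt_cooccurrence_tol > 0)
  structure(
    list(
      similarity_threshold = similarity_threshold, iso_mz_tol = iso_mz_tol,
      rt_cooccurrence_tol = rt_cooccurrence_tol,
      max_charge = as.integer(max_charge), max_isotopes = as.integer(max_isotopes)
    ),
    class = "annotation_params"
  )
}

#' Build the isotope-group hypothesis for a monoisotope candidate
#'
#' Candidate followers are peaks with larger m/z, apex RT within
#' `rt_cooccurrence_tol` of the mono apex, and strictly decreasing apex
#' intensities along the chain. For each charge z from `max_charge` down to
#' 1 the chain mono, f1, f2, ... is accepted when consecutive m/z gaps
#' equal `1/z` within `iso_mz_tol`; the highest viable z wins (the higher-z
#' spacing is the stricter pattern). When several peaks match a gap the
#' one nearest the expected m/z is taken.
#'
#' @param peaks A `peak_list` tibble.
#' @param mono_idx Row index of the monoisotope candidate in `peaks`.
#' @param candidate_idx Row indices eligible as followers.
#' @param params An [annotation_params()] list.
#'
#' @return `NULL` when no charge hypothesis fits, else a list with
#'   `charge` and `followers` (row indices ordered by ascending m/z).
#' @export
build_isotope_group <- function(peaks, mono_idx, candidate_idx,
                                params = annotation_params()) {
  mono_mz <- peaks$mz[mono_idx]
  cand <- candidate_idx[
    peaks$mz[candidate_idx] > mono_mz &
      abs(peaks$rt[candidate_idx] - peaks$rt[mono_idx]) <= params$rt_cooccurrence_tol
  ]
  if (length(cand) == 0L) return(NULL)
  for (z in seq(params$max_charge, 1L)) {
    chain <- integer(0)
    prev_int <- peaks$height[mono_idx]
    for (k in seq_len(params$max_isotopes)) {
      expected <- mono_mz + k / z
      hits <- cand[
        abs(peaks$mz[cand] - expected) <= params$iso_mz_tol &
          peaks$height[cand] < prev_int & !(cand %in% chain)
      ]
      if (length(hits) == 0L) break
      hit <- hits[which.min(abs(peaks$mz[hits] - expected))]
      chain <- c(chain, hit)
      prev_int <- peaks$height[hit]
    }
    if (length(chain) > 0L) return(list(charge = z, followers = chain))
  }
  NULL
}

#' Determine charge states, isotope ratios, and deisotope a peak list
#'
#' Iterates over peaks by descending apex intensity. For each unprocessed
#' peak a charge hypothesis is built with [build_isotope_group()]; the
#' envelope is confirmed when the shape similarity between the monoisotope
#' and second-isotope traces (over co-occurring scans) reaches
#' `similarity_threshold`. Confirmed monoisotopes receive the hypothesis
#' charge and an isotope ratio of `abundance(second) / abundance(mono)`,
#' and all grouped followers are removed from the list and from further
#' processing. Unconfirmed peaks keep charge 0 and ratio 0 and are
#' retained.
#'
#' @param peaks A `peak_list` from [detect_peaks()].
#' @param params An [annotation_params()] list.
#'
#' @return The deisotoped `peak_list`: annotated monoisotopes plus
#'   unassigned peaks, confirmed isotope followers removed, original
#'   descending-intensity order preserved.
#' @export
annotate_charges <- function(peaks, params = annotation_params()) {
  n <- nrow(peaks)
  if (n == 0L) return(peaks)
  ord <- order(-peaks$height, peaks$mz)
  processed <- rep(FALSE, n)
  removed <- rep(FALSE, n)
  charge <- rep(0L, n)
  ratio <- rep(0, n)
  for (i in ord) {
    if (processed[i] || removed[i]) next
    processed[i] <- TRUE
    cand <- which(!processed & !removed)
    grp <- build_isotope_group(peaks, i, cand, params)
    if (is.null(grp)) next
    second <- grp$followers[1]
    sim <- trace_similarity(peaks$trace[[i]], peaks$trace[[second]])
    if (sim >= params$similarity_threshold) {
      charge[i] <- grp$charge
      ratio[i] <- peaks$abundance[second] / peaks$abundance[i]
      removed[grp$followers] <- TRUE
      processed[grp$followers] <- TRUE
    }
  }
  out <- peaks[!removed, , drop = FALSE]
  out$charge <- charge[!removed]
  out$isotope_ratio <- ratio[!removed]
  out
}

#' Filter metabolite candidates by isotope ratio
#'
#' Keeps candidates whose theoretical second-isotope/monoisotope ratio lies
#' within `tol` of the observed ratio. Candidate tables come from upstream
#' formula-based computation (e.g. database searches); this tool only
#' applies the ratio filter.
#'
#' @param candidates Data frame with columns `id` and `theoretical_ratio`.
#' @param observed_ratio Isotope ratio measured for the peak.
#' @param tol Absolute tolerance (default 0.02).
#' @return The kept subset of `candidates`.
#' @export
filter_candidates_by_isotope_ratio <- function(candidates, observed_ratio,
                                               tol = 0.02) {
  stopifnot(all(c("id", "theoretical_ratio") %in% names(candidates)))
  candidates[abs(candidates$theoretical_ratio - observed_ratio) <= tol, ,
    drop = FALSE
  ]
}
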