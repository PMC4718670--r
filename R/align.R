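#' Alignment parameters
#'
#' @param mzTol m/z matching tolerance (Th, default 0.02).
#' @param rtTol Retention-time matching tolerance (minutes, default 0.2).
#' @param loess_span LOESS span as a fraction of landmark count (0.20).
#' @param min_landmarks Below this many landmarks the RT mapping falls back
#'   to identity (default 4).
#' @return A list of class `align_params`.
#' @export
align_params <- function(mzTol = 0.02, rtTol = 0.2, loess_span = 0.20,
                         min_landmarks = 4L) {
  stopifnot(mzTol > 0, rtTol > 0, loess_span > 0, loess_span <= 1)
  structure(
    list(
      mzTol = mzTol, rtTol = rtTol, loess_span = loess_span,
      min_landmarks = as.integer(min_landmarks)
    ),
    class = "align_params"
  )
}

#' Select the reference peak list
#'
#' The list with the largest number of detected peaks becomes the
#' reference; ties go to the first list in input order.
#'
#' @param peak_lists List of `peak_list` tibbles.
#' @return Index of the reference list.
#' @export
select_reference <- function(peak_lists) {
  sizes <- vapply(peak_lists, nrow, integer(1))
  if (all(sizes == 0L)) stop("cannot align: all peak lists are empty")
  which.max(sizes) # which.max takes the first maximum
}

#' Find landmark peak pairs between two peak lists
#'
#' Landmarks are peaks detected in both lists, i.e. pairs whose m/z and RT
#' differences fall within `mzTol` and `rtTol`. Matching is one-to-one and
#' greedy in descending reference-peak intensity; each reference peak takes
#' the unmatched target peak closest in |dRT| (ties: closest |dm/z|).
#'
#' @param ref,target `peak_list` tibbles.
#' @param params An [align_params()] list.
#' @return Tibble of landmarks with columns `ref_id`,
#'   `target_id`, `mz`, `ref_rt`, `target_rt`; attribute `fallback` is TRUE
#'   when fewer than `min_landmarks` pairs were found.
#' @export
find_landmarks <- function(ref, target, params = align_params()) {
  pairs <- greedy_match(
    ref$mz, ref$rt, ref$height, target$mz, target$rt,
    params$mzTol, params$rtTol
  )
  lm <- tibble::tibble(
    ref_id = ref$peak_id[pairs$ref], target_id = target$peak_id[pairs$target],
    mz = ref$mz[pairs$ref], ref_rt = ref$rt[pairs$ref],
    target_rt = target$rt[pairs$target]
  )
  attr(lm, "fallback") <- nrow(lm) < params$min_landmarks
  lm
}

# greedy one-to-one matching by descending reference intensity;
# returns integer index pairs
greedy_match <- function(ref_mz, ref_rt, ref_height, tgt_mz, tgt_rt,
                         mzTol, rtTol) {
  taken <- rep(FALSE, length(tgt_mz))
  ref_i <- integer(0)
  tgt_i <- integer(0)
  for (i in order(-ref_height)) {
    ok <- which(!taken & abs(tgt_mz - ref_mz[i]) <= mzTol &
      abs(tgt_rt - ref_rt[i]) <= rtTol)
    if (length(ok) == 0L) next
    drt <- abs(tgt_rt[ok] - ref_rt[i])
    dmz <- abs(tgt_mz[ok] - ref_mz[i])
    j <- ok[order(drt, dmz)][1]
    taken[j] <- TRUE
    ref_i <- c(ref_i, i)
    tgt_i <- c(tgt_i, j)
  }
  list(ref = ref_i, target = tgt_i)
}

#' Fit the LOESS retention-time mapping from landmarks
#'
#' Locally weighted regression (degree 1, tricube weights, span 0.20 of the
#' landmark count) of the RT offset `ref_rt - target_rt` on `target_rt`.
#' The mapping adjusts a target RT by its predicted offset; outside the
#' landmark RT range the offset is clamped to the nearest fitted value.
#' With fewer than `min_landmarks` landmarks the mapping is the identity.
#'
#' @param landmarks Tibble from [find_landmarks()].
#' @param params An [align_params()] list.
#' @return An object of class `rt_mapping`: call it as a function
#'   `mapping$adjust(rt)`; supports [generics::tidy()] and
#'   [generics::glance()].
#' @export
fit_rt_mapping <- function(landmarks, params = align_params()) {
  n <- nrow(landmarks)
  if (n < params$min_landmarks) {
    return(structure(
      list(adjust = identity, landmarks = landmarks, span = NA_real_,
        fallback = TRUE, fit = NULL),
      class = "rt_mapping"
    ))
  }
  # widen the span when landmarks are scarce so each local window holds
  # enough points for a degree-1 fit
  span <- if (n < 10) min(1, max(params$loess_span, 4 / n)) else params$loess_span
  df <- data.frame(
    x = landmarks$target_rt,
    offset = landmarks$ref_rt - landmarks$target_rt
  )
  fit <- stats::loess(offset ~ x, data = df, span = span, degree = 1,
    family = "gaussian",
    control = stats::loess.control(surface = "direct"))
  lo <- min(df$x)
  hi <- max(df$x)
  adjust <- function(rt) {
    rt + stats::predict(fit, data.frame(x = pmin(pmax(rt, lo), hi)))
  }
  structure(
    list(adjust = adjust, landmarks = landmarks, span = span,
      fallback = FALSE, fit = fit),
    class = "rt_mapping"
  )
}

#' @export
print.rt_mapping <- function(x, ...) {
  if (x$fallback) {
    cat("<rt_mapping> identity fallback (", nrow(x$landmarks), "landmarks )\n")
  } else {
    cat(sprintf(
      "<rt_mapping> LOESS on %d landmarks, span %.2f\n",
      nrow(x$landmarks), x$span
    ))
  }
  invisible(x)
}

#' Align a target peak list to a reference
#'
#' Adjusts the target's retention times through the fitted mapping, then
#' matches peaks one-to-one within `mzTol` and `rtTol` on adjusted RT.
#'
#' @param ref,target `peak_list` tibbles.
#' @param params An [align_params()] list.
#' @param mapping Optional prefitted [fit_rt_mapping()] result; computed
#'   from fresh landmarks when omitted.
#' @return List with `pairs` (tibble `ref_id`, `target_id`),
#'   `unmatched_ref`, `unmatched_target` (peak id vectors) and `target_rt_adj`
#'   (named by target peak id).
#' @export
align_pair <- function(ref, target, params = align_params(), mapping = NULL) {
  if (is.null(mapping)) {
    mapping <- fit_rt_mapping(find_landmarks(ref, target, params), params)
  }
  rt_adj <- mapping$adjust(target$rt)
  pairs <- greedy_match(
    ref$mz, ref$rt, ref$height, target$mz, rt_adj,
    params$mzTol, params$rtTol
  )
  list(
    pairs = tibble::tibble(
      ref_id = ref$peak_id[pairs$ref],
      target_id = target$peak_id[pairs$target]
    ),
    unmatched_ref = setdiff(ref$peak_id, ref$peak_id[pairs$ref]),
    unmatched_target = setdiff(target$peak_id, target$peak_id[pairs$target]),
    target_rt_adj = stats::setNames(rt_adj, target$peak_id)
  )
}

# Core multi-list aligner. `lists` is a named list of peak tibbles (peak_id,
# mz, rt, height, abundance, charge, isotope_ratio). Every non-reference
# list is landmark-mapped onto the reference; peaks then join the feature
# whose current representative is nearest (greedy by intensity, both
# tolerances), or found a new feature. Matching runs on LOESS-adjusted RTs;
# the constituent rows keep their raw RTs, so reported medians do not
# depend on which list happened to be the reference. Returns a tibble of
# features with a constituents list-column tagged by list name.
align_peak_tables <- function(lists, params) {
  ref_idx <- select_reference(lists)
  ref <- lists[[ref_idx]]
  tag <- function(tb, name, rt_adj) {
    tb$origin <- rep(name, nrow(tb))
    tb$rt_adj <- rt_adj
    tb
  }
  feats <- lapply(seq_len(nrow(ref)), function(i) {
    tag(ref[i, , drop = FALSE], names(lists)[ref_idx], ref$rt[i])
  })
  rep_mz <- ref$mz
  rep_rt <- ref$rt
  rep_height <- ref$height
  for (k in seq_along(lists)[-ref_idx]) {
    target <- lists[[k]]
    if (nrow(target) == 0L) next
    mapping <- fit_rt_mapping(find_landmarks(ref, target, params), params)
    rt_adj <- as.numeric(mapping$adjust(target$rt))
    pairs <- greedy_match(
      rep_mz, rep_rt, rep_height, target$mz, rt_adj,
      params$mzTol, params$rtTol
    )
    for (p in seq_along(pairs$ref)) {
      fi <- pairs$ref[p]
      j <- pairs$target[p]
      row <- tag(target[j, , drop = FALSE], names(lists)[k], rt_adj[j])
      feats[[fi]] <- dplyr::bind_rows(feats[[fi]], row)
    }
    new_idx <- setdiff(seq_len(nrow(target)), pairs$target)
    for (j in new_idx) {
      feats[[length(feats) + 1L]] <-
        tag(target[j, , drop = FALSE], names(lists)[k], rt_adj[j])
      rep_mz <- c(rep_mz, target$mz[j])
      rep_rt <- c(rep_rt, rt_adj[j])
      rep_height <- c(rep_height, target$height[j])
    }
    # refresh representatives of features that grew
    for (p in seq_along(pairs$ref)) {
      fi <- pairs$ref[p]
      rep_mz[fi] <- stats::median(feats[[fi]]$mz)
      rep_rt[fi] <- stats::median(feats[[fi]]$rt_adj)
    }
  }
  tibble::tibble(
    mz = vapply(feats, function(f) stats::median(f$mz), numeric(1)),
    rt = vapply(feats, function(f) stats::median(f$rt), numeric(1)),
    height = vapply(feats, function(f) stats::median(f$height), numeric(1)),
    constituents = lapply(feats, function(f) {
      tibble::as_tibble(f)[, setdiff(names(f), "rt_adj")]
    })
  )
}

#' Align technical replicates of one sample
#'
#' Aligns every replicate peak list to the reference replicate (the one
#' with most peaks) using landmark-based LOESS RT correction, assembles
#' features, and represents each feature by the median m/z and RT of its
#' constituent replicate peaks. Features present in only a subset of
#' replicates are kept.
#'
#' @param peak_lists Named list of deisotoped `peak_list` tibbles, one per
#'   replicate (names are replicate labels).
#' @param params An [align_params()] list.
#' @return Tibble of representative peaks: `mz`, `rt`, `height`, and a
#'   `constituents` list-column (one row per contributing replicate with
#'   `origin` = replicate label, abundance, charge, isotope ratio).
#' @export
align_replicates <- function(peak_lists, params = align_params()) {
  if (is.null(names(peak_lists))) {
    names(peak_lists) <- paste0("R", seq_along(peak_lists))
  }
  cols <- c("peak_id", "mz", "rt", "height", "abundance", "charge", "isotope_ratio")
  lists <- lapply(peak_lists, function(pl) tibble::as_tibble(pl)[, cols])
  align_peak_tables(lists, params)
}

#' Align representative peaks across samples
#'
#' Applies the replicate-level machinery one level up: each sample's
#' representative peaks (from [align_replicates()]) are aligned across
#' samples, and each aligned feature keeps the per-sample, per-replicate
#' abundance map of its constituents.
#'
#' @param sample_reps Named list (sample label -> [align_replicates()]
#'   output).
#' @param params An [align_params()] list.
#' @return A `feature_table` tibble: `feature_id`, `mz`, `rt` (medians over
#'   all constituent replicate peaks), and a `constituents` list-column
#'   with columns `sample`, `replicate`, `mz`, `rt`, `abundance`, `charge`,
#'   `isotope_ratio`.
#' @export
align_samples <- function(sample_reps, params = align_params()) {
  stopifnot(!is.null(names(sample_reps)))
  lists <- lapply(names(sample_reps), function(s) {
    reps <- sample_reps[[s]]
    tibble::tibble(
      peak_id = paste0(s, ".", seq_len(nrow(reps))),
      mz = reps$mz, rt = reps$rt, height = reps$height,
      constituents = reps$constituents
    )
  })
  names(lists) <- names(sample_reps)
  merged <- align_peak_tables(lists, params)
  cons <- lapply(merged$constituents, function(f) {
    parts <- lapply(seq_len(nrow(f)), function(i) {
      cc <- f$constituents[[i]]
      tibble::tibble(
        sample = f$origin[i], replicate = cc$origin, mz = cc$mz, rt = cc$rt,
        abundance = cc$abundance, charge = cc$charge,
        isotope_ratio = cc$isotope_ratio
      )
    })
    dplyr::bind_rows(parts)
  })
  out <- tibble::tibble(
    feature_id = paste0("F", seq_len(nrow(merged))),
    mz = vapply(cons, function(cc) stats::median(cc$mz), numeric(1)),
    rt = vapply(cons, function(cc) stats::median(cc$rt), numeric(1)),
    constituents = cons
  )
  structure(out, class = c("feature_table", class(tibble::tibble())))
}
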