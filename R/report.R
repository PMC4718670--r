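#' Summarize aligned features for reporting
#'
#' For every aligned feature: the reported m/z and RT are medians over all
#' constituent replicate peaks; each sample abundance is the median of that
#' sample's replicate abundances (replicates in which the feature was not
#' detected are excluded from the median, not imputed as zero); the
#' reported charge is the state detected in most replicates (ties broken
#' toward the higher charge, with 0 losing to any nonzero state); the
#' reported isotope ratio is the median over the constituents whose charge
#' equals the reported charge.
#'
#' @param features A `feature_table` from [align_samples()].
#' @param layout Optional named list `sample -> replicate labels` fixing
#'   the full column layout; derived from the constituents when omitted.
#'
#' @return A summarized tibble with columns `feature_id`, `mz`, `rt_min`,
#'   `charge`, `isotope_ratio`, `n_samples_detected`, one column per
#'   replicate (`<sample>/<replicate>`, NA when absent), one median column
#'   per sample, and the carried-over `constituents`.
#' @export
summarize_features <- function(features, layout = NULL) {
  cons_all <- dplyr::bind_rows(features$constituents)
  if (is.null(layout)) {
    layout <- lapply(
      split(cons_all$replicate, cons_all$sample),
      function(x) sort(unique(x))
    )
  }
  samples <- names(layout)
  rep_cols <- unlist(lapply(samples, function(s) paste(s, layout[[s]], sep = "/")))
  rows <- lapply(seq_len(nrow(features)), function(i) {
    cc <- features$constituents[[i]]
    ab <- stats::setNames(
      rep(NA_real_, length(rep_cols)), rep_cols
    )
    ab[paste(cc$sample, cc$replicate, sep = "/")] <- cc$abundance
    sample_med <- vapply(samples, function(s) {
      v <- cc$abundance[cc$sample == s]
      if (length(v) == 0L) NA_real_ else stats::median(v)
    }, numeric(1))
    ch <- majority_charge(cc$charge)
    iso <- cc$isotope_ratio[cc$charge == ch]
    tibble::tibble(
      feature_id = features$feature_id[i],
      mz = stats::median(cc$mz), rt_min = stats::median(cc$rt),
      charge = ch,
      isotope_ratio = if (length(iso)) stats::median(iso) else 0,
      n_samples_detected = length(unique(cc$sample)),
      !!!as.list(ab), !!!as.list(stats::setNames(sample_med, samples))
    )
  })
  out <- dplyr::bind_rows(rows)
  out$constituents <- features$constituents
  out
}

# charge detected in most replicates; tie -> higher charge; 0 loses to any
# nonzero state on a tie
majority_charge <- function(charges) {
  tab <- table(charges)
  ch <- as.integer(names(tab))
  best <- max(tab)
  cand <- ch[tab == best]
  if (length(cand) > 1 && any(cand > 0)) cand <- cand[cand > 0]
  as.integer(max(cand))
}

#' Filter a summarized feature table
#'
#' Keeps features satisfying every active criterion; inactive (`NULL`)
#' criteria impose nothing. Detection count is the number of samples with
#' at least one constituent replicate peak.
#'
#' @param features Summarized tibble from [summarize_features()].
#' @param rt_range,mz_range Numeric `c(min, max)` or `NULL`.
#' @param min_samples_detected Minimum number of samples in which the
#'   feature was detected (default 1).
#' @param charges Integer vector of allowed charge states, or `NULL`.
#' @param isotope_ratio_range Numeric `c(min, max)` or `NULL`.
#' @return The kept subset, same columns; idempotent.
#' @export
apply_filters <- function(features, rt_range = NULL, mz_range = NULL,
                          min_samples_detected = 1, charges = NULL,
                          isotope_ratio_range = NULL) {
  keep <- rep(TRUE, nrow(features))
  in_range <- function(x, r) x >= r[1] & x <= r[2]
  if (!is.null(rt_range)) keep <- keep & in_range(features$rt_min, rt_range)
  if (!is.null(mz_range)) keep <- keep & in_range(features$mz, mz_range)
  if (!is.null(charges)) keep <- keep & features$charge %in% charges
  if (!is.null(isotope_ratio_range)) {
    keep <- keep & in_range(features$isotope_ratio, isotope_ratio_range)
  }
  keep <- keep & features$n_samples_detected >= min_samples_detected
  features[keep, , drop = FALSE]
}
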