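#' LC-MS1 run container
#'
#' An `ms_run` is a tibble of signal points — one row per (m/z, intensity)
#' pair — with columns `scan_index`, `rt` (minutes), `mz` (Th) and
#' `intensity` (counts), carrying run-level metadata as attributes:
#' `run_id`, `mode` (`"profile"`, `"centroid"` or `"mixed"`), `source_path`
#' and a `scans` tibble (`scan_index`, `rt`, `centroided`) listing every MS1
#' scan, including scans that contributed no points.
#'
#' @param signals Data frame with columns `scan_index`, `rt`, `mz`,
#'   `intensity`. Retention times are minutes; rows for one scan must share
#'   one `rt`.
#' @param scans Optional tibble of per-scan metadata (`scan_index`, `rt`,
#'   `centroided`); derived from `signals` when omitted.
#' @param run_id Identifier for the run; defaults to `"run"`.
#' @param mode `"profile"`, `"centroid"`, `"mixed"` or `NA` (unknown).
#' @param source_path File the run was read from, if any.
#'
#' @return A tibble of class `ms_run`.
#' @export
ms_run <- function(signals, scans = NULL, run_id = "run", mode = NA_character_,
                   source_path = NA_character_) {
  signals <- tibble::as_tibble(signals)[, c("scan_index", "rt", "mz", "intensity")]
  stopifnot(all(signals$intensity >= 0), all(signals$mz > 0), all(signals$rt >= 0))
  signals <- dplyr::arrange(signals, .data$rt, .data$mz)
  if (is.null(scans)) {
    scans <- dplyr::distinct(signals, .data$scan_index, .data$rt)
    scans$centroided <- NA
  }
  scans <- dplyr::arrange(tibble::as_tibble(scans), .data$rt)
  if (anyDuplicated(scans$rt) > 0) {
    stop("scan retention times must be strictly increasing (ties forbidden)")
  }
  if (anyDuplicated(scans$scan_index) > 0) stop("duplicated scan_index in run")
  structure(signals,
    class = c("ms_run", class(tibble::tibble())),
    run_id = run_id, mode = mode, source_path = source_path, scans = scans
  )
}

#' @rdname ms_run
#' @param x An `ms_run`.
#' @export
run_scans <- function(x) attr(x, "scans")

#' @rdname ms_run
#' @export
run_mode <- function(x) attr(x, "mode")

#' @rdname ms_run
#' @export
run_id <- function(x) attr(x, "run_id")

#' @export
print.ms_run <- function(x, ...) {
  cat(sprintf(
    "<ms_run '%s'> %d signals in %d scans, mode: %s\n",
    attr(x, "run_id"), nrow(x), nrow(run_scans(x)), attr(x, "mode")
  ))
  NextMethod()
}

# rebuild an ms_run around new signal rows, keeping metadata
replace_signals <- function(run, signals) {
  ms_run(signals,
    scans = run_scans(run), run_id = attr(run, "run_id"),
    mode = attr(run, "mode"), source_path = attr(run, "source_path")
  )
}
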