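#' Read an LC-MS1 run from mzML or mzXML
#'
#' Reads every MS1 spectrum of a run into an [ms_run] tibble of signal
#' points. MSn (n > 1) spectra are skipped. Retention times are converted
#' to minutes. The acquisition mode is taken from the per-spectrum
#' centroided flag when the file declares it, otherwise inferred by
#' [detect_mode()].
#'
#' @param path Path to an mzML (1.1.x) or mzXML (3.x) file.
#' @param run_id Run identifier; defaults to the file name without extension.
#'
#' @return An [ms_run] with scans strictly ordered by retention time.
#' @export
read_run <- function(path, run_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(run_id)) run_id <- sub("\\.[^.]+$", "", basename(path))
  ms <- tryCatch(mzR::openMSfile(path),
    error = function(e) stop("cannot parse '", path, "' as mzML/mzXML: ",
      conditionMessage(e), call. = FALSE)
  )
  on.exit(mzR::close(ms), add = TRUE)
  hdr <- mzR::header(ms)
  ms1 <- which(hdr$msLevel == 1L)
  if (length(ms1) == 0L) stop("no MS1 spectra in '", path, "'")
  hdr <- hdr[ms1, , drop = FALSE]
  pk <- mzR::peaks(ms, ms1)
  if (is.matrix(pk)) pk <- list(pk)
  scans <- tibble::tibble(
    scan_index = hdr$acquisitionNum,
    rt = hdr$retentionTime / 60,
    centroided = as.logical(hdr$centroided)
  )
  npts <- vapply(pk, nrow, integer(1))
  signals <- tibble::tibble(
    scan_index = rep(scans$scan_index, npts),
    rt = rep(scans$rt, npts),
    mz = unlist(lapply(pk, function(m) m[, 1]), use.names = FALSE),
    intensity = unlist(lapply(pk, function(m) m[, 2]), use.names = FALSE)
  )
  run <- ms_run(signals, scans = scans, run_id = run_id, source_path = path)
  attr(run, "mode") <- detect_mode(run)
  run
}

#' Decide whether a run is profile or centroid mode
#'
#' Uses the per-scan centroided declaration when present. For undeclared
#' scans a spacing heuristic is applied: a scan is called profile when it
#' carries runs of at least 5 contiguous above-zero points whose median m/z
#' gap is below `mzWidth / 4`, i.e. the points are far denser than the
#' m/z clustering tolerance — the signature of continuum sampling.
#'
#' @param run An [ms_run] with at least one non-empty scan.
#' @param mzWidth m/z clustering tolerance (Th) used to scale the density
#'   heuristic; default 0.02.
#'
#' @return `"profile"`, `"centroid"`, or `"mixed"` when scans disagree.
#' @export
detect_mode <- function(run, mzWidth = 0.02) {
  scans <- run_scans(run)
  sig <- tibble::as_tibble(run)
  if (nrow(sig) == 0L) stop("cannot determine mode: all scans are empty")
  per_scan <- vapply(seq_len(nrow(scans)), function(i) {
    decl <- scans$centroided[i]
    if (isTRUE(decl)) return("centroid")
    if (isFALSE(decl)) return("profile")
    pts <- sig[sig$scan_index == scans$scan_index[i], ]
    if (nrow(pts) == 0L) return(NA_character_)
    scan_mode_heuristic(pts$mz, pts$intensity, mzWidth)
  }, character(1))
  per_scan <- per_scan[!is.na(per_scan)]
  if (length(per_scan) == 0L) stop("cannot determine mode: all scans are empty")
  modes <- unique(per_scan)
  if (length(modes) == 1L) modes else "mixed"
}

scan_mode_heuristic <- function(mz, intensity, mzWidth) {
  nz <- intensity > 0
  grp <- cumsum(c(TRUE, diff(nz) != 0))
  gaps <- unlist(lapply(split(seq_along(mz), grp), function(idx) {
    if (!nz[idx[1]] || length(idx) < 2) return(numeric(0))
    diff(mz[idx])
  }), use.names = FALSE)
  long_run <- any(vapply(split(seq_along(mz), grp),
    function(idx) nz[idx[1]] && length(idx) >= 5, logical(1)
  ))
  if (length(gaps) > 0 && stats::median(gaps) < mzWidth / 4 && long_run) {
    "profile"
  } else {
    "centroid"
  }
}

#' Write a quantitation table to csv or tab-separated txt
#'
#' One row per aligned feature with columns `feature_id`, `mz`, `rt_min`,
#' `charge`, `isotope_ratio`, one abundance column per replicate named
#' `<sample>/<replicate>`, then one median-abundance column per sample named
#' `<sample>`. Replicates in which a feature was not detected are rendered
#' as 0. Numeric fields carry at least 6 significant digits.
#'
#' @param features Summarized feature table from [summarize_features()].
#' @param path Output file path.
#' @param format `"csv"` (comma) or `"txt"` (tab).
#'
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(features, path, format = c("csv", "txt")) {
  format <- match.arg(format)
  tab <- quant_export_frame(features)
  out <- as.data.frame(lapply(tab, function(col) {
    if (is.numeric(col) && !is.integer(col)) sprintf("%.8g", col) else col
  }), check.names = FALSE, stringsAsFactors = FALSE)
  ok <- tryCatch({
    utils::write.table(out, path,
      sep = if (format == "csv") "," else "\t",
      quote = FALSE, row.names = FALSE, col.names = TRUE
    )
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write quantitation table to '", path, "'")
  invisible(path)
}

# flatten a summarized feature table to the export column contract
quant_export_frame <- function(features) {
  stopifnot(is.data.frame(features))
  base_cols <- c("feature_id", "mz", "rt_min", "charge", "isotope_ratio")
  rep_cols <- grep("/", names(features), fixed = TRUE, value = TRUE)
  sample_cols <- setdiff(names(features), c(base_cols, rep_cols, "constituents",
    "n_samples_detected"))
  tab <- features[, c(base_cols, rep_cols, sample_cols), drop = FALSE]
  for (cc in c(rep_cols, sample_cols)) {
    tab[[cc]][is.na(tab[[cc]])] <- 0
  }
  tab
}
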