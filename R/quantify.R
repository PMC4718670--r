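#' Quantify a set of in-memory LC-MS1 runs
#'
#' Runs the full label-free pipeline on already-loaded runs: centroid
#' profile scans, remove noise, detect peaks, determine charge states and
#' isotope ratios, align replicates within each sample and representative
#' peaks across samples, then summarize and filter.
#'
#' @param runs Named nested list: `sample -> replicate -> ms_run`.
#' @param mzWidth m/z clustering tolerance for peak detection (Th).
#' @param noise An [noise settings] list: `n_segments`, `overlap_fraction`,
#'   `snr_threshold` (see [remove_noise()]).
#' @param annotation An [annotation_params()] list.
#' @param align An [align_params()] list (carries mzTol and rtTol).
#' @param filters Named list of [apply_filters()] arguments, or `NULL`.
#' @param force_centroiding Centroid even scans declared centroid mode.
#' @param verbose Print per-replicate peak counts.
#'
#' @return The summarized, filtered feature tibble (see
#'   [summarize_features()]), with the per-replicate `peak_lists` attached
#'   as an attribute.
#' @export
quantify_runs <- function(runs, mzWidth = 0.02,
                          noise = list(n_segments = 10, overlap_fraction = 0.2,
                            snr_threshold = 3),
                          annotation = annotation_params(iso_mz_tol = mzWidth),
                          align = align_params(),
                          filters = NULL, force_centroiding = FALSE,
                          verbose = FALSE) {
  stopifnot(length(runs) >= 1, !is.null(names(runs)))
  peak_lists <- list()
  sample_reps <- list()
  for (s in names(runs)) {
    stopifnot(length(runs[[s]]) >= 1)
    reps <- lapply(runs[[s]], function(run) {
      if (force_centroiding || !identical(run_mode(run), "centroid")) {
        run <- centroid_run(run, mzWidth)
      }
      run <- denoise_run(run, noise$n_segments, noise$overlap_fraction,
        noise$snr_threshold)
      pl <- detect_peaks(run, mzWidth)
      annotate_charges(pl, annotation)
    })
    if (verbose) {
      for (r in names(reps)) {
        message(sprintf("%s/%s: %d deisotoped peaks", s, r, nrow(reps[[r]])))
      }
    }
    peak_lists[[s]] <- reps
    sample_reps[[s]] <- align_replicates(reps, align)
  }
  features <- align_samples(sample_reps, align)
  layout <- lapply(runs, names)
  summary <- summarize_features(features, layout = layout)
  if (!is.null(filters)) {
    summary <- do.call(apply_filters, c(list(summary), filters))
  }
  attr(summary, "peak_lists") <- peak_lists
  summary
}

#' Read a quantitation configuration file
#'
#' YAML with a `samples` map (sample label -> list of replicate file
#' paths), the three core tolerances (`mzWidth`, `mzTol`, `rtTol`) and
#' optional keys `segments`, `snr`, `similarity`, `iso_mz_tol`,
#' `rt_min`, `rt_max`, `min_samples`, `out`, `format`.
#'
#' @param path YAML file path.
#' @return Validated config list for [run_quantify()].
#' @export
read_quant_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_quant_config(cfg)
}

#' @rdname read_quant_config
#' @param cfg Config list to validate.
#' @export
validate_quant_config <- function(cfg) {
  if (is.null(cfg$samples) || length(cfg$samples) < 1) {
    stop("config error at 'samples': at least one sample is required")
  }
  for (s in names(cfg$samples)) {
    if (length(cfg$samples[[s]]) < 1) {
      stop("config error at 'samples/", s, "': at least one replicate path")
    }
  }
  defaults <- list(
    mzWidth = 0.02, mzTol = 0.02, rtTol = 0.2, segments = 10, snr = 3,
    similarity = 0.8, format = "csv", min_samples = 1
  )
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  for (k in c("mzWidth", "mzTol", "rtTol")) {
    if (cfg[[k]] <= 0) stop("config error at '", k, "': must be > 0")
  }
  cfg
}

#' Run the end-to-end quantitation workflow from a configuration
#'
#' Reads every replicate file, executes [quantify_runs()], and writes the
#' quantitation table when `out` is set in the config.
#'
#' @param config Config list (see [read_quant_config()]) or a path to a
#'   YAML config file.
#' @param verbose Log parameters and per-replicate peak counts.
#' @return The summarized feature tibble, invisibly when `out` is written.
#' @export
run_quantify <- function(config, verbose = TRUE) {
  if (is.character(config)) config <- read_quant_config(config)
  config <- validate_quant_config(config)
  if (verbose) {
    message(sprintf(
      "parameters: mzWidth=%g mzTol=%g rtTol=%g segments=%d snr=%g similarity=%g",
      config$mzWidth, config$mzTol, config$rtTol, config$segments,
      config$snr, config$similarity
    ))
  }
  runs <- lapply(config$samples, function(paths) {
    rl <- lapply(paths, read_run)
    names(rl) <- paste0("R", seq_along(rl))
    rl
  })
  filters <- NULL
  if (!is.null(config$rt_min) || !is.null(config$rt_max)) {
    filters <- list(rt_range = c(
      config$rt_min %||% 0, config$rt_max %||% Inf
    ))
  }
  filters <- c(filters, list(min_samples_detected = config$min_samples))
  iso_tol <- config$iso_mz_tol %||% config$mzWidth
  res <- quantify_runs(runs,
    mzWidth = config$mzWidth,
    noise = list(n_segments = config$segments, overlap_fraction = 0.2,
      snr_threshold = config$snr),
    annotation = annotation_params(
      similarity_threshold = config$similarity, iso_mz_tol = iso_tol,
      rt_cooccurrence_tol = config$rtTol
    ),
    align = align_params(mzTol = config$mzTol, rtTol = config$rtTol),
    filters = filters, verbose = verbose
  )
  if (!is.null(config$out)) {
    write_quant_table(res, config$out, config$format)
    if (verbose) message("wrote ", config$out)
    return(invisible(res))
  }
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
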