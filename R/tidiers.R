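#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an RT mapping: one row per landmark
#'
#' @param x An `rt_mapping` from [fit_rt_mapping()].
#' @param ... Unused.
#' @return Tibble with landmark RTs, observed and fitted offsets, and
#'   residuals (minutes).
#' @method tidy rt_mapping
#' @export
tidy.rt_mapping <- function(x, ...) {
  lm <- x$landmarks
  offset <- lm$ref_rt - lm$target_rt
  fitted <- as.numeric(x$adjust(lm$target_rt)) - lm$target_rt
  tibble::tibble(
    mz = lm$mz, ref_rt = lm$ref_rt, target_rt = lm$target_rt,
    offset = offset, fitted_offset = fitted, residual = offset - fitted
  )
}

#' @rdname tidy.rt_mapping
#' @method glance rt_mapping
#' @export
glance.rt_mapping <- function(x, ...) {
  td <- tidy(x)
  tibble::tibble(
    n_landmarks = nrow(td), span = x$span, fallback = x$fallback,
    rmse = if (nrow(td)) sqrt(mean(td$residual^2)) else NA_real_,
    max_abs_offset = if (nrow(td)) max(abs(td$offset)) else NA_real_
  )
}

#' Tidy a peak list: drop the trace column
#'
#' @param x A `peak_list` from [detect_peaks()].
#' @param ... Unused.
#' @return Plain tibble of per-peak scalars.
#' @method tidy peak_list
#' @export
tidy.peak_list <- function(x, ...) {
  tibble::as_tibble(x)[, setdiff(names(x), "trace")]
}

#' @rdname tidy.peak_list
#' @method glance peak_list
#' @export
glance.peak_list <- function(x, ...) {
  tibble::tibble(
    n_peaks = nrow(x),
    n_charged = sum(x$charge > 0),
    total_abundance = sum(x$abundance),
    rt_min = if (nrow(x)) min(x$rt) else NA_real_,
    rt_max = if (nrow(x)) max(x$rt) else NA_real_
  )
}

#' Plot extracted ion chromatograms of a peak list
#'
#' Draws the integrated trace of the `n_top` most abundant peaks with
#' dashed apex markers and shaded integration boundaries.
#'
#' @param object A `peak_list`.
#' @param n_top Number of peaks to draw (default 12).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot peak_list
#' @export
autoplot.peak_list <- function(object, n_top = 12, ...) {
  pk <- object[order(-object$abundance), ]
  pk <- pk[seq_len(min(n_top, nrow(pk))), ]
  df <- dplyr::bind_rows(stats::setNames(pk$trace, pk$peak_id), .id = "peak_id")
  lab <- sprintf("%s m/z %.4f", pk$peak_id, pk$mz)
  df$label <- factor(lab[match(df$peak_id, pk$peak_id)], levels = lab)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rt, y = .data$intensity)) +
    ggplot2::geom_area(alpha = 0.3, fill = "steelblue") +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_vline(
      data = tibble::tibble(label = factor(lab, levels = lab), rt = pk$rt),
      ggplot2::aes(xintercept = .data$rt), linetype = "dashed", linewidth = 0.3
    ) +
    ggplot2::facet_wrap(~label, scales = "free") +
    ggplot2::labs(x = "retention time (min)", y = "intensity (counts)") +
    ggplot2::theme_minimal()
}

#' Plot an RT mapping: landmark offsets and the fitted LOESS curve
#'
#' @param object An `rt_mapping`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rt_mapping
#' @export
autoplot.rt_mapping <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$target_rt)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$offset), alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted_offset), color = "firebrick") +
    ggplot2::labs(
      x = "retention time in aligning list (min)",
      y = "RT offset to reference (min)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-sample abundances of summarized features
#'
#' @param object Summarized feature tibble from [summarize_features()].
#' @param n_top Number of most abundant features to draw (default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_feature_abundances <- function(object, n_top = 20, ...) {
  cons <- dplyr::bind_rows(
    stats::setNames(object$constituents, object$feature_id),
    .id = "feature_id"
  )
  totals <- vapply(
    split(cons$abundance, cons$feature_id), sum, numeric(1)
  )
  keep <- names(sort(totals, decreasing = TRUE))[seq_len(min(n_top, length(totals)))]
  cons <- cons[cons$feature_id %in% keep, ]
  ggplot2::ggplot(cons, ggplot2::aes(
    x = .data$feature_id, y = .data$abundance, color = .data$sample
  )) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "abundance (counts x min)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
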