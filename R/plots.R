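#' Manhattan-style plot of a segregation-distortion scan
#'
#' Plots `-log10(p)` per marker along the map, faceted by chromosome, with
#' the significance threshold drawn as a horizontal guide. Requires the scan
#' to have been annotated with a map.
#'
#' @param object A `wba_distortion` result (with `chromosome`,
#'   `position_cM`).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.wba_distortion <- function(object, ...) {
  if (!"chromosome" %in% names(object)) {
    abort("distortion scan lacks map positions; rerun distortion_scan() with a map")
  }
  alpha <- attr(object, "alpha") %||% 0.005
  ggplot2::ggplot(object, ggplot2::aes(.data$position_cM, .data$neglog10_p)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant), size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$chromosome), scales = "free_x") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey40"),
                                 guide = "none") +
    ggplot2::labs(x = "Position (cM)", y = expression(-log[10](italic(p))))
}

#' Principal coordinate plot
#'
#' @param object A `wba_pcoa`.
#' @param metadata Optional sample metadata joined by `sample_id`.
#' @param colour Column of `metadata` to colour points by.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.wba_pcoa <- function(object, metadata = NULL, colour = "collection", ...) {
  pts <- object$points
  aes <- ggplot2::aes(.data$Axis1, .data$Axis2)
  if (!is.null(metadata)) {
    pts <- dplyr::left_join(pts, metadata, by = "sample_id")
    aes <- ggplot2::aes(.data$Axis1, .data$Axis2, colour = .data[[colour]])
  }
  ggplot2::ggplot(pts, aes) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "PCo1", y = "PCo2")
}

#' Log2R copy-number profile plot
#'
#' Raw Log2R points with the smoothed track overlaid, faceted by
#' chromosome.
#'
#' @param object A `wba_cnv_profile`.
#' @param calls Optional [call_cnv()] output to shade called segments.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.wba_cnv_profile <- function(object, calls = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$cM, .data$log2r)) +
    ggplot2::geom_point(size = 0.5, alpha = 0.4, colour = "grey50") +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed), colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::facet_wrap(ggplot2::vars(.data$chromosome), scales = "free_x") +
    ggplot2::labs(x = "Position (cM)", y = expression(Log[2] * R),
                  title = attr(object, "sample_id"))
  if (!is.null(calls) && nrow(calls)) {
    p <- p + ggplot2::geom_rect(
      data = calls,
      ggplot2::aes(xmin = .data$start_cM, xmax = .data$end_cM,
                   ymin = -Inf, ymax = Inf, fill = .data$direction),
      alpha = 0.15, inherit.aes = FALSE
    ) +
      ggplot2::scale_fill_manual(values = c(loss = "firebrick", gain = "royalblue"))
  }
  p
}

#' Minor-allele-frequency distribution plot
#'
#' Histogram of per-marker MAF within each collection.
#'
#' @param freq Output of [allele_frequencies()].
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
plot_maf_distribution <- function(freq, bins = 20) {
  freq %>%
    dplyr::filter(.data$collection != ".pooled", !is.na(.data$maf)) %>%
    ggplot2::ggplot(ggplot2::aes(.data$maf)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", colour = "white") +
    ggplot2::facet_wrap(ggplot2::vars(.data$collection), scales = "free_y") +
    ggplot2::labs(x = "Minor allele frequency", y = "Markers")
}

#' Rarefaction curve plot
#'
#' @param rarefaction Output of [polymorphism_rarefaction()].
#' @return A ggplot object.
#' @export
plot_rarefaction <- function(rarefaction) {
  ggplot2::ggplot(rarefaction,
                  ggplot2::aes(.data$size, .data$mean_pct_P,
                               colour = .data$collection)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean_pct_P - .data$sd_pct_P,
                                          ymax = .data$mean_pct_P + .data$sd_pct_P),
                             size = 0.2) +
    ggplot2::labs(x = "Subsample size", y = "% polymorphic markers")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
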