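#' Z-score landscape along the reporter
#'
#' Plots each guide's combined Z against its anchor position (the 5'-most
#' target base, paired by the spacer 3' end), one panel per spacer length,
#' with hits highlighted. Positive Z means splicing activation.
#'
#' @param results A `screen_results` object (analyzed with a library, so
#'   positions are available) or an annotated combined tibble.
#' @param fdr_threshold Threshold used for highlighting (display only).
#' @return A ggplot object.
#' @export
plot_z_landscape <- function(results, fdr_threshold = 0.01) {
  if (inherits(results, "screen_results")) results <- results$combined
  stopifnot(all(c("position", "Z", "length") %in% names(results)))
  dat <- dplyr::filter(results, !is.na(.data$position), !is.na(.data$Z))
  dat$hit <- !is.na(dat$fdr) & dat$fdr <= fdr_threshold
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$position, y = .data$Z)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$hit), size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick"),
                                 name = paste0("FDR <= ", fdr_threshold)) +
    ggplot2::facet_wrap(~length, ncol = 1,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "reporter position (nt)", y = "combined Z",
                  title = "Splicing-modulation landscape") +
    ggplot2::theme_bw()
}

#' @method autoplot screen_results
#' @export
autoplot.screen_results <- function(object, ...) {
  plot_z_landscape(object, ...)
}

#' MA-contour plot of flow-cytometry events
#'
#' Density contours of the per-event log-ratio M (relative exon inclusion)
#' against mean log-intensity A.
#'
#' @param events Event tibble with `M` and `A` columns (from
#'   [psi_log_ratio()]), or the list returned by it.
#' @return A ggplot object.
#' @export
plot_ma_contour <- function(events) {
  if (is.list(events) && !is.data.frame(events)) events <- events$events
  stopifnot(all(c("M", "A") %in% names(events)))
  ggplot2::ggplot(events, ggplot2::aes(x = .data$A, y = .data$M)) +
    ggplot2::geom_density_2d(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = stats::median(events$M),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "A = mean log2 intensity",
                  y = "M = log2(tdTomato / eGFP)") +
    ggplot2::theme_bw()
}

#' Per-shift R-squared of the spacer-length comparison
#'
#' @param shift_summary Tibble from [shift_correlation()] (`summary`
#'   element), or the whole list.
#' @return A ggplot object.
#' @export
plot_shift_r2 <- function(shift_summary) {
  if (is.list(shift_summary) && !is.data.frame(shift_summary)) {
    shift_summary <- shift_summary$summary
  }
  ggplot2::ggplot(shift_summary,
                  ggplot2::aes(x = factor(.data$shift), y = .data$r2)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "shift (nt, spacer 5' end)",
                  y = expression(R^2),
                  title = "25-nt vs 22-nt guide Z-score concordance") +
    ggplot2::theme_bw()
}
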