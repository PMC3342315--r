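#' Plot a TSS-relative binding histogram
#'
#' @param object A `binding_histogram` from [tss_histogram()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.binding_histogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_mid, y = .data$count)) +
    ggplot2::geom_col(width = unique(object$bin_end - object$bin_start)[1],
                      fill = "steelblue") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Position relative to TSS (bp)",
                  y = "Binding events") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.binding_histogram
#' @param hist A `binding_histogram`.
#' @export
plot_binding_histogram <- function(hist, ...) autoplot.binding_histogram(hist, ...)

#' Histogram of peak-to-motif distances
#'
#' @param distances Tibble from [closest_motif_distances()].
#' @param binwidth Bin width in bp (default 25).
#' @return A ggplot.
#' @export
plot_motif_distances <- function(distances, binwidth = 25) {
  ggplot2::ggplot(distances, ggplot2::aes(x = .data$distance)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "darkorange",
                            color = "white") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Peak center to closest motif (bp)", y = "Regions") +
    ggplot2::theme_minimal()
}

#' Volcano plot of a differential-expression result
#'
#' @param de A [de_test()] tibble.
#' @return A ggplot.
#' @export
plot_de_volcano <- function(de) {
  ggplot2::ggplot(de, ggplot2::aes(x = .data$lfc, y = -log10(.data$fdr),
                                   color = .data$reg_class)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_color_manual(values = c(down = "firebrick",
                                           up = "dodgerblue",
                                           unchanged = "grey60")) +
    ggplot2::labs(x = "log2 fold change (knockdown / control)",
                  y = "-log10 FDR", color = "class") +
    ggplot2::theme_minimal()
}

#' Heat map of gene-set co-occurrence p-values
#'
#' @param object A [cooccurrence()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.cooccurrence <- function(object, ...) {
  both <- dplyr::bind_rows(
    object,
    dplyr::rename(object, set_a = "set_b", set_b = "set_a")
  )
  ggplot2::ggplot(both, ggplot2::aes(x = .data$set_a, y = .data$set_b,
                                     fill = -log10(.data$p_value))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "-log10 p") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Odds ratio versus significance for a co-upregulation screen
#'
#' @param object A `coexp_screen` from [score_target_set()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.coexp_screen <- function(object, ...) {
  res <- object$results
  ggplot2::ggplot(res, ggplot2::aes(x = log2(.data$odds_ratio),
                                    y = -log10(.data$p_value),
                                    color = .data$is_target)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_vline(xintercept = log2(object$thresholds$or),
                        linetype = 2) +
    ggplot2::geom_hline(yintercept = -log10(object$thresholds$alpha),
                        linetype = 2) +
    ggplot2::scale_color_manual(values = c(`TRUE` = "firebrick",
                                           `FALSE` = "grey60"),
                                name = "target") +
    ggplot2::labs(x = "log2 odds ratio vs anchor", y = "-log10 Fisher p") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
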