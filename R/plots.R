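#' Plot helpers
#'
#' Small ggplot2 wrappers for the main result types.
#'
#' @param x Result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name loopvar-plots
NULL

#' @rdname loopvar-plots
#' @export
plot_orientation <- function(x, ...) {
  stopifnot(inherits(x, "ctcf_orientation"))
  ggplot2::ggplot(tibble::as_tibble(unclass(x)),
                  ggplot2::aes(.data$orientation, .data$percent)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "% of two-motif loops") +
    ggplot2::theme_minimal()
}

#' @rdname loopvar-plots
#' @param label_col Column naming each test (e.g. `state`, `tf`).
#' @export
plot_enrichment <- function(x, label_col = "label", ...) {
  df <- dplyr::mutate(tibble::as_tibble(x),
                      log2_or = log2(.data$odds_ratio))
  ggplot2::ggplot(df, ggplot2::aes(.data$log2_or, .data[[label_col]])) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$p < 0.05)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "log2 odds ratio", y = NULL, colour = "p < 0.05") +
    ggplot2::theme_minimal()
}

#' @rdname loopvar-plots
#' @export
plot_gwas_bins <- function(x, ...) {
  ggplot2::ggplot(x$bins, ggplot2::aes(factor(.data$bin), .data$fold)) +
    ggplot2::geom_col(fill = "darkred") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = "significance bin (1 = most significant)",
                  y = "fold enrichment") +
    ggplot2::theme_minimal()
}
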