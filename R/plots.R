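# ggplot2 views of the main result types.

#' Plot amplification curves
#'
#' Fluorescence against cycle for every well/channel trace of a long curve
#' table, faceted by channel — the view used to eyeball amplification before
#' Cq calling.
#'
#' @param curves Long tibble with `cycle`, `fluorescence`, `well`,
#'   `channel`.
#' @return A ggplot object.
#' @export
plot_amplification <- function(curves) {
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$cycle, y = .data$fluorescence,
                               group = interaction(.data$well,
                                                   .data$channel))) +
    ggplot2::geom_line(alpha = 0.4, colour = "steelblue") +
    ggplot2::facet_wrap(~channel) +
    ggplot2::labs(x = "cycle", y = "fluorescence") +
    ggplot2::theme_minimal()
}

#' Copy-number call plot
#'
#' Copy-number estimates per locus with their integer calls — the analogue
#' of the copy-number scatter produced by CN analysis software; tight
#' clustering of estimates around integers indicates a clean plate.
#'
#' @param object A `kir_calls` tibble.
#' @param loci Optional subset of loci to show.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.kir_calls <- function(object, loci = NULL, ...) {
  d <- as_tibble(object)
  if (!is.null(loci)) d <- d %>% filter(.data$locus %in% loci)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$locus, y = .data$cn_estimate,
                                  colour = factor(.data$cn_called))) +
    ggplot2::geom_jitter(width = 0.2, height = 0, alpha = 0.7) +
    ggplot2::labs(x = NULL, y = "copy-number estimate",
                  colour = "called CN") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Copy-number profile heatmap
#'
#' @param object A `kir_profiles` tibble.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.kir_profiles <- function(object, ...) {
  long <- as_tibble(object) %>%
    select("sample_id", dplyr::any_of(kir_loci())) %>%
    tidyr::pivot_longer(-"sample_id", names_to = "locus",
                        values_to = "cn")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$locus, y = .data$sample_id,
                                     fill = factor(.data$cn))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_d(name = "CN", na.value = "grey80") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
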