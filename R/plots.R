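# ggplot2 visualisations for the main result types.

#' Plot a mutation spectrum
#'
#' Bar chart of the 12 substitution-type fractions, G/C-site types
#' highlighted.
#'
#' @param spectrum An `ems_spectrum` (from [mutation_spectrum()]).
#' @return A ggplot object.
#' @export
plot_spectrum <- function(spectrum) {
  d <- as_tibble(spectrum) %>%
    dplyr::mutate(gc_site = .data$ref %in% c("G", "C"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$type, y = .data$fraction,
                                  fill = .data$gc_site)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(
      values = c(`TRUE` = "#D55E00", `FALSE` = "grey60"),
      labels = c(`TRUE` = "G/C site", `FALSE` = "A/T site"), name = NULL
    ) +
    ggplot2::labs(x = "substitution (ref>alt)", y = "fraction of SNPs") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot SNP density along the genome from a bin scan
#'
#' Per-bin SNP counts along each chromosome with the chi-square cuts and
#' bins coloured by density class.
#'
#' @param object An `ems_bin_scan`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ems_bin_scan <- function(object, ...) {
  d <- object$bins
  ggplot2::ggplot(d, ggplot2::aes(
    x = (.data$start + .data$end) / 2e6, y = .data$snp_count,
    colour = .data$class
  )) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = c(object$low_cut, object$high_cut),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::facet_wrap(~chrom, ncol = 1) +
    ggplot2::scale_colour_manual(values = c(
      coldspot = "#0072B2", low = "grey65", mid = "grey40",
      hotspot = "#D55E00"
    )) +
    ggplot2::labs(x = "position (Mb)", y = "EMS SNPs per bin",
                  colour = "class") +
    ggplot2::theme_minimal()
}

#' Plot per-class mean epigenetic signals
#'
#' @param signal_summary Tibble from [class_signal_summary()].
#' @return A ggplot object.
#' @export
plot_class_signal <- function(signal_summary) {
  d <- dplyr::filter(signal_summary, !is.na(.data$mean_signal))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$class, y = .data$mean_signal,
                                  group = .data$modification)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~modification, scales = "free_y") +
    ggplot2::labs(x = "bin SNP-density class", y = "mean max signal") +
    ggplot2::theme_minimal()
}
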