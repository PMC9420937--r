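# ggplot2 visualisations of result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @describeIn density_profile Metagene line plot of normalised density
#'   against TSS offset, coloured by strand class.
#' @param object A `density_profile`.
#' @param ... Unused.
#' @method autoplot density_profile
#' @export
autoplot.density_profile <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$offset_start, y = .data$density,
                               colour = .data$strand_class)) +
    ggplot2::annotate("rect", xmin = -200, xmax = 200, ymin = -Inf,
                      ymax = Inf, alpha = 0.12) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "distance to TSS (bp, gene orientation)",
                  y = "breaks per million per non-repeat base",
                  colour = "strand") +
    ggplot2::theme_minimal()
}

#' @describeIn frequency_matrix Logo-style stacked bar chart: per-position
#'   base frequencies scaled by information content.
#' @param object A `context_matrix`.
#' @param ... Unused.
#' @method autoplot context_matrix
#' @export
autoplot.context_matrix <- function(object, ...) {
  long <- tidyr::pivot_longer(
    select(as_tibble(object), "position", "f_a", "f_c", "f_g", "f_t",
           "information"),
    cols = c("f_a", "f_c", "f_g", "f_t"),
    names_to = "base", values_to = "freq")
  long$base <- toupper(sub("^f_", "", long$base))
  long$bits <- long$freq * long$information
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$position),
                                     y = .data$bits, fill = .data$base)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "position relative to nick (0 = base 5' of break)",
                  y = "information (bits)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of element odds ratios
#'
#' @param enrichment Output of [element_enrichment()] (optionally with a
#'   `sample` column for facetting).
#' @return A ggplot object; the dashed line marks no enrichment (OR = 1).
#' @export
plot_element_enrichment <- function(enrichment) {
  p <- ggplot2::ggplot(enrichment,
                       ggplot2::aes(x = factor(.data$class,
                                               levels = .element_classes),
                                    y = .data$odds_ratio)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "red") +
    ggplot2::labs(x = NULL, y = "odds ratio") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if ("sample" %in% names(enrichment)) {
    p <- p + ggplot2::facet_wrap(~sample)
  }
  p
}
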