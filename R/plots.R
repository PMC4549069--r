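# ggplot2 displays for spectra and tier summaries ---------------------------

#' Bar chart of the 12-type substitution spectrum
#'
#' Per-type mutation frequencies with Wilson 95% error bars, L-strand
#' orientation (complementary types side by side so strand bias is visible).
#'
#' @param spectrum a [substitution_spectrum()] table.
#' @return a ggplot object.
#' @export
plot_spectrum <- function(spectrum) {
  df <- as_tibble(spectrum) |>
    mutate(type = factor(.data$type, levels = unique(.data$type[order(.data$pair)])))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$type, y = .data$frequency)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      width = 0.3, linewidth = 0.3
    ) +
    ggplot2::labs(x = NULL, y = "mutation frequency",
                  title = "Substitution spectrum (L-strand, 12 types)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_spectrum
#' @param object,... autoplot interface.
#' @exportS3Method ggplot2::autoplot
autoplot.mito_spectrum <- function(object, ...) plot_spectrum(object)

#' Bar chart of the 96-class trinucleotide context spectrum
#'
#' Class fractions grouped by the six pyrimidine-centred substitutions,
#' COSMIC-style.
#'
#' @param context_spectrum a [context_spectrum()] table.
#' @return a ggplot object.
#' @export
plot_context_spectrum <- function(context_spectrum) {
  df <- as_tibble(context_spectrum)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$context,
                                   y = .data$fraction_pct,
                                   fill = .data$substitution)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_grid(. ~ substitution, scales = "free_x") +
    ggplot2::labs(x = "trinucleotide context", y = "% of point mutations",
                  title = "96-class mutation context spectrum") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(
      angle = 90, vjust = 0.5, size = 5, family = "mono"
    ))
}

#' @rdname plot_context_spectrum
#' @param object,... autoplot interface.
#' @exportS3Method ggplot2::autoplot
autoplot.mito_context_spectrum <- function(object, ...) {
  plot_context_spectrum(object)
}

#' Bar chart of the clonality-tier distribution
#'
#' @param tier_dist a [tier_distribution()] table.
#' @return a ggplot object.
#' @export
plot_tier_distribution <- function(tier_dist) {
  df <- mutate(tier_dist, tier = factor(.data$tier, levels = TIER_LEVELS))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tier, y = .data$percentage)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = NULL, y = "% of unique variants",
                  title = "Clonality tier distribution") +
    ggplot2::theme_minimal()
}
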