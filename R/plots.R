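# Plotting. Scores plot as an epitope map: per-codon points and per-amino-
# acid averages of the log2 bin ratio along the scanned window.

#' Epitope map of screen scores
#'
#' Plots the log2 conservation ratio (antibody-positive over
#' antibody-negative bin enrichment) along the scanned window: one point per
#' member codon, the per-amino-acid average as a crossbar, and the escape
#' threshold as a dashed line. Positions whose substitutions fall mostly
#' below the line are epitope candidates.
#'
#' @param object A `seed_screen_scores` tibble.
#' @param effect_threshold Escape threshold drawn on the ratio scale.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.seed_screen_scores <- function(object, effect_threshold = 0.5, ...) {
  records <- tidy(object) |>
    filter(!.data$control_class %in% c("stop", "deletion"))
  profiles <- aggregate_by_amino_acid(object)
  ggplot2::ggplot(records,
                  ggplot2::aes(x = .data$position, y = .data$log2_bin_ratio)) +
    ggplot2::geom_hline(yintercept = log2(effect_threshold),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_point(data = profiles, colour = "firebrick", size = 1.6,
                        shape = 95) +
    ggplot2::labs(x = "residue position",
                  y = expression(log[2] ~ "bin ratio (bound / unbound)"),
                  title = "Epitope map: conservation ratio per substitution") +
    ggplot2::theme_minimal()
}

#' Plot per-position escape fractions
#'
#' Bar chart of the fraction of substitutions escaping at each position,
#' with called epitope positions highlighted.
#'
#' @param calls Result of [call_epitope_positions()].
#' @return A ggplot object.
#' @export
plot_epitope_calls <- function(calls) {
  detail <- attr(calls, "detail")
  if (is.null(detail)) abort("`calls` carries no detail table")
  ggplot2::ggplot(detail,
                  ggplot2::aes(x = .data$position, y = .data$fraction_escaping,
                               fill = .data$called)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "firebrick"),
                               name = "called") +
    ggplot2::labs(x = "residue position", y = "fraction of substitutions escaping") +
    ggplot2::theme_minimal()
}
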