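#' Volcano plot of differential oxidation
#'
#' Plots `log2(mean ox A / mean ox B)` against `-log10(q)`, highlighting
#' significant peptides by direction.
#'
#' @param object A `redox_diff` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot redox_diff
#' @export
autoplot.redox_diff <- function(object, ...) {
  design <- attr(object, "design")
  df <- tidy(object)
  df <- df[!is.na(df$log2_ratio) & !is.na(df$neg_log10_q), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_ratio,
                                   y = .data$neg_log10_q,
                                   colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_hline(yintercept = -log10(design$params$alpha),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_colour_manual(values = c(up_in_A = "#c0392b",
                                            up_in_B = "#2e86c1",
                                            none = "grey70")) +
    ggplot2::labs(
      x = sprintf("log2(%% oxidation %s / %s)", design$conditions[1],
                  design$conditions[2]),
      y = "-log10 q-value", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Cumulative distribution of oxidation levels per condition
#'
#' @param profile An `ox_profile`.
#' @param design A [redox_design()].
#' @return A ggplot object (ECDF of per-peptide mean oxidation with class
#'   bounds marked).
#' @export
plot_oxidation_distribution <- function(profile,
                                        design = attr(profile, "design")) {
  s <- profile_summary(profile)
  s <- s[!is.na(s$mean_ox), ]
  ggplot2::ggplot(s, ggplot2::aes(x = .data$mean_ox,
                                  colour = .data$condition)) +
    ggplot2::stat_ecdf() +
    ggplot2::geom_vline(xintercept = design$params$class_bounds,
                        linetype = "dotted", colour = "grey40") +
    ggplot2::labs(x = "mean % oxidation", y = "cumulative fraction",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Oxidation-class distribution per condition
#'
#' @param results A `redox_diff` tibble.
#' @return A ggplot bar chart of class counts per condition.
#' @export
plot_class_distribution <- function(results) {
  design <- attr(results, "design")
  df <- dplyr::bind_rows(
    tibble::tibble(condition = design$conditions[1],
                   class = results$ox_class_A),
    tibble::tibble(condition = design$conditions[2],
                   class = results$ox_class_B)
  )
  df <- df[!is.na(df$class), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, fill = .data$condition)) +
    ggplot2::geom_bar(position = "dodge") +
    ggplot2::labs(x = "oxidation class", y = "peptides", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
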