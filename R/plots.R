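#' Plot a tag length distribution
#'
#' Side-by-side bars of the 10-32 nt length histogram, by library.
#'
#' @param hist tibble from [tag_length_histogram()].
#' @return a ggplot object.
#' @export
plot_length_distribution <- function(hist) {
  ggplot2::ggplot(hist, ggplot2::aes(x = factor(.data$length), y = .data$n,
                                     fill = .data$library)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "tag length (nt)", y = "tags",
                  fill = "library") +
    ggplot2::theme_minimal()
}

#' Volcano plot of a differential-expression result
#'
#' @param object an `srna_de` object from [run_de()].
#' @param ... unused.
#' @return a ggplot object: log2 fold change against -log10 p, coloured by
#'   significance label.
#' @export
autoplot.srna_de <- function(object, ...) {
  d <- tidy(object) |>
    filter(is.finite(.data$log2fc)) |>
    mutate(neglog10p = -log10(pmax(.data$p_value, 1e-300)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log2fc, y = .data$neglog10p,
                                  colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = c(-1, 1), linetype = "dashed") +
    ggplot2::labs(x = "log2 fold change (deprived / control)",
                  y = "-log10 p-value", colour = "label") +
    ggplot2::theme_minimal()
}

#' Bar chart of KOG category percentages
#'
#' The 25 sub-categories coloured by their main class, percentages over
#' assigned gene-KOG pairs.
#'
#' @param summary tibble from [summarize_kog()] at `level = "category"`.
#' @return a ggplot object.
#' @export
plot_kog_summary <- function(summary) {
  d <- summary |>
    left_join(kog_categories, by = "category")
  ggplot2::ggplot(d, ggplot2::aes(
    x = factor(.data$category, levels = rev(kog_categories$category)),
    y = .data$percent, fill = .data$main_class)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "% of assigned target genes",
                  fill = "main class") +
    ggplot2::theme_minimal()
}
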