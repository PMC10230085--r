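#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot geNorm stability and pairwise variation
#'
#' Bar chart of per-gene geNorm `M` values (most stable first); the
#' subtitle reports the most stable pair.
#'
#' @param object A `genorm_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot genorm_fit
#' @export
autoplot.genorm_fit <- function(object, ...) {
  d <- object$stability %>%
    mutate(gene = factor(.data$gene, levels = rev(.data$gene)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value, y = .data$gene)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "geNorm M (lower = more stable)", y = NULL,
      title = "geNorm expression stability",
      subtitle = paste("Most stable pair:",
                       paste(object$final_pair, collapse = " / "))
    ) +
    ggplot2::theme_minimal()
}

#' Plot stability values across methods
#'
#' @param stability Combined stability tibble (`method`, `gene`,
#'   `value`), e.g. from [stability_all()].
#' @return A ggplot object, one facet per method, genes ordered by value.
#' @export
plot_stability <- function(stability) {
  ggplot2::ggplot(
    stability,
    ggplot2::aes(x = stats::reorder(.data$gene, .data$value),
                 y = .data$value)
  ) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~method, scales = "free") +
    ggplot2::labs(x = NULL, y = "Stability value (lower = more stable)") +
    ggplot2::theme_minimal()
}

#' Plot comprehensive geometric-mean ranking
#'
#' @param comprehensive Tibble from [reffinder_aggregate()].
#' @param top Show at most this many genes (default all).
#' @return A ggplot object.
#' @export
plot_comprehensive <- function(comprehensive, top = Inf) {
  d <- comprehensive %>%
    arrange(.data$final_rank) %>%
    head(if (is.finite(top)) top else nrow(comprehensive)) %>%
    mutate(gene = factor(.data$gene, levels = rev(.data$gene)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$geomean_rank, y = .data$gene)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = "Geometric mean of method ranks", y = NULL,
                  title = "Comprehensive reference-gene ranking") +
    ggplot2::theme_minimal()
}

#' Plot relative expression ratios by tissue
#'
#' @param ratios Tibble from [pfaffl_ratio()].
#' @return A ggplot object (log2 scale, one facet per target).
#' @export
plot_ratios <- function(ratios) {
  ggplot2::ggplot(ratios,
                  ggplot2::aes(x = .data$tissue, y = .data$ratio)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::scale_y_continuous(trans = "log2") +
    ggplot2::facet_wrap(~target, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Relative expression (calibrator = 1)") +
    ggplot2::theme_minimal()
}
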