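#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_bar geom_pointrange
#'   geom_point geom_line labs scale_fill_viridis_c facet_wrap
#'   position_dodge theme_minimal
#' @export
ggplot2::autoplot

#' Heatmap of a peptide distance matrix
#'
#' @param object A `peptide_dist`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.peptide_dist <- function(object, ...) {
  df <- tidy(object, upper_only = FALSE)
  df$peptide_a <- factor(df$peptide_a, levels = object$peptides)
  df$peptide_b <- factor(df$peptide_b, levels = object$peptides)
  ggplot(df, aes(x = .data$peptide_a, y = .data$peptide_b,
                 fill = .data$distance)) +
    geom_tile() +
    scale_fill_viridis_c() +
    labs(x = NULL, y = NULL, fill = object$metric,
         title = sprintf("Pairwise %s distances (%d peptides)",
                         object$metric, length(object$peptides))) +
    theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Composition of a split assignment
#'
#' Record counts per split, coloured by binding label.
#'
#' @param object A `split_assignment`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.split_assignment <- function(object, ...) {
  df <- as_tibble(object) %>%
    count(.data$split, label = factor(.data$label))
  ggplot(df, aes(x = .data$split, y = .data$n, fill = .data$label)) +
    geom_bar(stat = "identity", position = position_dodge()) +
    labs(x = NULL, y = "records", fill = "label",
         title = paste0(attr(object, "method"), " split (seed ",
                        attr(object, "config")$seed, ")")) +
    theme_minimal()
}

#' AUROC by split with confidence intervals
#'
#' Mean test AUROC per split with the 95% confidence interval over seeds,
#' the package's analogue of a performance-vs-split figure.
#'
#' @param object A `tcr_benchmark`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tcr_benchmark <- function(object, ...) {
  df <- object$summary
  df$split_label <- factor(df$split_label, levels = unique(df$split_label))
  ggplot(df, aes(x = .data$split_label, y = .data$mean_auroc)) +
    geom_pointrange(aes(ymin = .data$ci_lo, ymax = .data$ci_hi)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    labs(x = NULL, y = "test AUROC",
         title = "Predictor performance by splitting strategy") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
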