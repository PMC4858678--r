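# ggplot2 views of the main result types.

#' Volcano plot of an induction profile
#'
#' @param object An induction profile.
#' @param fdr_max,min_fold Thresholds drawn as the responder region.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot induction_profile
#' @export
autoplot.induction_profile <- function(object, fdr_max = 0.05,
                                       min_fold = 1.5, ...) {
  df <- tibble::as_tibble(object)
  df$responder <- !is.na(df$fdr) & df$fdr <= fdr_max & df$fold >= min_fold
  ggplot2::ggplot(df, ggplot2::aes(.data$logratio, -log10(.data$p))) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$responder),
                        size = 0.6, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * log10(min_fold),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "logratio (induced - control, log10)",
                  y = "-log10 p",
                  title = attr(object, "tf")) +
    ggplot2::theme_minimal()
}

#' Heatmap of the TF-by-tissue correlation matrix
#'
#' Cells with |z| below the significance threshold are drawn white, as in
#' the usual presentation of these matrices; rows and columns follow the
#' clustering order.
#'
#' @param object A [correlation_matrix()] result.
#' @param z_min Significance threshold on |z|.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot correlation_matrix
#' @export
autoplot.correlation_matrix <- function(object, z_min = 2, ...) {
  df <- object$results
  df$z_shown <- ifelse(abs(df$z) >= z_min, df$z, NA_real_)
  df$tf <- factor(df$tf, levels = object$tf_order)
  df$tissue <- factor(df$tissue, levels = object$tissue_order)
  ggplot2::ggplot(df, ggplot2::aes(.data$tissue, .data$tf,
                                   fill = .data$z_shown)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0,
                                  na.value = "white", name = "z") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Rank-plot curve of bound-gene density
#'
#' @param object A [rank_plot()] result.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot rank_plot_curve
#' @export
autoplot.rank_plot_curve <- function(object, ...) {
  baseline <- attr(object, "n_bound") / attr(object, "n_genes")
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$center, .data$prop)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::geom_hline(yintercept = baseline, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "gene rank (sorted by logratio, descending)",
                  y = sprintf("proportion bound per %d-gene window",
                              attr(object, "window")),
                  title = attr(object, "tf")) +
    ggplot2::theme_minimal()
}

#' Scatter of TF profiles on the first two principal components
#'
#' @param object A [pca_profiles()] result.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot profile_pca
#' @export
autoplot.profile_pca <- function(object, ...) {
  ve <- object$var_explained / sum(object$var_explained) * 100
  ggplot2::ggplot(object$scores, ggplot2::aes(.data$PC1, .data$PC2)) +
    ggplot2::geom_point(colour = "firebrick") +
    ggplot2::geom_text(ggplot2::aes(label = .data$tf), vjust = -0.8,
                       size = 3) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", ve[1]),
                  y = sprintf("PC2 (%.1f%%)", ve[2])) +
    ggplot2::theme_minimal()
}
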