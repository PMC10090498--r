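#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the two |r| cumulative distributions and the KS cutoff
#'
#' @param object A [ks_cutoff()] result.
#' @param ... Unused.
#' @return A ggplot: healthy and disease ECDFs of |r| with the cutoff
#'   marked at the maximum deviation.
#' @export
autoplot.ks_cutoff <- function(object, ...) {
  df <- tidyr::pivot_longer(object$ecdf, -"abs_r",
                            names_to = "group", values_to = "cdf",
                            names_prefix = "cdf_")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$abs_r, y = .data$cdf,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = object$cutoff, linetype = "dashed") +
    ggplot2::annotate("text", x = object$cutoff, y = 0.05, hjust = -0.1,
                      label = sprintf("cutoff = %.3f, D = %.3f",
                                      object$cutoff, object$D)) +
    ggplot2::labs(x = "|r|", y = "cumulative proportion of gene pairs",
                  colour = NULL,
                  title = "Absolute co-expression CDFs and KS cutoff") +
    ggplot2::theme_minimal()
}

#' Co-expression "galaxy": gene pairs in the (|r| healthy, |r| disease) plane
#'
#' @param object A [classify_links()] result.
#' @param ... Unused.
#' @return A ggplot of all pairs coloured by region, with the cutoff
#'   partition lines.
#' @export
autoplot.link_classification <- function(object, ...) {
  cutoff <- attr(object, "cutoff")
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$abs_r_healthy,
                               y = .data$abs_r_disease,
                               colour = .data$region)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_vline(xintercept = cutoff, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = cutoff, linetype = "dashed") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "|r| healthy", y = "|r| FMS",
                  title = "Co-expression galaxy") +
    ggplot2::theme_minimal()
}

#' Rsum bar chart of the selected hub features
#'
#' @param object A [select_hubs()] result.
#' @param ... Unused.
#' @return A ggplot of the selected hubs' Rsum values by class.
#' @export
autoplot.hub_ranking <- function(object, ...) {
  if (!"selected" %in% names(object)) {
    stop("run select_hubs() first", call. = FALSE)
  }
  sel <- dplyr::filter(tibble::as_tibble(unclass_tbl(object)), .data$selected)
  sel$rsum <- ifelse(sel$hub_class == "DISRUPTED",
                     sel$rsum_disrupted, sel$rsum_invoked)
  ggplot2::ggplot(sel, ggplot2::aes(
    x = stats::reorder(.data$gene, .data$rsum),
    y = .data$rsum, fill = .data$hub_class
  )) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Rsum", fill = NULL,
                  title = "Selected hub gene features") +
    ggplot2::theme_minimal()
}

#' Accuracy heatmap over the (C, gamma) grid
#'
#' @param object A [grid_search_cv()] result.
#' @param ... Unused.
#' @return A ggplot heatmap of mean CV accuracy on log2 axes, best pair
#'   marked.
#' @export
autoplot.cv_report <- function(object, ...) {
  ggplot2::ggplot(object$grid,
                  ggplot2::aes(x = log2(.data$gamma), y = log2(.data$C),
                               fill = .data$mean_accuracy)) +
    ggplot2::geom_tile() +
    ggplot2::annotate("point", x = log2(object$best_gamma),
                      y = log2(object$best_C), shape = 4, size = 3) +
    ggplot2::labs(x = "log2 gamma", y = "log2 C", fill = "accuracy",
                  title = "Grid-search cross-validation accuracy") +
    ggplot2::theme_minimal()
}

#' Originals and noise replicates in the top-2 PCA plane
#'
#' @param object A [fidelity_report()] result.
#' @param ... Unused.
#' @return A ggplot: originals emphasised, replicates translucent.
#' @export
autoplot.fidelity_report <- function(object, ...) {
  df <- object$projection
  ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                   colour = .data$source_id)) +
    ggplot2::geom_point(data = df[df$replicate > 0, ], alpha = 0.4,
                        size = 1) +
    ggplot2::geom_point(data = df[df$replicate == 0, ], size = 2.5,
                        shape = 17) +
    ggplot2::guides(colour = "none") +
    ggplot2::labs(title = "Augmented samples in 2-D PCA space",
                  subtitle = "triangles: originals; dots: noise replicates") +
    ggplot2::theme_minimal()
}
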