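# ggplot2 views of the main result types.

#' @describeIn run_ensemble Density plot of the per-class F1 distribution
#'   of an ensemble.
#' @param object An `lv_ensemble`.
#' @param ... Unused.
#' @method autoplot lv_ensemble
#' @export
autoplot.lv_ensemble <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$f1, fill = .data$class)) +
    ggplot2::geom_density(alpha = 0.4, adjust = 1.5) +
    ggplot2::coord_cartesian(xlim = c(0, 1)) +
    ggplot2::labs(x = "per-class F1", y = "density",
                  title = sprintf("F1 over %d resamples (%s features)",
                                  object$n_iterations,
                                  length(object$features))) +
    ggplot2::theme_minimal()
}

#' @describeIn pca_batch_assessment Density plot of normalized
#'   within-study distances in gene versus LV space.
#' @param object A `batch_assessment`.
#' @param ... Unused.
#' @method autoplot batch_assessment
#' @export
autoplot.batch_assessment <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(space = "gene", distance = object$distances_gene),
    tibble::tibble(space = "LV", distance = object$distances_lv))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance, fill = .data$space)) +
    ggplot2::geom_density(alpha = 0.4) +
    ggplot2::labs(x = "normalized within-study distance", y = "density",
                  subtitle = sprintf("Wilcoxon p = %.3g", object$p_value)) +
    ggplot2::theme_minimal()
}

#' Heatmap of immune-score versus LV correlations
#'
#' @param cors Tibble from [correlate_immune_lv()].
#' @return A ggplot object.
#' @export
plot_immune_correlation <- function(cors) {
  ggplot2::ggplot(cors, ggplot2::aes(x = .data$cell_type, y = .data$lv,
                                     fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Per-cluster mean LV expression by tumor type
#'
#' @param expr_tbl Tibble from [cluster_expression_by_type()].
#' @return A ggplot object.
#' @export
plot_cluster_expression <- function(expr_tbl) {
  ggplot2::ggplot(expr_tbl,
                  ggplot2::aes(x = factor(.data$cluster),
                               y = .data$mean_expression,
                               fill = .data$tumor_type)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = "LV cluster", y = "mean LV expression",
                  fill = "tumor type") +
    ggplot2::theme_minimal()
}

#' Drug-enrichment bar plot
#'
#' @param enr Tibble from [drug_enrichment()] (optionally with a `cluster`
#'   column).
#' @param max_drugs Show at most this many drugs per panel (default 15).
#' @return A ggplot object.
#' @export
plot_drug_enrichment <- function(enr, max_drugs = 15) {
  df <- enr |>
    dplyr::arrange(.data$q_bh) |>
    dplyr::slice_head(n = max_drugs)
  p <- ggplot2::ggplot(df,
                       ggplot2::aes(x = stats::reorder(.data$drug, -.data$q_bh),
                                    y = -log10(.data$q_bh),
                                    fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "-log10 BH q", fill = "q < 0.05") +
    ggplot2::theme_minimal()
  if ("cluster" %in% names(enr)) {
    p <- p + ggplot2::facet_wrap(~cluster, scales = "free_y")
  }
  p
}
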