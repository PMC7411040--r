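# ggplot2 visualizations for the main result types.

#' Plot the PAC curve of a consensus clustering result
#'
#' @param object a `consensus_result`.
#' @param ... unused.
#' @return a ggplot: PAC versus K with the chosen K marked.
#' @method autoplot consensus_result
#' @export
autoplot.consensus_result <- function(object, ...) {
  df <- object$pac
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$pac)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k_opt, linetype = "dashed") +
    ggplot2::scale_x_continuous(breaks = df$k) +
    ggplot2::labs(x = "number of clusters K",
                  y = "proportion of ambiguous clustering",
                  title = sprintf("PAC curve (chosen K = %d)", object$k_opt)) +
    ggplot2::theme_minimal()
}

#' Heatmap of a consensus matrix
#'
#' @param cr a `consensus_result`.
#' @param k which K to show (default the chosen one).
#' @return a ggplot tile map with patients ordered by the final dendrogram.
#' @export
plot_consensus_matrix <- function(cr, k = cr$k_opt) {
  cm <- cr$consensus[[as.character(k)]]
  ord <- cr$tree$order
  cm <- cm[ord, ord]
  df <- tidyr::expand_grid(i = seq_len(nrow(cm)), j = seq_len(ncol(cm)))
  df$consensus <- cm[cbind(df$i, df$j)]
  ggplot2::ggplot(df, ggplot2::aes(.data$i, .data$j, fill = .data$consensus)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "white", high = "navy",
                                 limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Consensus matrix, K = %d", k)) +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier curves by group
#'
#' @param records survival records with `time_months`, `event` and the
#'   grouping column.
#' @param by grouping column name.
#' @return a ggplot step-function plot of survival by group.
#' @export
plot_km <- function(records, by = "group") {
  km <- km_estimate(records, by = by)
  # prepend S(0) = 1 per group for a complete step curve
  z <- dplyr::distinct(km, .data$group)
  z$time <- 0; z$estimate <- 1
  km <- dplyr::bind_rows(z, km[, c("group", "time", "estimate")])
  ggplot2::ggplot(km, ggplot2::aes(.data$time, .data$estimate,
                                   color = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "months", y = "survival probability") +
    ggplot2::theme_minimal()
}

#' Volcano-style view of an association screen
#'
#' @param screen tibble from [association_screen()].
#' @param fdr_cutoff highlighting threshold.
#' @return a ggplot of log2 fold change versus -log10 FDR.
#' @export
plot_association_volcano <- function(screen, fdr_cutoff = 0.05) {
  df <- screen[is.finite(screen$log_fold_change), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$log_fold_change,
                                   -log10(.data$fdr),
                                   color = .data$fdr < fdr_cutoff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey60",
                                           `TRUE` = "firebrick"),
                                name = sprintf("FDR < %.2g", fdr_cutoff)) +
    ggplot2::labs(x = "log2 fold change (carriers / non-carriers)",
                  y = "-log10 FDR") +
    ggplot2::theme_minimal()
}
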