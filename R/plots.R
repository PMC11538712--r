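#' Forest plot for a random-effects fit
#'
#' Per-cohort effects with 95% intervals and the pooled estimate (dashed
#' line).
#'
#' @param object An `rem_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rem_fit
#' @export
autoplot.rem_fit <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$g, y = .data$cohort_id)) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = object$mu_hat, linetype = "dashed") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::geom_point(ggplot2::aes(size = .data$weight), shape = 15) +
    ggplot2::scale_size_area(max_size = 4, guide = "none") +
    ggplot2::labs(x = "Hedges' G (positive = depleted in cases)", y = NULL,
                  title = object$species_id,
                  subtitle = sprintf("pooled %.3f [%s], I2 = %.0f%%",
                                     object$mu_hat, object$method, object$I2)) +
    ggplot2::theme_minimal()
}

#' Fold-AUC plot for a cross-validation report
#'
#' @param object A `cv_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cv_report
#' @export
autoplot.cv_report <- function(object, ...) {
  ggplot2::ggplot(object$folds, ggplot2::aes(x = .data$test_id, y = .data$auc)) +
    ggplot2::geom_hline(yintercept = 0.5, colour = "grey70") +
    ggplot2::geom_hline(yintercept = object$mean_auc, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "test cohort", y = "AUC",
                  title = sprintf("%s (mean AUC %.3f)", object$scheme, object$mean_auc)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Probability-shift plot for a treatment report
#'
#' Before/after distributions of the classifier probability of the disease
#' class.
#'
#' @param object A `shift_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot shift_report
#' @export
autoplot.shift_report <- function(object, ...) {
  probs <- dplyr::mutate(object$probabilities,
                         group = factor(.data$group, levels = c("before", "after")))
  ggplot2::ggplot(probs, ggplot2::aes(x = .data$group, y = .data$prob_case)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.4, size = 0.8) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "P(classified as case)",
                  title = sprintf("probability shift (Wilcoxon p = %.2g)", object$wilcoxon_p)) +
    ggplot2::theme_minimal()
}

#' Heatmap of diet-species associations
#'
#' Spearman rho per food item and species; significant cells
#' (FDR < `fdr_thresh`) are starred.
#'
#' @param grid An `association_grid` from [diet_species_correlations()].
#' @param fdr_thresh FDR threshold for the significance stars.
#' @return A ggplot object.
#' @export
plot_association_grid <- function(grid, fdr_thresh = 0.1) {
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$species_id, y = .data$item_id,
                                     fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(data = grid[!is.na(grid$q) & grid$q < fdr_thresh, ],
                       label = "*", vjust = 0.75) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b",
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman rho") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1, vjust = 0.5))
}
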