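#' Plot a ROC curve
#'
#' @param object A `ctp_roc` from [roc_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ctp_roc
#' @export
autoplot.ctp_roc <- function(object, ...) {
  df <- as_tibble(object)
  ggplot(df, aes(x = 1 - .data$specificity, y = .data$sensitivity)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    geom_line() +
    coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    labs(x = "1 - specificity", y = "Sensitivity",
         title = sprintf("%s (%s), AUC = %.2f", toupper(attr(object, "parameter")),
                         attr(object, "direction"), attr(object, "auc"))) +
    theme_minimal()
}

#' Plot one precision-recall curve
#'
#' @param object A `ctp_pr` from [precision_recall_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ctp_pr
#' @export
autoplot.ctp_pr <- function(object, ...) {
  df <- dplyr::filter(as_tibble(object), !is.na(.data$precision))
  ggplot(df, aes(x = .data$recall, y = .data$precision)) +
    geom_line() + geom_point(size = 0.8) +
    coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    labs(x = "Recall", y = "Precision", title = attr(object, "source")) +
    theme_minimal()
}

#' Precision-recall curves of all sources in an experiment
#'
#' Reproduces the per-scenario comparison of the four single-parameter
#' curves against the probability curve.
#'
#' @param experiment A `ctp_experiment` from [run_experiment()].
#' @return A ggplot faceted by scenario.
#' @export
plot_pr_comparison <- function(experiment) {
  df <- dplyr::filter(experiment$pr_curves, !is.na(.data$precision))
  ggplot(df, aes(x = .data$recall, y = .data$precision,
                 colour = .data$source)) +
    geom_line() +
    facet_wrap(~scenario) +
    coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    labs(x = "Recall", y = "Precision", colour = "Map") +
    theme_minimal()
}

#' Boxplots of per-case volume differences by classification method
#'
#' Predicted minus ground-truth volume for each test case, per
#' classification method and scenario.
#'
#' @param experiment A `ctp_experiment` from [run_experiment()].
#' @return A ggplot faceted by scenario.
#' @export
plot_volume_differences <- function(experiment) {
  ggplot(experiment$differences,
         aes(x = .data$method, y = .data$difference)) +
    geom_hline(yintercept = 0, linetype = "dashed", colour = "grey60") +
    geom_boxplot() +
    facet_wrap(~scenario) +
    labs(x = NULL, y = "Volume difference (mL)") +
    theme_minimal()
}
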