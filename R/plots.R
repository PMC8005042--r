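#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Training-history curve
#'
#' Per-epoch training loss and validation RMSE of a fitted model, with
#' the best (restored) epoch marked.
#'
#' @param object A `multignn_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot multignn_fit
#' @export
autoplot.multignn_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, cols = c("train_loss", "val_rmse"),
                           names_to = "metric", values_to = "value")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value,
                                  colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "value (log scale)",
                  title = paste0(object$config$architecture,
                                 " training history"),
                  subtitle = paste0("best epoch ", object$best_epoch,
                                    ", validation RMSE ",
                                    signif(object$val_rmse, 3))) +
    ggplot2::theme_minimal()
}

#' Observed-versus-predicted scatter
#'
#' @param fit A `multignn_fit` or `qsar_fit`.
#' @param data For a `multignn_fit`, a tibble with `graph` and `pic50`
#'   columns to predict on; ignored for a `qsar_fit` (training data
#'   shown).
#' @return A ggplot object annotated with RMSE and R-squared.
#' @export
plot_predictions <- function(fit, data = NULL) {
  if (inherits(fit, "qsar_fit")) {
    obs <- fit$observed; pred <- fit$fitted
  } else {
    stopifnot(!is.null(data))
    obs <- data$pic50; pred <- predict(fit, data)
  }
  m <- regression_metrics(pred, obs)
  ggplot2::ggplot(tibble::tibble(observed = obs, predicted = pred),
                  ggplot2::aes(x = .data$observed, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "observed pIC50", y = "predicted pIC50",
                  subtitle = sprintf("RMSE %.3f, R² %.3f",
                                     m$rmse, m$r_squared)) +
    ggplot2::theme_minimal()
}

#' Vote-score bar chart
#'
#' @param object A `vote_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot vote_table
#' @export
autoplot.vote_table <- function(object, ...) {
  ranked <- total_votes(object)
  ranked$id <- factor(ranked$id, levels = rev(ranked$id))
  ggplot2::ggplot(ranked, ggplot2::aes(x = .data$total, y = .data$id)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "total vote score", y = NULL) +
    ggplot2::theme_minimal()
}
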