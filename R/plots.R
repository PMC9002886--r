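#' Plots for cross-validation reports
#'
#' `autoplot()` (and the `plot_*` helpers) render the three standard views
#' of a biometric identification experiment: the CMC curve (identification
#' rate against rank), the macro-averaged ROC curve with its nAUC and EER
#' annotated, and the training/validation loss curves averaged over folds.
#'
#' @param object,cv A `gait_cv`.
#' @param type Which plot: `"cmc"`, `"roc"` or `"loss"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gait_cv <- function(object, type = c("cmc", "roc", "loss"), ...) {
  switch(match.arg(type),
         cmc = plot_cmc(object),
         roc = plot_roc(object),
         loss = plot_loss(object))
}

#' @rdname autoplot.gait_cv
#' @export
plot_cmc <- function(cv) {
  ggplot2::ggplot(cv$cmc, ggplot2::aes(x = .data$rank, y = .data$cmc)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Rank", y = "Identification rate",
                  title = "Cumulative match characteristic") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.gait_cv
#' @export
plot_roc <- function(cv) {
  roc <- if (inherits(cv, "macro_roc")) cv else cv$roc
  ggplot2::ggplot(roc$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_line() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = "Macro-averaged ROC",
                  subtitle = sprintf("nAUC = %.4f, EER = %.4f",
                                     roc$nauc, roc$eer)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.gait_cv
#' @export
plot_loss <- function(cv) {
  h <- if (inherits(cv, "gait_cnn_fit")) {
    dplyr::mutate(cv$history, fold = 1L)
  } else {
    cv$history
  }
  avg <- dplyr::summarise(
    dplyr::group_by(h, .data$epoch),
    training = mean(.data$loss),
    validation = mean(.data$val_loss),
    .groups = "drop")
  long <- tidyr::pivot_longer(avg, c("training", "validation"),
                              names_to = "curve", values_to = "loss")
  long <- long[is.finite(long$loss), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                     colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Epoch", y = "Categorical cross-entropy",
                  colour = NULL, title = "Mean loss over folds") +
    ggplot2::theme_minimal()
}
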