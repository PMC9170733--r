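#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an evaluation report
#'
#' `autoplot()` on a [evaluate()] result draws one of the standard report
#' panels: the hold-out ROC curve, the ranked nonzero feature importances,
#' or the confusion matrix.
#'
#' @param object A `cd_eval`.
#' @param type `"roc"`, `"importance"` or `"confusion"`.
#' @param top_n Number of features shown on the importance panel.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cd_eval <- function(object, type = c("roc", "importance", "confusion"),
                             top_n = 20, ...) {
  type <- match.arg(type)
  if (type == "roc") {
    if (is.na(object$auc)) {
      stop("ROC undefined: hold-out contains a single class", call. = FALSE)
    }
    r <- pROC::roc(response = object$predictions$actual,
                   predictor = object$predictions$prob,
                   levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
    d <- tibble::tibble(fpr = rev(1 - r$specificities),
                        tpr = rev(r$sensitivities))
    ggplot2::ggplot(d, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
      ggplot2::geom_step(linewidth = 0.8, colour = "#2166ac") +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                           colour = "grey60") +
      ggplot2::coord_equal() +
      ggplot2::labs(
        x = "False positive rate", y = "True positive rate",
        title = sprintf("Hold-out ROC, tier '%s'", object$tier),
        subtitle = sprintf("AUC %.3f (sd %.3f), n = %d", object$auc,
                           object$auc_sd, object$n_holdout)
      ) +
      ggplot2::theme_minimal()
  } else if (type == "importance") {
    d <- utils::head(object$importance, top_n)
    ggplot2::ggplot(d, ggplot2::aes(x = .data$gain,
                                    y = stats::reorder(.data$feature,
                                                       .data$gain))) +
      ggplot2::geom_col(fill = "#2166ac") +
      ggplot2::labs(x = "Relative importance (gain)", y = NULL,
                    title = sprintf("Feature importance, tier '%s'",
                                    object$tier)) +
      ggplot2::theme_minimal()
  } else {
    d <- as.data.frame(object$confusion)
    ggplot2::ggplot(d, ggplot2::aes(x = .data$actual, y = .data$predicted,
                                    fill = .data$Freq)) +
      ggplot2::geom_tile() +
      ggplot2::geom_text(ggplot2::aes(label = .data$Freq), size = 5) +
      ggplot2::scale_fill_gradient(low = "white", high = "#2166ac",
                                   guide = "none") +
      ggplot2::labs(x = "Actual", y = "Predicted",
                    title = sprintf("Confusion matrix, tier '%s'",
                                    object$tier)) +
      ggplot2::theme_minimal()
  }
}

#' Compare tiers in one panel
#'
#' Bar chart of hold-out accuracy and AUC across the three model tiers of
#' a [run_tiers()] report.
#'
#' @param object A `cd_tier_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cd_tier_report <- function(object, ...) {
  d <- object$summary |>
    tidyr::pivot_longer(c("accuracy", "auc"), names_to = "metric",
                        values_to = "value") |>
    dplyr::mutate(tier = factor(.data$tier,
                                levels = c("base", "activity", "full")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$tier, y = .data$value,
                                  fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(accuracy = "#92c5de",
                                          auc = "#2166ac")) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Model tier", y = NULL, fill = NULL,
                  title = "Hold-out performance by model tier") +
    ggplot2::theme_minimal()
}

#' Plot minute-level activity signals
#'
#' Line plot of the ENMO and VMC minute series for a few subjects, the
#' quickest visual check of the circadian structure feeding the feature
#' bank.
#'
#' @param minute_signals Output of [compute_minute_signals()].
#' @param subjects Optional subject ids to show (default: first 4).
#' @return A ggplot object.
#' @export
plot_minute_signals <- function(minute_signals, subjects = NULL) {
  if (is.null(subjects)) {
    subjects <- utils::head(unique(minute_signals$subject_id), 4)
  }
  d <- minute_signals |>
    dplyr::filter(.data$subject_id %in% subjects) |>
    tidyr::pivot_longer(c("enmo", "vmc"), names_to = "signal",
                        values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$minute / 60, y = .data$value,
                                  colour = .data$subject_id)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~ .data$signal, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Hour of day", y = "Signal value",
                  colour = "Subject") +
    ggplot2::theme_minimal()
}
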