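#' Plot the ROC curve of an evaluation report
#'
#' @param object An `eval_report` from [classification_metrics()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eval_report <- function(object, ...) {
  ggplot2::ggplot(object$roc_points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.7, colour = "#2c7fb8") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC curve (AUC = %.3f)", object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Plot the training history of a fitted model
#'
#' @param object A trained `rbp_cnn`.
#' @param ... Unused.
#' @return A ggplot object with loss and accuracy panels over epochs.
#' @export
autoplot.rbp_cnn <- function(object, ...) {
  if (is.null(object$history)) abort("model has no training history yet")
  long <- tidyr::pivot_longer(object$history, -"epoch",
    names_to = "metric", values_to = "value"
  )
  long$partition <- ifelse(grepl("^val", long$metric), "validation", "train")
  long$what <- ifelse(grepl("loss", long$metric), "loss", "accuracy")
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$epoch, y = .data$value, colour = .data$partition
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(
      xintercept = object$best_epoch,
      linetype = "dotted", colour = "grey50"
    ) +
    ggplot2::facet_wrap(~what, scales = "free_y") +
    ggplot2::labs(x = "Epoch", y = NULL, colour = NULL, title = "Training history") +
    ggplot2::theme_minimal()
}

#' Information-content logo of a motif
#'
#' Stacked-bar sequence logo: at each position the letters are stacked in
#' increasing order of probability and scaled so the total bar height is
#' the column's information content (2 - Shannon entropy, in bits).
#'
#' @param object A `pfm`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pfm <- function(object, ...) {
  probs <- object$probs
  w <- ncol(probs)
  ic <- vapply(seq_len(w), function(j) {
    p <- probs[, j]
    2 + sum(ifelse(p > 0, p * log2(p), 0))
  }, numeric(1))
  df <- do.call(rbind, lapply(seq_len(w), function(j) {
    ord <- order(probs[, j])
    data.frame(
      position = j,
      letter = factor(PFM_ALPHABET[ord], levels = PFM_ALPHABET),
      height = probs[ord, j] * ic[j]
    )
  }))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$position, y = .data$height, fill = .data$letter,
    label = .data$letter
  )) +
    ggplot2::geom_col(width = 0.85, colour = NA) +
    ggplot2::geom_text(
      position = ggplot2::position_stack(vjust = 0.5),
      size = 3, colour = "white", fontface = "bold"
    ) +
    ggplot2::scale_fill_manual(values = c(
      A = "#109648", C = "#255c99", G = "#f7b32b", U = "#d62839"
    ), guide = "none") +
    ggplot2::scale_x_continuous(breaks = seq_len(w)) +
    ggplot2::labs(
      x = "Position", y = "Information (bits)",
      title = paste0(object$name, " (nsites = ", object$nsites, ")")
    ) +
    ggplot2::theme_minimal()
}
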