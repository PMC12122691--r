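#' @export
print.predann_fit <- function(x, ...) {
  cat("Paired EEG/music model trained with the PredANN objective\n")
  cat(sprintf("  encoders: %s, %d blocks [%s], embedding %d\n",
              x$encoder$family, x$encoder$n_blocks,
              paste(x$encoder$channels_per_block, collapse = ", "),
              x$encoder$embedding_dim))
  cat(sprintf("  classes: %d   window: %g s   delay: %g ms   seed: %d\n",
              x$n_classes, x$window_seconds, x$delay_ms, x$seed))
  cat(sprintf("  loss: lambda=%g, tau=%g, stop_gradient=%s\n",
              x$loss_config$lambda_predann, x$loss_config$temperature,
              x$loss_config$stop_gradient))
  cat(sprintf("  best validation accuracy: %.3f (epoch %d; chance %.3f)\n",
              x$best_val_accuracy, x$best_epoch,
              chance_level(x$n_classes)))
  invisible(x)
}

#' Summarize a fitted paired model
#'
#' @param object A `"predann_fit"`.
#' @param ... Unused.
#' @return An object of class `"summary.predann_fit"` with loss-trace
#'   endpoints, validation trace, parameter counts, and the PredANN
#'   gradient-isolation audit.
#' @export
summary.predann_fit <- function(object, ...) {
  tr <- object$loss_trace
  structure(list(
    fit = object,
    n_epochs = nrow(tr),
    first_loss = tr$total[1L], last_loss = tr$total[nrow(tr)],
    best_val_accuracy = object$best_val_accuracy,
    best_epoch = object$best_epoch,
    chance = chance_level(object$n_classes),
    parameter_count = parameter_count(object$model),
    gradient_audit = object$gradient_audit,
    n_train_excerpts = length(object$train_excerpts),
    n_val_excerpts = length(object$val_excerpts)),
    class = "summary.predann_fit")
}

#' @export
print.summary.predann_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  epochs: %d   mean loss/segment: %.4f -> %.4f\n",
              x$n_epochs, x$first_loss, x$last_loss))
  cat(sprintf("  excerpts: %d train / %d validation\n",
              x$n_train_excerpts, x$n_val_excerpts))
  cat(sprintf("  parameters: EEG branch %d, music branch %d\n",
              x$parameter_count["eeg"], x$parameter_count["music"]))
  cat(sprintf(
    "  PredANN gradient audit (max |grad|): EEG %.3g, music %.3g%s\n",
    x$gradient_audit$eeg, x$gradient_audit$music,
    if (x$fit$loss_config$stop_gradient) " (stop-gradient on)" else ""))
  invisible(x)
}

#' Predict song classes for EEG windows
#'
#' Runs the best-validation EEG branch on new EEG windows.  Windows must
#' already be preprocessed the way training data were (robust-scaled,
#' clamped) and have the fitted window length.
#'
#' @param object A `"predann_fit"`.
#' @param newdata A single EEG matrix (channels x samples), a list of
#'   such matrices, or a list of [paired_segment()]s.
#' @param type `"prob"` for a `n x n_classes` matrix of softmax scores
#'   (columns named by zero-based class), `"class"` for the zero-based
#'   argmax vector.
#' @param ... Unused.
#' @return Score matrix or class vector.
#' @export
predict.predann_fit <- function(object, newdata,
                                type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (is.matrix(newdata)) newdata <- list(newdata)
  segs <- lapply(newdata, function(s)
    if (inherits(s, "paired_segment")) s$eeg else as.matrix(s))
  enc <- encode(object$model, segs, "eeg")
  probs <- softmax_rows(enc$logits)
  colnames(probs) <- as.character(seq_len(object$n_classes) - 1L)
  if (type == "class") max.col(probs, ties.method = "first") - 1L
  else probs
}

#' Plot training diagnostics
#'
#' Loss-component traces per epoch with the validation-accuracy trace
#' overlaid on a secondary axis.
#'
#' @param x A `"predann_fit"`.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.predann_fit <- function(x, ...) {
  tr <- x$loss_trace
  graphics::matplot(tr$epoch, tr[, c("cls_eeg", "cls_music", "predann")],
                    type = "l", lty = 1, col = c(2, 4, 3),
                    xlab = "epoch", ylab = "mean loss per segment",
                    main = "PredANN training", ...)
  graphics::legend("topright",
                   c("cls EEG", "cls music", "PredANN", "val accuracy"),
                   lty = c(1, 1, 1, 2), col = c(2, 4, 3, 1), bty = "n")
  if (nrow(x$val_trace)) {
    usr <- graphics::par("usr")
    acc_y <- usr[3] + (usr[4] - usr[3]) * x$val_trace$accuracy
    graphics::lines(x$val_trace$epoch, acc_y, lty = 2)
    graphics::axis(4, at = usr[3] + (usr[4] - usr[3]) * c(0, 0.5, 1),
                   labels = c("0", "0.5", "1"))
  }
  invisible(x)
}

#' Extract model parameters
#'
#' @param object A `"predann_fit"`.
#' @param ... Unused.
#' @return The nested parameter list of the best-validation model, with
#'   branches `eeg` and `music`.
#' @export
coef.predann_fit <- function(object, ...) object$model$params
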