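#' Save a model checkpoint
#'
#' Serializes the best-validation weights together with a manifest
#' (encoder spec, class count, channel count, window/delay settings,
#' loss config, seed) so the model can be reloaded bit-identically.
#'
#' @param fit A [predann_fit()] result (or a bare `"predann_model"`).
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(fit, path) {
  obj <- if (inherits(fit, "predann_fit")) {
    list(model = fit$model,
         manifest = list(encoder = fit$encoder, n_classes = fit$n_classes,
                         fs_eeg = fit$fs_eeg,
                         window_seconds = fit$window_seconds,
                         delay_ms = fit$delay_ms,
                         loss_config = fit$loss_config, seed = fit$seed,
                         best_val_accuracy = fit$best_val_accuracy))
  } else if (inherits(fit, "predann_model")) {
    list(model = fit, manifest = list(seed = fit$seed))
  } else stop("`fit` must be a predann_fit or predann_model")
  saveRDS(obj, path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path File written by [save_checkpoint()].
#' @return List with `model` (a `"predann_model"`) and `manifest`.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj$model, "predann_model"))
    stop("not a model checkpoint: ", path)
  obj
}

#' Write a paired dataset container
#'
#' Stores recordings and stimuli in a single serialized container file.
#'
#' @param dataset A `"synthetic_dataset"` or compatible list with
#'   `recordings` and `stimuli`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  if (is.null(dataset$recordings) || is.null(dataset$stimuli))
    stop("`dataset` must contain `recordings` and `stimuli`")
  saveRDS(dataset, path)
  invisible(path)
}

#' Read a paired dataset container
#'
#' @param path File written by [write_dataset()].
#' @return The dataset list.
#' @export
read_dataset <- function(path) {
  ds <- readRDS(path)
  if (is.null(ds$recordings) || is.null(ds$stimuli))
    stop("not a paired dataset container: ", path)
  ds
}

#' Read a YAML run configuration
#'
#' Maps a YAML file with optional sections `synthetic`, `preprocessing`,
#' `loss`, and `training` onto the package's configuration objects.
#' Unknown keys are rejected so typos surface early.
#'
#' @param path YAML file.
#' @return List with elements `synthetic` ([synthetic_config()] or
#'   `NULL`), `loss` ([loss_config()]), and `training` (named list of
#'   [predann_fit()] arguments).
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("synthetic", "preprocessing", "loss", "training")
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config section(s): ",
                        paste(bad, collapse = ", "))
  syn <- if (!is.null(y$synthetic)) do.call(synthetic_config, y$synthetic)
  loss <- do.call(loss_config, if (is.null(y$loss)) list() else y$loss)
  training <- if (is.null(y$training)) list() else y$training
  if (!is.null(y$preprocessing)) training <- c(training, y$preprocessing)
  list(synthetic = syn, loss = loss, training = training)
}
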