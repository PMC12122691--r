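#' Construct an EEG recording
#'
#' Bundles a multichannel EEG signal with its sampling rate and identity
#' metadata.  Channels are rows, samples are columns.  Song identifiers are
#' zero-based class labels, the convention used throughout the package (and
#' in all printed class indices).
#'
#' @param data Numeric matrix, `n_channels x n_samples`.
#' @param fs Sampling rate in Hz (default 125, the rate EEG is assumed to be
#'   downsampled to before modelling).
#' @param subject_id Subject identifier (integer or character).
#' @param song_id Zero-based class label in `[0, n_classes)`.
#' @return An object of class `"eeg_recording"`.
#' @export
eeg_recording <- function(data, fs = 125, subject_id = NA, song_id = NA) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric matrix (channels x samples)")
  if (nrow(data) < 1L || ncol(data) < 1L)
    stop("EEG recording must have at least one channel and one sample")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a positive scalar sampling rate in Hz")
  structure(
    list(data = data, fs = fs, subject_id = subject_id, song_id = song_id),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), subject=%s, song=%s\n",
    nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
    format(x$subject_id), format(x$song_id)))
  invisible(x)
}

#' Construct an audio stimulus
#'
#' A mono waveform with sampling rate and class label.  By default the
#' synthetic pipeline represents audio at the EEG rate so that paired
#' windows have equal sample counts; any positive rate is accepted.
#'
#' @param waveform Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param song_id Zero-based class label.
#' @return An object of class `"audio_stimulus"`.
#' @export
audio_stimulus <- function(waveform, fs, song_id = NA) {
  if (!is.numeric(waveform) || length(waveform) < 1L)
    stop("`waveform` must be a non-empty numeric vector")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a positive scalar sampling rate in Hz")
  structure(list(waveform = as.numeric(waveform), fs = fs, song_id = song_id),
            class = "audio_stimulus")
}

#' @export
print.audio_stimulus <- function(x, ...) {
  cat(sprintf("<audio_stimulus> %d samples @ %g Hz (%.1f s), song=%s\n",
              length(x$waveform), x$fs, length(x$waveform) / x$fs,
              format(x$song_id)))
  invisible(x)
}

#' Construct a paired EEG/audio segment
#'
#' A delay-aligned training or evaluation unit: an EEG window, the audio
#' window it responds to, and both modality labels.  For genuinely paired
#' segments the two labels agree; `strict = TRUE` enforces this.
#'
#' @param eeg Numeric matrix `n_channels x W_e`.
#' @param audio Numeric vector of `W_a` samples.
#' @param label_eeg,label_music Zero-based class labels.
#' @param delay_ms Non-negative stimulus-to-response latency in
#'   milliseconds that was applied when cutting the EEG window.
#' @param subject_id Optional subject identifier carried for reporting.
#' @param strict Require `label_eeg == label_music`.
#' @return An object of class `"paired_segment"`.
#' @export
paired_segment <- function(eeg, audio, label_eeg, label_music = label_eeg,
                           delay_ms = 0, subject_id = NA, strict = TRUE) {
  if (!is.matrix(eeg)) eeg <- matrix(eeg, nrow = 1L)
  if (delay_ms < 0) stop("`delay_ms` must be non-negative")
  if (strict && !isTRUE(label_eeg == label_music))
    stop("paired segment has mismatched labels (label_eeg != label_music)")
  structure(
    list(eeg = eeg, audio = as.numeric(audio), label_eeg = label_eeg,
         label_music = label_music, delay_ms = delay_ms,
         subject_id = subject_id),
    class = "paired_segment")
}

#' @export
print.paired_segment <- function(x, ...) {
  cat(sprintf(
    "<paired_segment> eeg %dx%d, audio %d, label=%s, delay=%g ms\n",
    nrow(x$eeg), ncol(x$eeg), length(x$audio), format(x$label_eeg),
    x$delay_ms))
  invisible(x)
}

#' Window predictions for a long excerpt
#'
#' Per-window softmax score vectors produced by sliding a trained
#' classifier over a long evaluation excerpt, the object that the mean,
#' max, and majority aggregation rules consume.
#'
#' @param scores Numeric matrix `n_windows x n_classes`; rows should be
#'   (approximately) probability vectors, in temporal window order.
#' @param true_label Zero-based true class, or `NA` if unknown.
#' @param tol Row-sum tolerance used for validation (default 0.01, loose
#'   enough for scores re-entered from rounded printouts).
#' @return An object of class `"window_predictions"`.
#' @export
window_predictions <- function(scores, true_label = NA, tol = 0.01) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 1L) stop("need at least one window of scores")
  if (any(!is.finite(scores)) || any(scores < 0))
    stop("scores must be finite and non-negative")
  rs <- rowSums(scores)
  if (any(abs(rs - 1) > tol))
    stop(sprintf("window score rows must sum to 1 (max deviation %.3g)",
                 max(abs(rs - 1))))
  structure(list(scores = scores, true_label = true_label),
            class = "window_predictions")
}

#' @export
print.window_predictions <- function(x, ...) {
  cat(sprintf("<window_predictions> %d windows x %d classes, true label %s\n",
              nrow(x$scores), ncol(x$scores), format(x$true_label)))
  invisible(x)
}

#' Chance-level accuracy of uniform guessing
#'
#' @param n_classes Number of classes (>= 1).
#' @return `1 / n_classes`; for the 10-song task this is 0.1.
#' @export
#' @examples
#' chance_level(10)
chance_level <- function(n_classes) {
  if (!is.numeric(n_classes) || length(n_classes) != 1L || n_classes < 1)
    stop("`n_classes` must be a positive integer")
  1 / n_classes
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards, so seeded helpers do not clobber the session
# stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
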