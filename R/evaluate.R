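#' Sliding-window softmax scores over a long excerpt
#'
#' Slides overlapping windows (default 3 s at a 1-s stride) over an EEG
#' excerpt and scores each with the fitted classifier: an L-second
#' excerpt yields `L - window + 1` windows at a 1-s stride (a 5-s
#' excerpt yields three).
#'
#' @param fit A [predann_fit()] result.
#' @param excerpt An [eeg_recording()], or a numeric matrix at the
#'   fitted EEG rate.
#' @param window_seconds,stride_seconds Window and stride (defaults 3, 1).
#' @param true_label Zero-based true class; taken from the recording's
#'   `song_id` when available.
#' @return A [window_predictions()].
#' @export
sliding_window_scores <- function(fit, excerpt, window_seconds = 3,
                                  stride_seconds = 1, true_label = NA) {
  stopifnot(inherits(fit, "predann_fit"))
  if (inherits(excerpt, "eeg_recording")) {
    if (is.na(true_label)) true_label <- as.numeric(excerpt$song_id)
    excerpt <- excerpt$data
  }
  fs <- fit$fs_eeg
  w <- round(window_seconds * fs)
  if (ncol(excerpt) < w)
    stop(sprintf("excerpt (%d samples) shorter than window (%d)",
                 ncol(excerpt), w))
  wins <- extract_windows(excerpt, w, max(round(stride_seconds * fs), 1L))
  window_predictions(predict(fit, wins, type = "prob"),
                     true_label = true_label)
}

new_aggregation_result <- function(method, evidence) {
  k <- unname(which.max(evidence)) - 1L   # ties: lowest class index
  structure(list(method = method, predicted_class = k,
                 per_class_evidence = as.numeric(evidence)),
            class = "aggregation_result")
}

#' @export
print.aggregation_result <- function(x, ...) {
  cat(sprintf("<aggregation_result> method=%s, predicted class %d\n",
              x$method, x$predicted_class))
  invisible(x)
}

#' Mean aggregation of window scores
#'
#' Per-class evidence is the column-wise mean of the window softmax
#' scores; the prediction is its argmax, so windows with sharper
#' (higher-confidence) scores weigh in proportionally.
#'
#' @param wp A [window_predictions()].
#' @return An `"aggregation_result"`.
#' @export
aggregate_mean <- function(wp) {
  stopifnot(inherits(wp, "window_predictions"))
  new_aggregation_result("mean", colMeans(wp$scores))
}

#' Max aggregation of window scores
#'
#' Per-class evidence is the column-wise maximum over windows; the
#' prediction is the class holding the single highest score anywhere in
#' the score matrix, so one highly confident window decides the excerpt.
#'
#' @param wp A [window_predictions()].
#' @return An `"aggregation_result"`.
#' @export
aggregate_max <- function(wp) {
  stopifnot(inherits(wp, "window_predictions"))
  new_aggregation_result("max", apply(wp$scores, 2L, max))
}

#' Majority aggregation of window scores
#'
#' Each window first votes for its argmax class; the excerpt prediction
#' is the modal vote.  Ties are broken by the earliest window whose
#' prediction is among the tied classes (so with three windows voting
#' 8, 0, 7 the prediction is 8).
#'
#' @param wp A [window_predictions()].
#' @return An `"aggregation_result"`; `per_class_evidence` holds vote
#'   counts.
#' @export
aggregate_majority <- function(wp) {
  stopifnot(inherits(wp, "window_predictions"))
  votes <- max.col(wp$scores, ties.method = "first") - 1L
  counts <- tabulate(votes + 1L, nbins = ncol(wp$scores))
  tied <- which(counts == max(counts)) - 1L
  win <- votes[votes %in% tied][1L]
  res <- structure(list(method = "majority", predicted_class = win,
                        per_class_evidence = as.numeric(counts)),
                   class = "aggregation_result")
  res
}

#' Aggregate window scores by a named method
#'
#' @param wp A [window_predictions()].
#' @param method `"mean"`, `"max"` or `"majority"`.
#' @return An `"aggregation_result"`.
#' @export
aggregate_windows <- function(wp, method = c("mean", "max", "majority")) {
  switch(match.arg(method),
         mean = aggregate_mean(wp),
         max = aggregate_max(wp),
         majority = aggregate_majority(wp))
}

#' McNemar's test on paired binary outcome arrays
#'
#' Compares two classifiers evaluated on the same items: each prediction
#' is marked 1 (correct) or 0 (incorrect) and the test examines only the
#' discordant pairs, `n_01` (A wrong, B right) and `n_10` (A right,
#' B wrong).  The exact method uses the two-sided binomial tail
#' `p = min(1, 2 P(X <= min(n01, n10) | n01 + n10, 1/2))`; the `chi2`
#' method uses the continuity-corrected chi-square statistic
#' `(|n01 - n10| - 1)^2 / (n01 + n10)` on 1 degree of freedom, the
#' large-sample variant whose p-values can underflow to the smallest
#' representable double for very unbalanced counts.
#'
#' @param correct_a,correct_b Equal-length binary (0/1 or logical)
#'   vectors.
#' @param method `"exact"` (default, robust at small discordant counts)
#'   or `"chi2"`.
#' @return An object of class `"mcnemar_result"`: `n_01`, `n_10`,
#'   `statistic`, `p_value`, `method`.
#' @export
#' @examples
#' mcnemar_test(c(1, 0, 0, 1), c(1, 1, 0, 1))$p_value
mcnemar_test <- function(correct_a, correct_b,
                         method = c("exact", "chi2")) {
  method <- match.arg(method)
  a <- as.integer(as.logical(correct_a))
  b <- as.integer(as.logical(correct_b))
  if (length(a) != length(b) || !length(a))
    stop("outcome arrays must have equal positive length")
  n01 <- sum(a == 0L & b == 1L)
  n10 <- sum(a == 1L & b == 0L)
  n <- n01 + n10
  if (method == "exact") {
    stat <- min(n01, n10)
    p <- if (n == 0L) 1 else min(1, 2 * stats::pbinom(stat, n, 0.5))
  } else {
    stat <- if (n == 0L) 0 else (abs(n01 - n10) - 1)^2 / n
    p <- if (n == 0L) 1 else stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  structure(list(n_01 = n01, n_10 = n10, statistic = stat,
                 p_value = p, method = method),
            class = "mcnemar_result")
}

#' @export
print.mcnemar_result <- function(x, ...) {
  cat(sprintf(
    "McNemar %s test: n01=%d, n10=%d, statistic=%g, p=%.4g\n",
    x$method, x$n_01, x$n_10, x$statistic, x$p_value))
  invisible(x)
}

#' Accuracy breakdown over a prediction table
#'
#' Computes overall accuracy plus per-song, per-subject and (when a
#' `length_seconds` column is present) per-evaluation-length accuracies.
#' Within every complete partition the count-weighted mean of the cell
#' accuracies equals the overall accuracy.
#'
#' @param predictions Data frame with columns `predicted`, `true`,
#'   `song`, `subject`, and optionally `length_seconds`.
#' @return An object of class `"accuracy_breakdown"`: `overall`,
#'   `by_song`, `by_subject`, `by_length` (or `NULL`), `n`.
#' @export
accuracy_report <- function(predictions) {
  req <- c("predicted", "true", "song", "subject")
  miss <- setdiff(req, names(predictions))
  if (length(miss))
    stop("missing metadata column(s): ", paste(miss, collapse = ", "))
  if (any(is.na(predictions[req])))
    stop("missing values in prediction metadata")
  ok <- predictions$predicted == predictions$true
  by <- function(key) {
    v <- tapply(ok, predictions[[key]], mean)
    v[order(as.numeric(names(v)))]
  }
  structure(list(
    overall = mean(ok),
    by_song = by("song"),
    by_subject = by("subject"),
    by_length = if ("length_seconds" %in% names(predictions)) by("length_seconds"),
    n = nrow(predictions)),
    class = "accuracy_breakdown")
}

#' @export
print.accuracy_breakdown <- function(x, ...) {
  cat(sprintf("Accuracy over %d predictions: %.3f\n", x$n, x$overall))
  cat("  by song:    ",
      paste(sprintf("%s: %.2f", names(x$by_song), x$by_song),
            collapse = "  "), "\n")
  cat("  by subject: ",
      paste(sprintf("%s: %.2f", names(x$by_subject), x$by_subject),
            collapse = "  "), "\n")
  if (!is.null(x$by_length))
    cat("  by length:  ",
        paste(sprintf("%ss: %.2f", names(x$by_length), x$by_length),
              collapse = "  "), "\n")
  invisible(x)
}

#' Evaluate a fit over a range of evaluation lengths
#'
#' Tiles the fit's validation excerpts into non-overlapping L-second
#' evaluation units for each requested length, scores each unit with
#' overlapping 3-s windows at a 1-s stride, aggregates per unit with
#' each requested method, and returns the full prediction table.  The
#' unit's EEG slice starts at the delay-shifted position so evaluation
#' windows see the same alignment as training windows.
#'
#' @param fit A [predann_fit()] result.
#' @param lengths Evaluation lengths in seconds (default `3:7`).
#' @param methods Aggregation methods to apply.
#' @param window_seconds,stride_seconds Within-unit windowing
#'   (defaults 3, 1).
#' @return Data frame with columns `length_seconds`, `method`,
#'   `predicted`, `true`, `song`, `subject`.
#' @export
evaluate_lengths <- function(fit, lengths = 3:7,
                             methods = c("mean", "max", "majority"),
                             window_seconds = 3, stride_seconds = 1) {
  stopifnot(inherits(fit, "predann_fit"))
  fs <- fit$fs_eeg
  dshift <- round(fit$delay_ms * fs / 1000)
  rows <- list()
  for (ex in fit$val_excerpts) {
    n <- ncol(ex$eeg)
    for (L in lengths) {
      nL <- round(L * fs)
      starts <- seq.int(0L, by = nL, length.out = max((n - dshift) %/% nL, 0L))
      for (s0 in starts) {
        seg <- ex$eeg[, (s0 + dshift + 1L):(s0 + dshift + nL), drop = FALSE]
        wp <- sliding_window_scores(fit, seg, window_seconds, stride_seconds,
                                    true_label = ex$song_id)
        for (m in methods) {
          agg <- aggregate_windows(wp, m)
          rows[[length(rows) + 1L]] <- data.frame(
            length_seconds = L, method = m,
            predicted = agg$predicted_class, true = ex$song_id,
            song = ex$song_id, subject = ex$subject_id)
        }
      }
    }
  }
  do.call(rbind, rows)
}
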