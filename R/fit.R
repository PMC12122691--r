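#' Seed every random stream used by the package
#'
#' Weight initialization, excerpt splitting, window sampling and
#' augmentation all draw from R's global RNG; seeding it once makes a
#' whole training run reproducible (two runs with equal seed and config
#' produce identical loss traces).
#'
#' @param seed Integer seed.
#' @return The seed, invisibly.
#' @export
set_global_seed <- function(seed) {
  set.seed(as.integer(seed))
  invisible(seed)
}

# Preprocess every recording (robust scale, clamp) and cut it into
# excerpts annotated with subject, song and absolute start time.
build_excerpts <- function(recordings, clamp_bound, total_seconds,
                           excerpt_seconds) {
  out <- list()
  for (rec in recordings) {
    total <- if (is.null(total_seconds))
      floor(ncol(rec$data) / rec$fs / excerpt_seconds) * excerpt_seconds
    else total_seconds
    excs <- preprocess_recording(rec, bound = clamp_bound,
                                 total_seconds = total,
                                 excerpt_seconds = excerpt_seconds)
    for (e in excs) {
      out[[length(out) + 1L]] <- list(
        eeg = e$data, fs = e$fs, song_id = as.numeric(rec$song_id),
        subject_id = rec$subject_id,
        t0 = (attr(e, "excerpt_index") - 1L) * excerpt_seconds)
    }
  }
  out
}

# Cut delay-aligned paired training/eval segments from excerpts on a
# stride grid.  `offsets` gives a per-excerpt random clip offset in EEG
# samples (augmentation); audio windows are cut from the stimulus at the
# absolute time of the EEG excerpt.  EEG windows that would cross the
# excerpt end after the delay shift are dropped, not padded.
cut_segments <- function(excerpts, stimuli, window_seconds, delay_ms,
                         fs_audio, stride, offsets = NULL) {
  segs <- list()
  for (k in seq_along(excerpts)) {
    ex <- excerpts[[k]]
    w_e <- round(window_seconds * ex$fs)
    w_a <- round(window_seconds * fs_audio)
    dshift <- round(delay_ms * ex$fs / 1000)
    n <- ncol(ex$eeg)
    off <- if (is.null(offsets)) 0L else offsets[[k]]
    if (n < w_e + dshift + off) {
      warning(sprintf("excerpt %d shorter than window+delay; skipped", k))
      next
    }
    stim <- stimuli[[ex$song_id + 1L]]
    starts <- seq.int(off, n - w_e - dshift, by = stride)
    for (o in starts) {
      a0 <- round((ex$t0 + o / ex$fs) * fs_audio)
      if (a0 + w_a > length(stim$waveform)) next
      segs[[length(segs) + 1L]] <- list(
        eeg = ex$eeg[, (o + dshift + 1L):(o + dshift + w_e), drop = FALSE],
        audio = stim$waveform[(a0 + 1L):(a0 + w_a)],
        label = ex$song_id, subject = ex$subject_id)
    }
  }
  segs
}

# Forward + backward over one paired mini-batch; returns the loss
# breakdown and the gradient tree matching model$params.
batch_step <- function(params, spec, segs, loss_cfg) {
  eeg_list <- lapply(segs, `[[`, "eeg")
  aud_list <- lapply(segs, `[[`, "audio")
  labels <- vapply(segs, `[[`, numeric(1), "label")
  xe <- batch_from_segments(eeg_list, spec$family, "eeg")
  xm <- batch_from_segments(aud_list, spec$family, "music")
  fe <- branch_fwd(params$eeg, spec, xe)
  fm <- branch_fwd(params$music, spec, xm)
  ce <- classification_loss_grad(t(fe$z1), labels)
  cm <- classification_loss_grad(t(fm$z1), labels)
  pa <- predann_loss_grad(t(fm$z2), t(fe$z2), loss_cfg)
  lam <- loss_cfg$lambda_predann
  ge <- branch_bwd(params$eeg, spec, fe, dz1 = t(ce$grad),
                   dz2 = lam * t(pa$dE))
  gm <- branch_bwd(params$music, spec, fm, dz1 = t(cm$grad),
                   dz2 = lam * t(pa$dM))
  list(breakdown = total_loss(ce$loss, cm$loss, pa$loss, loss_cfg),
       grads = list(eeg = ge, music = gm),
       # gradients of the PredANN term alone, for the isolation audit
       audit = list(
         eeg = tree_max_abs(branch_bwd(params$eeg, spec, fe, NULL, t(pa$dE))),
         music = tree_max_abs(branch_bwd(params$music, spec, fm, NULL,
                                         t(pa$dM)))))
}

softmax_rows <- function(x) exp(row_log_softmax(as.matrix(x)))

# EEG-only classification accuracy of `params` on a list of segments.
eeg_accuracy <- function(params, spec, segs) {
  if (!length(segs)) return(NA_real_)
  x <- batch_from_segments(lapply(segs, `[[`, "eeg"), spec$family, "eeg")
  z1 <- branch_fwd(params$eeg, spec, x)$z1
  pred <- apply(z1, 2L, which.max) - 1L
  mean(pred == vapply(segs, `[[`, numeric(1), "label"))
}

#' Fit a paired EEG/music model with the PredANN objective
#'
#' The core fitting routine.  Takes a paired dataset (EEG recordings plus
#' the stimuli they respond to), preprocesses every recording (per-channel
#' robust scaling, clamping to `clamp_bound`), cuts it into
#' `excerpt_seconds` excerpts, performs a seeded stratified
#' train/validation split on the excerpts (stratified by song), and
#' optimizes the total loss `cls_EEG + cls_music + lambda * PredANN` by
#' Adam over mini-batches of delay-aligned paired windows.
#'
#' Each epoch is one pass over the training stride grid
#' (`train_stride` samples) with a fresh random clip offset per excerpt
#' (the sliding-window + random-clipping augmentation, under which every
#' sample position is eventually visited despite the coarse stride).
#' Validation accuracy (EEG branch, argmax over class logits) is
#' measured every `eval_every` epochs on windows cut at `val_stride`,
#' and the best-validation weights are kept.
#'
#' @param data A [simulate_dataset()] result, or any list with elements
#'   `recordings` (list of [eeg_recording()]) and `stimuli` (list of
#'   [audio_stimulus()] indexed by song id).
#' @param encoder An [encoder_spec()]; both branches use it.
#' @param loss A [loss_config()].
#' @param window_seconds Paired window length in seconds (default 3).
#' @param delay_ms Assumed stimulus-to-EEG latency used for alignment
#'   (default 200 ms).
#' @param train_stride Training stride in EEG samples (default 200).
#' @param val_stride Validation stride in EEG samples; default one
#'   window (non-overlapping).  Stride 1 scores every sample position.
#' @param epochs Number of training epochs.
#' @param batch_size Paired segments per optimization step.
#' @param lr Adam learning rate.
#' @param excerpt_seconds Excerpt length for splitting (default 30).
#' @param total_seconds Duration kept per recording; `NULL` keeps the
#'   largest multiple of `excerpt_seconds` available.
#' @param train_fraction Stratified split fraction (default 0.75).
#' @param clamp_bound Post-scaling clamp bound (default 20).
#' @param eval_every Epochs between validation passes.
#' @param seed Integer seed for the whole run.
#' @param verbose Print a line per validation pass.
#' @return An object of class `"predann_fit"`; see the methods
#'   [print.predann_fit()], [summary.predann_fit()],
#'   [predict.predann_fit()], [plot.predann_fit()], [coef.predann_fit()].
#' @export
predann_fit <- function(data,
                        encoder = encoder_spec(),
                        loss = loss_config(),
                        window_seconds = 3, delay_ms = 200,
                        train_stride = 200, val_stride = NULL,
                        epochs = 60, batch_size = 32, lr = 1e-3,
                        excerpt_seconds = 30, total_seconds = NULL,
                        train_fraction = 0.75, clamp_bound = 20,
                        eval_every = 5, seed = 0, verbose = FALSE) {
  stopifnot(inherits(encoder, "encoder_spec"), inherits(loss, "loss_config"))
  if (is.null(data$recordings) || is.null(data$stimuli))
    stop("`data` must contain `recordings` and `stimuli`")
  set_global_seed(seed)
  fs_eeg <- data$recordings[[1L]]$fs
  fs_audio <- data$stimuli[[1L]]$fs
  n_classes <- length(data$stimuli)
  n_ch <- nrow(data$recordings[[1L]]$data)

  excerpts <- build_excerpts(data$recordings, clamp_bound, total_seconds,
                             excerpt_seconds)
  if (!length(excerpts)) stop("no excerpts could be cut from the recordings")
  labels <- vapply(excerpts, `[[`, numeric(1), "song_id")
  sp <- stratified_split(excerpts, train_fraction = train_fraction,
                         seed = seed, labels = labels)
  train_ex <- sp$train; val_ex <- sp$validation
  if (!length(train_ex)) stop("empty training set")

  w_e <- round(window_seconds * fs_eeg)
  if (is.null(val_stride)) val_stride <- w_e
  val_segs <- cut_segments(val_ex, data$stimuli, window_seconds, delay_ms,
                           fs_audio, stride = val_stride)

  model <- init_predann_model(encoder, n_classes, n_ch, seed = seed)
  params <- model$params
  opt <- adam_init(params)
  trace <- vector("list", epochs)
  val_trace <- list()
  best <- list(acc = -Inf, params = params, epoch = 0L)
  audit <- NULL

  for (ep in seq_len(epochs)) {
    offsets <- sample.int(train_stride, length(train_ex),
                          replace = TRUE) - 1L
    segs <- cut_segments(train_ex, data$stimuli, window_seconds, delay_ms,
                         fs_audio, stride = train_stride, offsets = offsets)
    if (!length(segs)) stop("no training segments; window too long?")
    ord <- sample(length(segs))
    sums <- c(cls_eeg = 0, cls_music = 0, predann = 0, total = 0)
    n_seen <- 0L
    for (b in split(ord, ceiling(seq_along(ord) / batch_size))) {
      st <- batch_step(params, encoder, segs[b], loss)
      if (!is.finite(st$breakdown$total))
        stop(sprintf("training diverged (non-finite loss) at epoch %d", ep))
      if (is.null(audit)) audit <- st$audit
      upd <- adam_step(params, st$grads, opt, lr = lr)
      params <- upd$params; opt <- upd$state
      sums <- sums + unlist(st$breakdown)[names(sums)]
      n_seen <- n_seen + length(b)
    }
    trace[[ep]] <- c(epoch = ep, sums / n_seen)
    if (ep %% eval_every == 0L || ep == epochs) {
      acc <- eeg_accuracy(params, encoder, val_segs)
      val_trace[[length(val_trace) + 1L]] <- c(epoch = ep, accuracy = acc)
      if (!is.na(acc) && acc > best$acc)
        best <- list(acc = acc, params = params, epoch = ep)
      if (verbose)
        message(sprintf("epoch %4d  loss %.4f  val acc %.3f",
                        ep, sums[["total"]] / n_seen, acc))
    }
  }

  model$params <- best$params
  structure(list(
    model = model, final_params = params,
    loss_trace = as.data.frame(do.call(rbind, trace)),
    val_trace = as.data.frame(do.call(rbind, val_trace)),
    best_val_accuracy = best$acc, best_epoch = best$epoch,
    gradient_audit = audit,
    n_classes = n_classes, fs_eeg = fs_eeg, fs_audio = fs_audio,
    window_seconds = window_seconds, delay_ms = delay_ms,
    excerpt_seconds = excerpt_seconds,
    loss_config = loss, encoder = encoder, seed = seed,
    train_excerpts = train_ex, val_excerpts = val_ex,
    stimuli = data$stimuli,
    call = match.call()),
    class = "predann_fit")
}
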