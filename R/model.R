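#' Specify a convolutional encoder
#'
#' Both modalities use structurally identical encoders from one of two
#' families: `cnn1d` treats the input as a multichannel 1-D sequence
#' (EEG channels are convolution channels), `cnn2d` treats it as a
#' single-channel 2-D grid (EEG: channels x time; audio: a height-1
#' grid, so 2-D kernels act purely temporally).  All convolutions use
#' kernel 3, stride 1, padding 1, which preserves spatial and temporal
#' extents exactly; each block follows the convolution with a rectifier
#' and a factor-2 max-pool, and the last block feeds global average
#' pooling.
#'
#' @param family `"cnn1d"` or `"cnn2d"`.
#' @param channels_per_block Integer vector of feature-map counts, one
#'   per block (default `c(32, 64, 64, 128)`).
#' @param kernel_size Convolution kernel (fixed at 3).
#' @param padding Convolution padding (fixed at 1).
#' @param embedding_dim Width of the contrastive embedding produced by
#'   Projector II (default 128).
#' @return An object of class `"encoder_spec"`.
#' @export
encoder_spec <- function(family = c("cnn1d", "cnn2d"),
                         channels_per_block = c(32, 64, 64, 128),
                         kernel_size = 3, padding = 1,
                         embedding_dim = 128) {
  family <- match.arg(family)
  if (kernel_size != 3 || padding != 1)
    stop("only the shape-preserving kernel 3 / padding 1 convention is supported")
  if (length(channels_per_block) < 1L || any(channels_per_block < 1))
    stop("`channels_per_block` must be a positive integer vector")
  structure(list(family = family,
                 n_blocks = length(channels_per_block),
                 channels_per_block = as.integer(channels_per_block),
                 kernel_size = 3L, padding = 1L,
                 embedding_dim = as.integer(embedding_dim)),
            class = "encoder_spec")
}

#' @export
print.encoder_spec <- function(x, ...) {
  cat(sprintf("<encoder_spec> %s, %d blocks [%s], k=3 p=1, embedding %d\n",
              x$family, x$n_blocks,
              paste(x$channels_per_block, collapse = ", "),
              x$embedding_dim))
  invisible(x)
}

# Initialize one encoder branch (conv blocks + Projector I + Projector II).
# Projector I is a linear class head; Projector II is one hidden rectified
# layer followed by a linear map to the contrastive embedding.
init_branch <- function(spec, in_channels, n_classes) {
  taps <- if (spec$family == "cnn1d") 3L else 9L
  prev <- in_channels
  blocks <- lapply(spec$channels_per_block, function(ch) {
    blk <- list(w = init_weight(ch, taps * prev), b = numeric(ch))
    prev <<- ch
    blk
  })
  width <- prev
  hid <- spec$embedding_dim
  list(blocks = blocks,
       proj1 = list(w = init_weight(n_classes, width), b = numeric(n_classes)),
       proj2 = list(w1 = init_weight(hid, width), b1 = numeric(hid),
                    w2 = init_weight(spec$embedding_dim, hid),
                    b2 = numeric(spec$embedding_dim)))
}

#' Initialize a paired two-branch model
#'
#' Builds the EEG branch and the music branch: two structurally identical
#' encoders per `spec`, each feeding Projector I (class logits over
#' `n_classes` songs) and Projector II (contrastive embedding).  The
#' branches share no parameters.
#'
#' @param spec An [encoder_spec()] shared structurally by both branches.
#' @param n_classes Number of song classes.
#' @param eeg_channels Number of EEG channels (used by `cnn1d` as input
#'   channels; `cnn2d` treats them as the grid height).
#' @param seed Integer seed for weight initialization.
#' @return An object of class `"predann_model"`.
#' @export
init_predann_model <- function(spec, n_classes, eeg_channels, seed = 0) {
  stopifnot(inherits(spec, "encoder_spec"))
  in_eeg <- if (spec$family == "cnn1d") eeg_channels else 1L
  in_music <- 1L
  params <- with_seed(seed, list(
    eeg = init_branch(spec, in_eeg, n_classes),
    music = init_branch(spec, in_music, n_classes)))
  structure(list(params = params, spec = spec,
                 n_classes = as.integer(n_classes),
                 eeg_channels = as.integer(eeg_channels), seed = seed),
            class = "predann_model")
}

#' @export
print.predann_model <- function(x, ...) {
  pc <- parameter_count(x)
  cat(sprintf(
    "<predann_model> %s encoders, %d classes, %d EEG channels; parameters: EEG branch %d, music branch %d\n",
    x$spec$family, x$n_classes, x$eeg_channels, pc["eeg"], pc["music"]))
  invisible(x)
}

#' Per-branch parameter counts
#'
#' @param model A `"predann_model"`.
#' @return Named integer vector with elements `eeg` and `music`.
#' @export
parameter_count <- function(model) {
  c(eeg = as.integer(tree_n_params(model$params$eeg)),
    music = as.integer(tree_n_params(model$params$music)))
}

# Convert a list of equally-shaped segments (matrices for EEG, vectors
# for audio) into the batch array layout the encoder family expects.
batch_from_segments <- function(segments, family, modality) {
  B <- length(segments)
  if (modality == "eeg") {
    C <- nrow(segments[[1L]]); Tn <- ncol(segments[[1L]])
    x <- array(unlist(segments, use.names = FALSE), c(C, Tn, B))
    if (family == "cnn2d") x <- array(x, c(1L, C, Tn, B))
  } else {
    Tn <- length(segments[[1L]])
    x <- array(unlist(segments, use.names = FALSE), c(1L, Tn, B))
    if (family == "cnn2d") x <- array(x, c(1L, 1L, Tn, B))
  }
  x
}

# Forward one branch.  Returns features, both projector outputs
# ([n_classes x B] and [d x B]) and the caches needed for backward.
branch_fwd <- function(branch, spec, x) {
  caches <- vector("list", spec$n_blocks)
  conv_f <- if (spec$family == "cnn1d") conv1d_fwd else conv2d_fwd
  pool_f <- if (spec$family == "cnn1d") pool1d_fwd else pool2d_fwd
  for (i in seq_len(spec$n_blocks)) {
    cv <- conv_f(x, branch$blocks[[i]]$w, branch$blocks[[i]]$b)
    rl <- relu_fwd(cv$out)
    pl <- pool_f(rl$out)
    caches[[i]] <- list(conv = cv$cache, relu = rl$cache, pool = pl$cache)
    x <- pl$out
  }
  gp <- gap_fwd(x)
  p1 <- linear_fwd(gp$out, branch$proj1$w, branch$proj1$b)
  h <- linear_fwd(gp$out, branch$proj2$w1, branch$proj2$b1)
  hr <- relu_fwd(h$out)
  p2 <- linear_fwd(hr$out, branch$proj2$w2, branch$proj2$b2)
  list(feat = gp$out, z1 = p1$out, z2 = p2$out,
       caches = list(blocks = caches, gap = gp$cache, p1 = p1$cache,
                     h = h$cache, hrelu = hr$cache, p2 = p2$cache))
}

# Backward one branch given upstream gradients on the two projector
# outputs ([n_classes x B], [d x B]); either may be NULL (treated as 0).
branch_bwd <- function(branch, spec, fw, dz1, dz2) {
  g <- list(blocks = vector("list", spec$n_blocks),
            proj1 = list(w = branch$proj1$w * 0, b = branch$proj1$b * 0),
            proj2 = list(w1 = branch$proj2$w1 * 0, b1 = branch$proj2$b1 * 0,
                         w2 = branch$proj2$w2 * 0, b2 = branch$proj2$b2 * 0))
  dfeat <- fw$feat * 0
  if (!is.null(dz1)) {
    l1 <- linear_bwd(dz1, fw$caches$p1)
    g$proj1$w <- l1$dw; g$proj1$b <- l1$db
    dfeat <- dfeat + l1$dx
  }
  if (!is.null(dz2)) {
    l2 <- linear_bwd(dz2, fw$caches$p2)
    g$proj2$w2 <- l2$dw; g$proj2$b2 <- l2$db
    dh <- relu_bwd(l2$dx, fw$caches$hrelu)
    lh <- linear_bwd(dh, fw$caches$h)
    g$proj2$w1 <- lh$dw; g$proj2$b1 <- lh$db
    dfeat <- dfeat + lh$dx
  }
  dx <- gap_bwd(dfeat, fw$caches$gap)
  conv_b <- if (spec$family == "cnn1d") conv1d_bwd else conv2d_bwd
  pool_b <- if (spec$family == "cnn1d") pool1d_bwd else pool2d_bwd
  for (i in rev(seq_len(spec$n_blocks))) {
    ck <- fw$caches$blocks[[i]]
    dx <- pool_b(dx, ck$pool)
    dx <- relu_bwd(dx, ck$relu)
    cb <- conv_b(dx, ck$conv)
    g$blocks[[i]] <- list(w = cb$dw, b = cb$db)
    dx <- cb$dx
  }
  g
}

#' Encode a batch of segments with one branch
#'
#' Runs one modality's encoder and projectors on a list of equally-shaped
#' segments.  Deterministic given fixed weights.
#'
#' @param model A `"predann_model"`.
#' @param segments List of EEG matrices (channels x time) or audio
#'   vectors, all the same shape.
#' @param modality `"eeg"` or `"music"`.
#' @return List with `features` (`B x width`), `logits`
#'   (`B x n_classes`) and `embedding` (`B x d`), rows in input order.
#' @export
encode <- function(model, segments, modality = c("eeg", "music")) {
  modality <- match.arg(modality)
  stopifnot(inherits(model, "predann_model"))
  if (!length(segments)) stop("empty segment list")
  if (modality == "eeg") {
    ch <- vapply(segments, nrow, integer(1))
    if (any(ch != model$eeg_channels))
      stop(sprintf("EEG segments must have %d channels (got %s)",
                   model$eeg_channels, paste(unique(ch), collapse = ",")))
  }
  x <- batch_from_segments(segments, model$spec$family, modality)
  fw <- branch_fwd(model$params[[modality]], model$spec, x)
  list(features = t(fw$feat), logits = t(fw$z1), embedding = t(fw$z2))
}

#' Forward both branches on a paired batch
#'
#' Computes the four projector outputs for a mini-batch of paired
#' segments: EEG class logits `z_E_I`, EEG contrastive embedding
#' `z_E_II`, music class logits `z_M_I`, and music contrastive embedding
#' `z_M_II` (all `B x .` matrices, row i of both modalities sharing a
#' song).  The two branches share no parameters.
#'
#' @param model A `"predann_model"`.
#' @param eeg_segments List of EEG matrices (channels x time).
#' @param audio_segments List of audio vectors, same length as
#'   `eeg_segments`.
#' @param labels_eeg,labels_music Zero-based class vectors of length B.
#' @param strict Validate that paired labels agree.
#' @return An object of class `"embedding_batch"`: list with `z_E_I`,
#'   `z_E_II`, `z_M_I`, `z_M_II`, `labels_E`, `labels_M`, `B`.
#' @export
forward_pair <- function(model, eeg_segments, audio_segments,
                         labels_eeg = NULL, labels_music = labels_eeg,
                         strict = TRUE) {
  stopifnot(inherits(model, "predann_model"))
  if (length(eeg_segments) != length(audio_segments))
    stop(sprintf("batch sizes differ: %d EEG vs %d audio segments",
                 length(eeg_segments), length(audio_segments)))
  if (strict && !is.null(labels_eeg) && !is.null(labels_music) &&
      any(labels_eeg != labels_music))
    stop("paired batch has mismatched EEG/music labels")
  e <- encode(model, eeg_segments, "eeg")
  m <- encode(model, audio_segments, "music")
  structure(list(z_E_I = e$logits, z_E_II = e$embedding,
                 z_M_I = m$logits, z_M_II = m$embedding,
                 labels_E = labels_eeg, labels_M = labels_music,
                 B = length(eeg_segments)),
            class = "embedding_batch")
}
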