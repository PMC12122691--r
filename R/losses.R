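#' Loss configuration
#'
#' @param lambda_predann Non-negative weight of the PredANN term in the
#'   total loss (0 recovers the classification-only baseline; 0.05 is the
#'   default operating point).
#' @param temperature Positive InfoNCE temperature dividing cosine
#'   similarities before the softmax (default 0.1, constant, not
#'   learned).
#' @param stop_gradient Block gradients through the music embeddings in
#'   the PredANN term (default `TRUE`); `FALSE` is the
#'   "stop-gradient-free" ablation.
#' @return An object of class `"loss_config"`.
#' @export
loss_config <- function(lambda_predann = 0.05, temperature = 0.1,
                        stop_gradient = TRUE) {
  if (lambda_predann < 0) stop("`lambda_predann` must be >= 0")
  if (!is.numeric(temperature) || temperature <= 0)
    stop("`temperature` must be strictly positive")
  structure(list(lambda_predann = lambda_predann, temperature = temperature,
                 stop_gradient = isTRUE(stop_gradient)),
            class = "loss_config")
}

# Numerically stable log-softmax over the rows of a matrix.
row_log_softmax <- function(x) {
  m <- apply(x, 1L, max)
  s <- x - m
  s - log(rowSums(exp(s)))
}

#' Summed cross-entropy classification loss
#'
#' `sum_i CE(softmax(logits_i), label_i)` over the batch (summed, not
#' averaged, matching the summation convention of the paired
#' classification objective).
#'
#' @param logits Numeric matrix `B x K` of unnormalized class scores.
#' @param labels Zero-based integer class vector of length B.
#' @return Non-negative scalar loss.
#' @export
#' @examples
#' classification_loss(matrix(0, 1, 10), 0)  # log(10)
classification_loss <- function(logits, labels) {
  logits <- as.matrix(logits)
  K <- ncol(logits)
  if (length(labels) != nrow(logits))
    stop("labels/logits batch size mismatch")
  if (any(labels < 0 | labels >= K))
    stop(sprintf("labels must lie in [0, %d)", K))
  ls <- row_log_softmax(logits)
  -sum(ls[cbind(seq_len(nrow(logits)), labels + 1L)])
}

# Loss plus gradient w.r.t. logits (softmax minus one-hot, summed form).
classification_loss_grad <- function(logits, labels) {
  ls <- row_log_softmax(logits)
  p <- exp(ls)
  idx <- cbind(seq_len(nrow(logits)), labels + 1L)
  g <- p
  g[idx] <- g[idx] - 1
  list(loss = -sum(ls[idx]), grad = g)
}

#' Cosine similarity of two vectors
#'
#' @param u,v Nonzero numeric vectors of equal length.
#' @return `u . v / (|u| |v|)` in `[-1, 1]`.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stop("vectors must have equal length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine similarity undefined for a zero vector")
  sum(u * v) / (nu * nv)
}

# Row-normalize a matrix to unit Euclidean norm; errors on zero rows.
row_unit <- function(x, what) {
  n <- sqrt(rowSums(x^2))
  if (any(n == 0)) stop(sprintf("zero row(s) in %s embeddings", what))
  list(unit = x / n, norm = n)
}

#' PredANN contrastive loss
#'
#' The symmetric two-term InfoNCE objective on cosine similarities
#' between the music and EEG contrastive embeddings,
#' `s_ij = sim(sg(z_M_II,i), z_E_II,j) / tau`: for each pair i the
#' matched (diagonal) similarity is scored against all in-batch EEG
#' candidates (first term) and against all in-batch music anchors (second
#' term), and the two log-softmax diagonals are summed over the batch and
#' negated.  All off-diagonal pairs act as negatives regardless of their
#' class labels.  With `cfg$stop_gradient` the gradient with respect to
#' the music embeddings (and everything upstream of them) is identically
#' zero, so the term only trains the EEG branch to predict the music
#' representations.
#'
#' @param z_M_II,z_E_II Numeric matrices `B x d` of music and EEG
#'   contrastive embeddings (paired rows), no zero rows.
#' @param cfg A [loss_config()].
#' @return Non-negative scalar loss (0 when B = 1).
#' @export
predann_loss <- function(z_M_II, z_E_II, cfg = loss_config()) {
  predann_loss_grad(z_M_II, z_E_II, cfg, want_grad = FALSE)$loss
}

# Loss plus gradients with respect to both embedding blocks.  dM is an
# all-zero matrix when cfg$stop_gradient is TRUE.
predann_loss_grad <- function(z_M_II, z_E_II, cfg = loss_config(),
                              want_grad = TRUE) {
  z_M_II <- as.matrix(z_M_II); z_E_II <- as.matrix(z_E_II)
  if (!all(dim(z_M_II) == dim(z_E_II)))
    stop("embedding blocks must have identical shapes")
  B <- nrow(z_M_II)
  if (B < 1L) stop("batch must contain at least one pair")
  m <- row_unit(z_M_II, "music"); e <- row_unit(z_E_II, "EEG")
  S <- (m$unit %*% t(e$unit)) / cfg$temperature   # s_ij = sim(m_i, e_j)/tau
  lr <- row_log_softmax(S)              # softmax over EEG candidates j
  lc <- t(row_log_softmax(t(S)))        # softmax over music anchors (col i)
  diag_idx <- cbind(seq_len(B), seq_len(B))
  loss <- -sum(lr[diag_idx]) - sum(lc[diag_idx])
  if (!want_grad) return(list(loss = loss))
  Pr <- exp(lr); Pc <- exp(lc)
  G <- Pr + Pc
  G[diag_idx] <- G[diag_idx] - 2
  G <- G / cfg$temperature              # dL/dS_ij (pre-temperature scale)
  # chain through cosine normalization
  dE_unit <- t(G) %*% m$unit
  dE <- (dE_unit - e$unit * rowSums(dE_unit * e$unit)) / e$norm
  if (cfg$stop_gradient) {
    dM <- z_M_II * 0
  } else {
    dM_unit <- G %*% e$unit
    dM <- (dM_unit - m$unit * rowSums(dM_unit * m$unit)) / m$norm
  }
  list(loss = loss, dE = dE, dM = dM)
}

#' Assemble the total training loss
#'
#' `total = cls_eeg + cls_music + lambda * predann`: the two
#' classification losses plus the weighted PredANN term.  With
#' `lambda_predann = 0` this is the classification-only baseline used as
#' the ablation reference.
#'
#' @param cls_eeg,cls_music,predann Finite loss components.
#' @param cfg A [loss_config()].
#' @return An object of class `"loss_breakdown"`: list with `cls_eeg`,
#'   `cls_music`, `predann`, `total`.
#' @export
total_loss <- function(cls_eeg, cls_music, predann, cfg = loss_config()) {
  parts <- c(cls_eeg = cls_eeg, cls_music = cls_music, predann = predann)
  if (any(!is.finite(parts)))
    stop("non-finite loss component: ",
         paste(names(parts)[!is.finite(parts)], collapse = ", "))
  structure(list(cls_eeg = cls_eeg, cls_music = cls_music,
                 predann = predann,
                 total = cls_eeg + cls_music + cfg$lambda_predann * predann),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf(
    "<loss_breakdown> total %.4f (clsE %.4f + clsM %.4f + predann %.4f)\n",
    x$total, x$cls_eeg, x$cls_music, x$predann))
  invisible(x)
}
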