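# Shared builders for tiny, fast fixtures.  Everything is generated in
# code; nothing is read from disk.

# A miniature synthetic study: 3 classes, 1 subject, 4 channels, short
# recordings.  Small enough that a fit runs in a few seconds.
tiny_config <- function(...) {
  defaults <- list(n_classes = 3, n_subjects = 1, n_channels = 4,
                   fs_eeg = 125, duration_seconds = 24, delay_ms = 200,
                   snr_db = 20, seed = 1)
  do.call(synthetic_config, utils::modifyList(defaults, list(...)))
}

tiny_encoder <- function(family = "cnn1d") {
  encoder_spec(family = family, channels_per_block = c(4, 8),
               embedding_dim = 8)
}

# Fit on the miniature study with few epochs; arguments override
# defaults.  Excerpts are 8 s so the 24-s recordings give 3 each.
tiny_fit <- function(epochs = 3, lambda = 0.05, stop_gradient = TRUE,
                     seed = 1, ...) {
  ds <- simulate_dataset(tiny_config())
  predann_fit(ds, encoder = tiny_encoder(),
              loss = loss_config(lambda_predann = lambda,
                                 stop_gradient = stop_gradient),
              epochs = epochs, batch_size = 16, excerpt_seconds = 8,
              train_fraction = 2 / 3, eval_every = max(epochs, 1),
              seed = seed, ...)
}

# Brute-force evaluation of the symmetric InfoNCE objective by explicit
# double loops over pairwise cosine similarities -- the independent
# oracle for predann_loss.
brute_force_predann <- function(M, E, tau) {
  B <- nrow(M)
  total <- 0
  for (i in seq_len(B)) {
    pos <- exp(cosine_similarity(M[i, ], E[i, ]) / tau)
    den_e <- sum(vapply(seq_len(B), function(j)
      exp(cosine_similarity(M[i, ], E[j, ]) / tau), numeric(1)))
    den_m <- sum(vapply(seq_len(B), function(j)
      exp(cosine_similarity(M[j, ], E[i, ]) / tau), numeric(1)))
    total <- total - log(pos / den_e) - log(pos / den_m)
  }
  total
}

# Central finite-difference gradient of scalar-valued f at x (an array),
# used to audit analytic backward passes.
numerical_grad <- function(f, x, eps = 1e-6) {
  g <- array(0, dim(as.array(x)))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# Results of the desk-scale experiments are computed once per test run
# and shared across acceptance assertions.
.experiment_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .experiment_cache))
    assign(key, expr, envir = .experiment_cache)
  get(key, envir = .experiment_cache)
}
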