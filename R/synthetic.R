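#' Configuration for the synthetic paired EEG/audio generator
#'
#' Describes a simulated listening study: `n_classes` distinct stimuli
#' ("songs"), `n_subjects` listeners, multichannel EEG responses at
#' `fs_eeg` with a fixed stimulus-to-response latency `delay_ms` and
#' additive noise at `snr_db`.  Defaults mirror the shape of a
#' naturalistic music-listening EEG study scaled to desk size; the full
#' shape (20 subjects, 10 songs, 128 channels, 125 Hz) is reachable by
#' changing the counts.
#'
#' @param n_classes Number of stimulus classes (>= 2).
#' @param n_subjects Number of simulated subjects (>= 1).
#' @param n_channels EEG channels per subject (>= 1).
#' @param fs_eeg EEG sampling rate in Hz (default 125).
#' @param fs_audio Audio sampling rate in Hz (default equal to `fs_eeg`
#'   so paired windows have equal sample counts).
#' @param duration_seconds Length of each stimulus/recording.
#' @param delay_ms Generating stimulus-to-EEG latency in ms (default 200,
#'   the physiologically motivated optimum for auditory encoding).
#' @param snr_db Per-channel signal-to-noise power ratio in dB.
#' @param seed Integer seed; generation is a pure function of the config.
#' @param noise `"white"` (default) or `"pink"` channel noise.
#' @return An object of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_classes = 5, n_subjects = 2, n_channels = 8,
                             fs_eeg = 125, fs_audio = fs_eeg,
                             duration_seconds = 60, delay_ms = 200,
                             snr_db = 10, seed = 0, noise = c("white", "pink")) {
  noise <- match.arg(noise)
  stopifnot(n_classes >= 2, n_subjects >= 1, n_channels >= 1,
            fs_eeg > 0, fs_audio > 0, duration_seconds > 0, delay_ms >= 0)
  structure(list(
    n_classes = as.integer(n_classes), n_subjects = as.integer(n_subjects),
    n_channels = as.integer(n_channels), fs_eeg = fs_eeg,
    fs_audio = fs_audio, duration_seconds = duration_seconds,
    delay_ms = delay_ms, snr_db = snr_db, seed = as.integer(seed),
    noise = noise), class = "synthetic_config")
}

#' Generate the bank of class-distinct stimuli
#'
#' Each class k gets a sinusoidal carrier at a class-specific frequency
#' (linearly spaced from 5 Hz to 60% of Nyquist), amplitude-modulated at
#' a class-specific rate (log-spaced from 1.5 to 12 Hz) and by a slowly
#' varying seeded random envelope.  Carriers separate classes
#' spectrally; the modulation rates separate their envelopes (the
#' feature the simulated cortex encodes); the random envelope makes each
#' stimulus non-stationary so that different time windows carry
#' different content.
#'
#' @param cfg A [synthetic_config()].
#' @return List of `n_classes` [audio_stimulus()] objects, song ids
#'   `0 .. n_classes-1`.
#' @export
generate_stimulus_bank <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  n <- round(cfg$duration_seconds * cfg$fs_audio)
  t <- (seq_len(n) - 1L) / cfg$fs_audio
  nyq <- cfg$fs_audio / 2
  lapply(seq_len(cfg$n_classes) - 1L, function(k) {
    f_k <- 5 + (k * (nyq * 0.6 - 5)) / max(cfg$n_classes - 1L, 1L)
    r_k <- 1.5 * (12 / 1.5)^(k / max(cfg$n_classes - 1L, 1L))
    am <- 0.55 + 0.45 * sin(2 * pi * r_k * t + k)
    slow <- with_seed(cfg$seed * 131 + k, stats::rnorm(n))
    slow <- moving_average(slow, max(round(cfg$fs_audio), 3L))
    slow <- 1 + 0.6 * slow / max(stats::sd(slow), 1e-12)
    slow <- pmax(slow, 0.1)
    w <- am * slow * sin(2 * pi * f_k * t)
    audio_stimulus(w / max(abs(w)), cfg$fs_audio, song_id = k)
  })
}

# Centered moving average with reflected edges (no NA at boundaries).
moving_average <- function(x, width) {
  width <- max(as.integer(width), 1L)
  half <- width %/% 2L
  xp <- c(rev(x[seq_len(half)]), x, rev(x[(length(x) - half + 1L):length(x)]))
  f <- stats::filter(xp, rep(1 / width, width), sides = 2)
  as.numeric(f[(half + 1L):(half + length(x))])
}

#' Stimulus envelope as encoded by the simulated cortex
#'
#' Rectify, smooth with a short moving average (passband wide enough to
#' keep the class-specific modulation rates), then convolve with a fixed
#' causal 3-tap temporal kernel -- the simplest
#' temporal-response-function-like forward model under which the latency
#' is identifiable.
#'
#' @param waveform Numeric stimulus vector.
#' @param fs Sampling rate of the waveform in Hz.
#' @return Numeric envelope, same length, standardized to unit variance.
#' @export
stimulus_envelope <- function(waveform, fs) {
  env <- moving_average(abs(waveform), max(round(fs / 25), 3L))
  k <- c(0.5, 0.3, 0.2)
  out <- k[1] * env
  out[-1] <- out[-1] + k[2] * env[-length(env)]
  out[-(1:2)] <- out[-(1:2)] + k[3] * env[1:(length(env) - 2L)]
  out <- out - mean(out)
  out / max(stats::sd(out), 1e-12)
}

# Subject-specific channel mixing weights, drawn once per subject.
subject_mixing <- function(cfg, subject) {
  with_seed(cfg$seed * 7919 + subject * 104729,
            stats::rnorm(cfg$n_channels))
}

# Pink (1/f) noise of length n via spectral shaping of white noise.
pink_noise <- function(n) {
  w <- stats::rnorm(n)
  sp <- stats::fft(w)
  f <- c(1, seq_len(n - 1L))
  f <- pmin(f, n - f + 1)  # symmetric frequency index
  sp <- sp / sqrt(f)
  x <- Re(stats::fft(sp, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Simulate one subject's EEG response to a stimulus
#'
#' The recording is a subject-specific channel mixing of the
#' latency-shifted stimulus envelope transform plus per-channel noise
#' scaled so the empirical per-channel signal-to-noise power ratio equals
#' `cfg$snr_db` (within sampling error, < 0.5 dB at these lengths).
#' The envelope is shifted later by `delay_ms`; samples before the first
#' delayed response are zero (no pre-stimulus response).
#'
#' @param stim An [audio_stimulus()].
#' @param cfg A [synthetic_config()].
#' @param subject Subject index (1-based).
#' @return An [eeg_recording()] with `n_channels` rows at `fs_eeg`.
#' @export
simulate_eeg_response <- function(stim, cfg, subject = 1L) {
  stopifnot(inherits(stim, "audio_stimulus"), inherits(cfg, "synthetic_config"))
  env <- stimulus_envelope(stim$waveform, stim$fs)
  n_eeg <- round(cfg$duration_seconds * cfg$fs_eeg)
  if (stim$fs != cfg$fs_eeg) {  # bring envelope to the EEG rate
    env <- stats::spline(seq_along(env), env,
                         xout = seq(1, length(env), length.out = n_eeg))$y
  }
  d <- round(cfg$delay_ms * cfg$fs_eeg / 1000)
  shifted <- c(numeric(d), env)[seq_len(n_eeg)]
  a <- subject_mixing(cfg, subject)
  sig <- outer(a, shifted)                      # channels x samples
  sig_pow <- rowMeans(sig^2)
  noise_sd <- sqrt(sig_pow / 10^(cfg$snr_db / 10))
  noise <- with_seed(
    cfg$seed * 31 + subject * 1009 + as.numeric(stim$song_id) * 97,
    {
      m <- if (cfg$noise == "pink")
        t(replicate(cfg$n_channels, pink_noise(n_eeg)))
      else matrix(stats::rnorm(cfg$n_channels * n_eeg), cfg$n_channels)
      m * noise_sd
    })
  eeg_recording(sig + noise, cfg$fs_eeg, subject_id = subject,
                song_id = stim$song_id)
}

#' Simulate a full paired dataset
#'
#' One recording per (subject, song) pair, plus the stimulus bank and the
#' generating ground truth.  Generation is a pure function of the config.
#'
#' @param cfg A [synthetic_config()].
#' @return An object of class `"synthetic_dataset"`: list with `stimuli`
#'   (length `n_classes`), `recordings` (length
#'   `n_subjects * n_classes`), `ground_truth` (data frame of subject,
#'   song, delay_ms, snr_db), and `config`.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  stimuli <- generate_stimulus_bank(cfg)
  recs <- list()
  gt <- list()
  i <- 0L
  for (s in seq_len(cfg$n_subjects)) {
    for (stim in stimuli) {
      i <- i + 1L
      recs[[i]] <- simulate_eeg_response(stim, cfg, s)
      gt[[i]] <- data.frame(subject = s, song = as.numeric(stim$song_id),
                            delay_ms = cfg$delay_ms, snr_db = cfg$snr_db)
    }
  }
  structure(list(stimuli = stimuli, recordings = recs,
                 ground_truth = do.call(rbind, gt), config = cfg),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic_dataset> %d songs x %d subjects, %d channels @ %g Hz, %g s, delay %g ms, SNR %g dB\n",
    x$config$n_classes, x$config$n_subjects, x$config$n_channels,
    x$config$fs_eeg, x$config$duration_seconds, x$config$delay_ms,
    x$config$snr_db))
  invisible(x)
}

#' Worked-example window scores for a 5-s evaluation
#'
#' The 3 x 10 matrix of per-window softmax scores from the published
#' worked example of a 5-s evaluation of a 10-song classifier (three 3-s
#' windows at a 1-s stride; true song 7).  Window argmaxes are 8, 0, 7;
#' majority aggregation yields 8, max aggregation yields 7.
#'
#' @return A [window_predictions()] with `true_label = 7`.
#' @export
#' @examples
#' wp <- table8_fixture()
#' aggregate_majority(wp)$predicted_class  # 8
#' aggregate_max(wp)$predicted_class       # 7
table8_fixture <- function() {
  scores <- rbind(
    c(1.35e-1, 5.56e-7, 1.76e-2, 2.19e-3, 1.08e-2,
      4.01e-3, 4.62e-4, 9.53e-3, 8.19e-1, 1.11e-3),
    c(3.75e-1, 1.02e-5, 8.16e-3, 2.03e-2, 1.21e-1,
      1.74e-4, 3.35e-3, 1.21e-1, 3.39e-1, 1.20e-2),
    c(7.10e-3, 3.15e-9, 4.26e-5, 2.05e-5, 1.66e-4,
      3.49e-7, 1.34e-6, 9.93e-1, 9.35e-5, 2.04e-6))
  window_predictions(scores, true_label = 7)
}
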