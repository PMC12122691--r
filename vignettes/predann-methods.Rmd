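---
title: "Cross-modal contrastive training of EEG music-identification models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-modal contrastive training of EEG music-identification models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(predann)
```

## The problem

Identifying which song a listener is hearing from scalp EEG is a hard
multiclass decoding problem: the neural trace of the stimulus is buried
in noise, and labelled EEG is scarce and expensive compared to the
stimulus audio, which is clean and unlimited. `predann` implements a
training framework that exploits this asymmetry. Two structurally
identical convolutional encoders process the two modalities
independently; alongside the usual classification objective, the EEG
encoder is trained to *predict* the stimulus-side network embedding of
the audio the subject was hearing, through a contrastive
(InfoNCE-style) loss with a stop-gradient on the audio side — the
PredANN loss. The audio branch is only needed during training; at test
time the EEG branch alone classifies.

## Model and losses

Each branch is a CNN encoder followed by two heads: Projector I
produces class logits over the $K$ songs, Projector II produces a
contrastive embedding. For a mini-batch of $B$ paired windows, with
EEG outputs $z^{EI}_i, z^{EII}_i$ and music outputs
$z^{MI}_i, z^{MII}_i$ and shared labels $c_i$:

* classification: $\mathcal{L}_{clsE} = \sum_i \mathrm{CE}(z^{EI}_i, c_i)$
  and likewise $\mathcal{L}_{clsM}$ (summed over the batch);
* PredANN: with $s_{ij} = \mathrm{sim}(\mathrm{sg}(z^{MII}_i),
  z^{EII}_j)/\tau$ (cosine similarity, temperature $\tau$,
  stop-gradient $\mathrm{sg}$),
  $$\mathcal{L}_{PredANN} = -\sum_i \left[
    \log \frac{e^{s_{ii}}}{\sum_j e^{s_{ij}}} +
    \log \frac{e^{s_{ii}}}{\sum_j e^{s_{ji}}} \right];$$
* total: $\mathcal{L} = \mathcal{L}_{clsE} + \mathcal{L}_{clsM} +
  \lambda\, \mathcal{L}_{PredANN}$.

Every off-diagonal pair in the batch is a negative, *including pairs
that share a song label*: the equation is index-based, and this is
deliberate — distinguishing the matched audio window from other windows
of the same song forces the EEG embedding to carry temporal, not just
categorical, information. It is also what makes the assumed
stimulus–response latency identifiable (below).

With `stop_gradient = TRUE` (default) the PredANN term contributes
*exactly zero* gradient to every music-branch parameter — the music
branch learns only from its own classification loss, and the EEG branch
chases a target that does not chase it back. Setting the flag to
`FALSE` gives the stop-gradient-free ablation; `lambda_predann = 0`
gives the classification-only baseline. The fitted object records a
per-run gradient audit of this contract (`summary()` prints it).

### Choices the equations leave open

* **Temperature** $\tau$: fixed at 0.1 (common InfoNCE practice), not
  learned, configurable via `loss_config()`.
* **Embeddings are not re-normalized** before the loss; cosine
  similarity normalizes internally, so the loss is invariant to
  per-row positive rescaling (tested as a property).
* **Projector II** is one rectified hidden layer then a linear map;
  Projector I is linear. The contrastive embedding width defaults to
  128 (full profile) or 32 (desk profile).
* **Blocks** are convolution (kernel 3, stride 1, padding 1 — the
  shape-preserving convention both families use) → rectifier →
  factor-2 max-pool, with global average pooling before the heads.
  No normalization layers: at these depths they are unnecessary and
  omitting them keeps runs bit-reproducible.
* **Summation vs averaging**: both classification and contrastive
  losses are summed over the batch, as written; Adam makes the
  optimization largely invariant to that scale.

The `cnn1d` family treats EEG channels as convolution channels; the
`cnn2d` family treats the recording as a single-channel channels × time
grid, and audio as a height-1 grid so 2-D kernels act purely
temporally. Gradients for every layer are hand-derived and audited
against finite differences in the test suite.

## Preprocessing pipeline

The order is fixed: per-channel robust scaling, then clamping, then
excerpting.

* `robust_scale_channels()`: per channel, subtract the median and
  divide by the IQR (type-7 quantiles — the linear-interpolation
  default of mainstream numeric stacks). Statistics are fitted per
  channel per recording; zero-IQR channels are centred only and
  flagged.
* `clamp_values()`: clip to ±20 (idempotent).
* `truncate_and_excerpt()`: keep the first 240 s, split into eight
  30-s excerpts (desk profile: 60 s → two excerpts).
* `stratified_split()`: 75:25 train/validation over excerpts,
  stratified by song, with (subject, song) excerpts as sampled units;
  seeded and reproducible.
* `apply_delay()` / `cut_segments`: the audio window covers
  $[t, t+w)$; the EEG window covers the same interval shifted later by
  the assumed latency (rounded to the nearest sample; windows that
  would cross an excerpt boundary after shifting are dropped, not
  padded — no fabricated data). Sample indices are zero-based,
  windows half-open.

Training extraction uses a stride of 200 samples with a fresh uniform
random clip offset per excerpt per epoch, so despite the coarse grid
every sample position is eventually visited; evaluation uses a fine
stride (down to 1). An "epoch" is one pass over the stride grid under
that epoch's offsets.

## The synthetic study

Nothing external is needed to exercise the pipeline: the generator
emulates a naturalistic listening study with known ground truth.
Stimulus $k$ is a sinusoidal carrier (linearly spaced, 5 Hz to 60% of
Nyquist) amplitude-modulated at a class-specific rate (log-spaced,
1.5–12 Hz — log spacing keeps neighbouring rates discriminable by the
local-derivative statistics a small CNN can measure) and by a slow
seeded random envelope that makes each stimulus non-stationary, so
different time windows carry different content. The simulated cortex
encodes the stimulus envelope (rectification, short moving average,
and a fixed causal 3-tap kernel — the simplest temporal-response-like
forward model under which latency is identifiable), shifts it 200 ms
later, mixes it into channels with subject-specific seeded weights,
and adds white (optionally pink) noise calibrated per channel to the
requested SNR. Generation is a pure function of the configuration.

What this emulates: class-structured stimuli, a latency-shifted noisy
envelope code, subject-specific topography. What it does not: volume
conduction, oscillatory background (alpha), artifacts, non-linear or
multi-lag response functions. Passing tests on this generator
demonstrate that the training machinery works end to end — not that
the architecture would reach any particular accuracy on real EEG.

### Desk-scale study conditions

All end-to-end properties are exercised at one fixed scale, chosen to
fit a single CPU while leaving the phenomena visible: 5 songs,
2 subjects, 8 channels at 125 Hz, 60-s recordings (30-s excerpts,
75:25 split → 3 train / 1 validation excerpt per song), 3-s windows,
stride 200, encoder blocks (16, 16, 32) with a 32-dimensional
embedding, 60 epochs of Adam at learning rate $10^{-3}$, batch 32.
Two noise regimes are used: **+10 dB** ("clean"), where the task
should be essentially solved (validation accuracy well above 0.9
versus a 0.2 chance level), and a **−5 dB noisy** regime where the
baseline classifier lands mid-way between chance and ceiling — the
SNR was selected by piloting the $\lambda = 0$ baseline alone across
SNR levels, because an ablation measured at floor or ceiling is
uninformative. At that operating
point the package's stochastic properties are asserted as directions
aggregated over seeds, not magnitudes: $\lambda = 0.05$ versus
$\lambda = 0$, accuracy non-decreasing in evaluation length for the
mean rule, and the latency sweep peaking at (or adjacent to) the
generating 200 ms on a {0, 100, 200, 400} ms grid.

## Long-window evaluation and statistics

A trained classifier scores a long excerpt through overlapping 3-s
windows at a 1-s stride (an $L$-second excerpt gives $L-2$ windows)
and the per-window softmax rows are combined by one of three rules:

* **mean** — column-wise average, argmax;
* **max** — column-wise maximum, argmax (the class holding the single
  most confident score anywhere wins);
* **majority** — per-window argmax votes, modal class, ties broken by
  the earliest window whose vote is among the tied classes.

The tie-break rule reproduces the published worked example exactly
(`table8_fixture()`): window votes 8, 0, 7 with equal counts give 8
under majority, while max aggregation yields 7. Argmax ties in mean
and max (measure-zero events) resolve to the lowest class index.

Paired model comparison uses McNemar's test on binary correctness
arrays. The default is the exact two-sided binomial tail on the
discordant counts, `p = min(1, 2 P(X ≤ min(n01, n10)))` — robust at
the small discordant totals desk-scale runs produce; the
continuity-corrected chi-square variant is available for large-sample
practice (it is the variant whose p-values underflow toward the
smallest representable double for very lopsided counts). Accuracy
reports provide overall, per-song, per-subject and per-length
breakdowns; cells are count-weighted, so each complete partition
averages back to the overall accuracy exactly.

## Numerical notes and limitations

* Quantiles are type 7; the delay shift rounds to the nearest sample;
  `round(0.5)` follows R's round-half-to-even.
* The exact McNemar p is capped at 1; zero discordant pairs give
  p = 1 by convention.
* Softmax and log-softmax are computed with max-subtraction; the
  PredANN gradient is analytic (no autodiff), verified against brute
  force and finite differences.
* Checkpoints (`save_checkpoint()`) reload bit-identically; runs are
  deterministic given `seed` because every stochastic step draws from
  the single seeded RNG stream.
* Known limitations: no batch normalization or learning-rate
  schedules; the 2-D family is exercised at small scale only; the
  generator's linear envelope code understates the difficulty of real
  EEG; training is single-threaded (BLAS aside).
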