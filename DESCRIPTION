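Package: predann
Title: Cross-Modal Contrastive Training of EEG Music-Identification Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Trains convolutional EEG song-identification models with an
    auxiliary stop-gradient InfoNCE objective (the PredANN loss) that teaches
    the EEG encoder to predict stimulus-side network embeddings of the music
    being heard.  Provides robust-scaler preprocessing with clamping,
    stimulus-response delay alignment, sliding-window extraction, stratified
    excerpt splitting, a synthetic paired EEG/audio data generator with known
    class structure and latency, seeded training of paired 1D/2D CNN encoders
    with dual projection heads, sliding-window score aggregation (mean, max,
    majority), per-song and per-subject accuracy breakdowns, and exact and
    chi-square McNemar tests for paired classifier comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, graphics, yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
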