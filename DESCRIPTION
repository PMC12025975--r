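Package: aftanet
Title: Self-Supervised Frequency-Time Attention Transformers for EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Self-supervised masked-reconstruction Transformer for multichannel
    EEG with adaptive frequency-time attention. Provides a seeded synthetic EEG
    generator (band-limited oscillations, 1/f background, line interference,
    spike-wave bursts), standard EEG preprocessing (zero-phase band-pass and
    notch filtering, polyphase resampling, fixed-length epoching, augmentation,
    class balancing), spatiotemporal patching with dual-ratio masking, an
    adaptive frequency filtering module with learnable spectral gains and an
    energy-thresholded mask, frequency-gated self-attention blocks, a momentum
    encoder with feature alignment, masked-patch reconstruction pretraining,
    fine-tuning heads for seizure-style classification and prediction, and
    evaluation metrics (balanced accuracy, AUROC, weighted F1, Cohen's kappa).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
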