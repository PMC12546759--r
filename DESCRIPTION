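Package: cardiodiff
Title: Conditional Latent Diffusion Synthesis of 12-Lead ECG Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generates 12-lead electrocardiogram (ECG) signals conditioned on
    free-text clinical reports and patient-specific covariates (sex, age,
    heart rate) with a 1D latent denoising diffusion model. A convolutional
    variational autoencoder compresses fixed-length 12-lead recordings into a
    compact latent representation; a conditional 1D U-Net noise predictor with
    self- and cross-attention is trained under the standard DDPM objective and
    sampled by ancestral denoising. The package also provides the data-curation
    pipeline for WFDB-format ECG archives (RR-interval validation with a
    QRS-detector fallback, record filtering, polyphase downsampling), ordered
    prompt construction and condition-vector assembly, a seeded synthetic ECG
    fixture generator with known ground truth, and a three-level evaluation
    suite: Frechet distance on encoder representations, k-nearest-neighbour
    manifold precision, recall and F1, heart-rate mean absolute error, and a
    CLIP-style text-signal alignment score.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
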