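---
title: "Conditional latent diffusion for 12-lead ECG synthesis: models, parameters and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional latent diffusion for 12-lead ECG synthesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Large 12-lead electrocardiogram archives pair each recording with
machine-generated free-text reports and patient covariates (sex, age) and a
machine-measured RR interval. `cardiodiff` learns the conditional
distribution of the 12-lead signal given a text description and
patient-specific values, so that new ECGs can be synthesized for a stated
condition ("sinus tachycardia", a 75-year-old male at 120 bpm, ...), and
provides the matching evaluation toolkit for judging such generators.

## Model

### Signal representation and curation

Raw records are 12 x 5000 matrices (10 s at 500 Hz, millivolts). Curation
follows fixed rules:

* Heart rate comes from the machine RR interval, `hr = 60000 / rr_ms`, when
  the RR lies in 300–1500 ms. RR anomalies (0 ms, 65535 ms) fall outside
  that window and trigger a fallback: a QRS detector is run on each of the
  12 leads; a lead contributes `60 / median(inter-beat interval)` when it
  has at least two detections, and the record-level rate is the median over
  contributing leads. If all 12 leads fail, the heart rate is absent.
* Records missing heart rate, sex or age are discarded; order is preserved.
* Signals are downsampled 5000 -> 1024 samples per lead by anti-aliased
  resampling: a zero-phase Butterworth low-pass at 90% of the new Nyquist
  (forward-backward, so no phase shift and exact preservation of
  constants) followed by cubic-spline evaluation on the target grid —
  chosen over plain decimation to avoid aliasing QRS energy. The sampling
  rate becomes 102.4 Hz.
* Each record is min–max normalized to [-1, 1]; the affine parameters are
  stored and inverted after generation. Bounded inputs suit the VAE and
  keep the diffusion latents on a predictable scale.

### Variational autoencoder

The encoder is a strided 1D convolutional network that halves the length
`log2(1024 / latent_len)` times while moving 12 lead channels to
`latent_ch` channels (default latent 4 x 128); two convolutional heads emit
the posterior mean and log-variance. The decoder mirrors the encoder with
linear-interpolation upsampling followed by convolution. Latents are drawn
by reparameterization, `z = mu + exp(log_var / 2) * eps`, and training
minimizes reconstruction MSE (mean over all entries) plus an annealed KL
divergence to N(0, I):

    L = MSE(x, x_hat) + lambda(epoch) * KL(q(z|x) || N(0, I))

with `lambda` ramping linearly from 0 to `lambda_max` over `ramp_epochs`
epochs (monotonic KL annealing, mitigating KL vanishing). The KL uses the
standard closed form `-1/2 * sum(1 + log_var - mu^2 - exp(log_var))` in the
log-variance parameterization.

Three numerical choices matter in practice and are worth recording:

* **`lambda_max` default is 2e-5.** The KL here is a *sum* over the latent
  entries (O(100) nats for a 4 x 128 latent at moderate compression). A
  weight of 1e-3 makes the KL term several times the reconstruction term;
  in our runs it visibly collapsed the posterior mid-training (the KL fell
  by an order of magnitude while reconstruction error rose). 2e-5 keeps
  the KL term an order of magnitude below the MSE at convergence while
  still regularizing scale.
* **The log-variance head starts at -6.** With the conventional
  near-zero initialization the posterior sd is ~1 while the useful latent
  mean variation is ~0.1, so early training the decoder receives almost
  pure noise and learns the dataset mean — a local optimum it does not
  leave on a small budget. Starting with sd ~ exp(-3) lets reconstruction
  drive the latent structure first; the KL then grows the variance to its
  proper level.
* **Upsampling is linear interpolation, not nearest-neighbour.**
  Nearest-neighbour upsampling imprints a blocking artifact at the latent
  stride (every 32 samples for a 1024/32 decoder), which a QRS detector
  happily mistakes for beats.

### Diffusion in latent space

The DDPM scheduler uses `T` steps with a linear beta schedule; defaults
`T = 1000`, `beta` in [0.00085, 0.0120] (a `scaled_linear` option spaces
`sqrt(beta)` linearly between the same endpoints). Forward noising is

    z_t = sqrt(abar_t) z_0 + sqrt(1 - abar_t) eps,   eps ~ N(0, I)

and the reverse chain draws `z_{t-1} ~ N(mu_q, sigma_t^2 I)` with the
standard posterior mean built from the predicted noise, using the
convention `abar_0 := 1` under which the final (t = 1) step has exactly
zero variance — no special-casing needed. The training loss is the mean
squared error between true and predicted noise (mean-per-element
reduction, so the loss scale does not depend on the latent size).

**Scaling the schedule with T.** The default endpoints are calibrated for
T = 1000, where `abar_T ~ 0.002`: the terminal forward marginal is close
to the N(0, I) that ancestral sampling starts from. If T is reduced (the
package's reduced test configurations use T = 50) the endpoints must be
rescaled so that `sum(beta) ~ 6`; otherwise `abar_T` stays far from zero
and generation starts from a distribution the model never saw. The
reduced configurations therefore use beta in [0.004, 0.25].

Clean latents for diffusion training are the posterior *means* (not fresh
reparameterized samples — lower-variance targets), standardized per
channel to zero mean and unit sd over the training set; the affine is
stored in the fit and inverted before decoding.

### Noise predictor

A 1D U-Net predicts the noise from `(z_t, t, c)`:

* down stages enrich channels while halving length (stride-2
  convolution); up stages mirror them with linear upsampling, and each up
  stage receives the same-resolution down activation by channel-wise
  concatenation (skip connections);
* kernel size 7 throughout; the stage count and channel schedule are
  configuration (default seven stages, (32, 64, 96, 128, 160, 192, 224));
* the time step indexes a *trainable* embedding table (d = 64)
  initialized row-wise as `[sin(t f_i) | cos(t f_i)]` with the geometric
  frequency ladder `f_i = exp(-10 i / (d/2 - 1))`; the embedding is
  linearly projected to each stage's width and broadcast-added along the
  length axis (per-stage injection is the standard reading of "add to
  the latent");
* self-attention over the length axis and cross-attention on the
  condition sit at the bottleneck, with cross-attention repeated at the
  coarsest up stage. The condition is a single token; the softmax over
  one key is identically 1, so only the value path of cross-attention is
  live and the query/key projections would be inert parameters — the
  layer therefore implements just the value path plus output projection,
  which keeps the "every parameter receives gradient" property honest.

### Conditioning

Reports are rendered into ordered prompts — a single report as "The
report of the ECG is that {text}.", multiple reports as "Most
importantly, The 1st diagnosis is {text}." followed by "As a
supplementary condition, the 2nd/3rd/... diagnosis is {text}." — joined
into one string and embedded once. The condition vector is

    c = [ embed(prompt) | heart_rate | age | sex ]

with sex encoded F -> 0, M -> 1. In the default `"scaled"` mode heart
rate and age are divided by 100 to stay commensurate with a unit-norm
text embedding; `"raw"` mode passes them unchanged (the literal
concatenation). The bundled embedder is seeded feature hashing over
lower-cased alphanumeric tokens with L2 normalization — deterministic,
offline, and adequate for testing; any deterministic embedder with a
`dim` and an `embed` closure can be plugged in instead, e.g. an adapter
over an external semantic embedding service with on-disk caching.

Ablation variants reproduce the usual grid: `no_patient_info` drops the
three scalar slots (text-only conditioning); `no_vae` runs the diffusion
directly on the 12 x 1024 signal.

## Evaluation

Three levels, all against pluggable encoders:

* **Signal level.** Frechet distance between Gaussian moment-matches of
  encoder representations, `||mu_r - mu_g||^2 + Tr(S_r + S_g - 2 (S_r
  S_g)^{1/2})`, computed via the symmetric square-root form with
  eigenvalues clamped at zero and the result clipped at zero. Manifold
  precision/recall with k = 3: each set's manifold is the union of
  hyperspheres centred at its points with k-NN radii (self excluded —
  otherwise duplicate points collapse every radius to zero); precision
  is the covered fraction of generated points, recall the covered
  fraction of real points, boundary inclusive. High precision with low
  recall is the mode-collapse signature.
* **Feature level.** Mean absolute error between the conditioning heart
  rate and the rate detected on each generated waveform by the same QRS
  detector used in curation.
* **Diagnostic level.** A CLIP-style score: cosine similarity between
  text and signal representations in a space trained jointly with a
  symmetric InfoNCE objective (temperature 0.07) over matched pairs —
  a small 1D CNN signal encoder and a 2-layer perceptron text projector.
  Any objective that makes matched pairs score above mismatched ones is
  acceptable; InfoNCE is simply the conventional choice.

## Synthetic fixtures

The generator emulates what the model assumes about real archives:
quasi-periodic 12-lead signals with a controllable rate in 40–160 bpm
(beats at 60/hr s with <2% jitter), a narrow positive Gaussian QRS-like
spike (sd 22 ms, matching a physiological 80–100 ms QRS) plus a broader
delayed T-like bump, a fixed 12-entry lead projection (aVR negative),
baseline wander, white noise (sd 0.03 mV), paired two-token reports whose
rate term follows the clinical 60/100 bpm bands, sex ~ Bernoulli(0.5) and
age uniform on 20–90. Ground truth (planted beat times, class labels) is
returned alongside.

What it does **not** emulate: P waves, PR/QT interval structure,
arrhythmic beat-to-beat irregularity, pathological morphologies (ST
shifts, AF), electrode noise bursts, or inter-lead timing physiology.
Passing tests on these fixtures therefore demonstrates that the pipeline's
contracts and learning dynamics are correct — not that the model produces
clinically convincing ECGs; that claim would need real archives and
human/clinical validation.

## Reduced test configurations

The test suite and the acceptance script train a reduced pipeline chosen
to exercise every component within a desk-scale CPU budget: 1000 synthetic
records, latent 2 x 32, T = 50 with beta in [0.004, 0.25], a 3-stage
U-Net (24, 32, 48), hash embedder of dim 64, VAE batch 64. The
conditional-recovery check generates ECGs at 50/80/120 bpm and verifies
that detected rates order correctly and that conditioning strictly beats
a condition-zeroed baseline on heart-rate MAE under paired seeds. These
problem sizes are the package's standing reduced configuration; the
full-scale defaults (latent 4 x 128, T = 1000, 7 stages, batch 512,
learning rate 5e-4) remain the exported defaults.

## Known limitations

* The networks are plain R + BLAS; training beyond tens of thousands of
  records is impractical — the package targets method correctness and
  desk-scale experiments, not production training.
* The hash embedder carries no semantics beyond token identity; semantic
  alignment scores are only meaningful with a semantic embedder plugged
  in.
* The QRS detector is envelope-based and tuned for the 40–160 bpm band at
  the curated sampling rates; it is not a clinical-grade detector.
* `no_vae` variants run diffusion on 12 x 1024 signals and are an order
  of magnitude slower per step; they exist for the ablation contract.
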