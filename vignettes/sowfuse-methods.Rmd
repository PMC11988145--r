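---
title: "Methods: multimodal thermal-acoustic estrus detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal thermal-acoustic estrus detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The detection problem

Estrus — the fertile phase of the sow's reproductive cycle — must be
caught within a narrow window for insemination to succeed; missed or
silent estrus directly depresses the piglets-weaned-per-sow-per-year
(PSY) figure that drives farm productivity. Two non-contact signals
carry complementary information: vulvar-region warming visible in a
thermal infrared image of the hindquarters, and changes in
vocalization (pitch, harmonic richness, amplitude modulation). Neither
alone is reliable: a sizeable fraction of gilts show *silent* estrus
with no distinctive vocalization, while thermal contrast is degraded by
hair, stains, and ambient drift. `sowfuse` implements a full pipeline
that denoises both modalities, extracts a feature vector from each with
a dedicated neural encoder, fuses them with a learned, input-dependent
attention weight, and classifies the fused representation.

## Signal preprocessing

**Images.** Each grayscale frame is (1) min–max normalized to $[0,1]$,
(2) standardized per image to zero mean and unit population variance,
and (3) wavelet-denoised: a separable 2-D orthonormal discrete wavelet
transform (default `db4`, 2 levels), hard thresholding of the detail
coefficients,

$$\hat W_{j,k} = \begin{cases} W_{j,k} & |W_{j,k}| \ge \lambda \\ 0 & |W_{j,k}| < \lambda, \end{cases}$$

and inverse transform. The coarsest approximation band is never
thresholded. By default $\lambda$ is the Donoho universal threshold
$\hat\sigma\sqrt{2\ln n}$ with $\hat\sigma = \mathrm{median}(|HH_1|)/0.6745$;
a fixed-$\lambda$ mode applies the rule above literally. Hard
thresholding is the default because it leaves genuine structure
untouched above threshold; soft shrinkage is available behind a flag.

*Boundary handling.* The transform uses periodic extension rather than
symmetric extension. This is a deliberate numerical choice: with
periodization and an orthonormal filter bank the transform matrix is
exactly orthogonal, so Parseval's identity and perfect reconstruction
hold to machine precision — properties the test suite asserts at
`1e-6` (relative energy) and `1e-8` (max reconstruction error). With
symmetric extension those identities are only approximate. The cost is
potential wrap-around artifacts on images whose opposite edges differ
strongly, which is negligible for hindquarters frames that are
dominated by a central subject. Each level halves both dimensions, so
the image must be even-sized (and at least the filter length) at every
level; violations raise an error rather than silently padding.

**Audio.** Clips are mixed to mono (channel average), transformed with
the FFT, multiplied bin-wise by the *magnitude* response of an analog
Chebyshev Type-I band-pass prototype

$$|H(\omega)| = \frac{G}{\sqrt{1 + \epsilon^2 T_N^2(\omega/\omega_p)}},$$

under the standard low-pass-to-band-pass mapping
$\omega \mapsto (\omega^2-\omega_0^2)/(B\omega)$, and inverted back to
the time domain. Because the applied response is real, the filter is
zero-phase: in-band content is not delayed, which the tests verify via
the cross-correlation peak lag. A conventional bilinear-transform IIR
realization (`signal::cheby1` + forward–backward filtering) is
available with `method = "iir"` and agrees with the spectral path in
the passband.

Defaults: order 4, ripple 0.5 dB, passband 100–4000 Hz. The band is a
judgment call, not a measured constant: it covers grunt fundamentals
(~100–350 Hz) and scream harmonics while excluding mains/fan hum
(50 Hz and low harmonics) and high-frequency bird chirps and dripping.
$T_N$ is evaluated in closed form ($\cos(N\arccos x)$ inside the unit
interval, $\cosh$ outside); overflow for extreme arguments maps
harmlessly to zero gain.

## Feature extractors

**Image encoder.** A small Vision-Transformer: non-overlapping patches
are embedded by a shared linear map (equivalently a convolution with
kernel = stride = patch size), a learned positional table is added, and
a stack of pre-norm encoder layers (multi-head self-attention,
$\mathrm{softmax}(QK^\top/\sqrt{d_k})V$, then a ReLU FFN
$\mathrm{ReLU}(xW_1+b_1)W_2+b_2$, each with a residual connection)
processes the tokens; the final layer norm is followed by mean pooling
over tokens. Pre-norm ordering was chosen for stability at small
scale; a CLS-token pooling mode exists behind a flag. Package defaults
are depth 4, 4 heads, embedding 128, patch 16 on 224×224 input — all
configurable, none claimed to be the original design's values, which
are not public.

**Audio encoder.** Three 1-D convolutions over the filtered waveform
(ReLU + average pooling ×4 after each), the third dilated (default
rate 2) to widen the receptive field at zero parameter cost, then
global average pooling over time and a linear map to the feature
dimension. Waveform input (rather than a spectrogram) keeps the
preprocessing chain's output as the encoder input. Convolutions use
*circular* padding; combined with global average pooling this makes
the extractor exactly invariant to circular time shifts that are
multiples of the cumulative stride (64 samples at the default pooling)
— an exactness the tests assert at `1e-12`.

## Adaptive cross-attention fusion

The pooled image feature $X$ and audio feature $Y$ are concatenated to
$Z = [X, Y]$ and passed through a ReLU MLP
($H = \mathrm{ReLU}(W_{in}Z + b_{in})$, then $k = 2$ hidden ReLU
layers); a sigmoid output layer produces the attention weight
$A \in [0,1]$. $A$ is applied as a convex combination of the two
features after linear projection to a common dimension:

$$\mathrm{fused} = A \cdot \mathrm{proj}_{img}(X) + (1-A) \cdot \mathrm{proj}_{aud}(Y).$$

Two genuinely open design points were resolved as follows:

- **Shape of $A$**: a per-sample scalar by default, because the
  fixed-weight baselines it is compared against (0.5/0.5, 0.7/0.3,
  0.3/0.7) are scalar; a per-dimension vector mode is available via
  `weight_mode = "vector"`.
- **How $A$ enters the fusion**: the convex-combination rule makes
  every fixed-weight baseline an exact special case of the adaptive
  wiring (frozen $A$ reproduces it bit for bit), so ablation deltas
  measure only what the adaptivity adds.

The sigmoid output layer is zero-initialized, so training starts at
$A = 0.5$ — balanced fusion — and learns to deviate. This removes a
failure mode where a randomly initialized saturated gate starves one
modality of gradient from the first step.

## DenseNet-SE backbone

The fused vector is reshaped (bijectively, column-major) into a small
$C_0 \times h_0 \times w_0$ feature map and passed through: a 3×3 stem
convolution; three dense blocks (each layer consumes the concatenation
of the block input and all previous layer outputs, emitting `growth`
channels) whose outputs are gated by squeeze-and-excitation blocks
(global average pool per channel, bottleneck MLP with reduction $r$,
sigmoid gate); 2×2 average pooling between blocks; global average
pooling; and a fully connected 2-logit head. Channel bookkeeping
(block output = input + layers × growth) is asserted structurally in
the tests. No batch normalization is used — the engine is
batch-free — and plain conv+ReLU layers proved sufficient at this
scale. The reshape adapter is the simplest information-preserving
bridge from a vector to a conv stack; a 1-D DenseNet variant was
considered and rejected to stay with a conventional 2-D conv/pool
layout.

## Training

Adam (batch 16, learning rate 0.001, 100 epochs in the full-scale
configuration) minimizes 2-class cross-entropy. A reduce-on-plateau
schedule multiplies the learning rate by 0.1 after 5 consecutive
epochs without strict validation-loss improvement ("drop period 5" is
read as plateau patience, since the training procedure is described as
validation-monitored; a fixed-step decay mode is also provided). The
best-validation checkpoint is retained. All randomness (initialization,
shuffling, generation) flows from explicit seeds; two runs with equal
seeds produce bit-identical histories.

Everything — both encoders, fusion, backbone — trains end-to-end on a
small reverse-mode automatic-differentiation engine written for this
package (`R/autodiff.R`). Every backward rule is validated against
central finite differences in the test suite; full-model gradients
agree with numerical derivatives at relative error ~1e-9.

## The synthetic data generator

Real paired farm data are not publicly deposited, so the package ships
a generator whose defaults emulate the study conditions: 960 pairs
(480 per class), 96×96 thermal-like images and 1 s clips (16 kHz).

- **Images**: smooth ambient background with a mild gradient, a
  soft-edged warm ellipse whose elevation is class-dependent
  (estrus +0.35, non-estrus +0.15 on the [0,1] scale, ±0.10 uniform
  per-animal jitter so the class ranges overlap slightly), sparse
  bright/dark speckle and short strokes emulating hair and stains
  (amplitude 0.2 — fine-scale, modest-contrast texture of the kind
  coefficient thresholding removes), and Gaussian sensor noise
  (sd 0.06). A fraction `image_occlusion_frac = 0.10` of frames have
  the warm region attenuated to 30% of its elevation, emulating
  occlusion by the tail, dung, or camera angle.
- **Audio**: a harmonic stack with class-dependent fundamental
  (estrus ~U(250, 350) Hz with 5 harmonics and 8 Hz amplitude
  modulation; non-estrus ~U(120, 180) Hz with 3 harmonics), 50 Hz hum
  with harmonics, transient 6–7.5 kHz chirps, and white noise at
  ~3 dB SNR. A fraction `call_overlap_frac = 0.2` of samples draw
  their call from the *other* class's distribution, modelling silent
  estrus (reported in 10–30% of gilts) and distress calls in
  non-estrus animals. This keeps audio genuinely informative but caps
  its ceiling below the thermal cue, reproducing the qualitative
  ordering observed on farm data (image-only > audio-only, fusion
  best).

The occlusion and call-overlap fractions give the two modalities
*complementary* failure modes — the situation multimodal fusion
exists for: a frame-occluded estrus sow is still audible, a silent
one still visibly warm, and only the ~2% of samples failing both
cues are irreducibly ambiguous. With these defaults a two-feature
logistic oracle (mean warm-region intensity + call-band power ratio)
reaches ~92–93% held-out accuracy: learnable but not trivial, leaving
headroom for fusion to beat either single modality. Setting the class parameters equal
(`null_synthetic_spec()`) removes all label signal and calibrates any
classifier's expected accuracy to 50%.

**What passing tests do and do not show.** The generator produces
stylized Gaussian blobs and harmonic stacks; it has no radiometric
temperature calibration, no animal pose or occlusion variation, no
per-animal identity structure (so no identity-leakage control across
splits), and no realistic acoustic room response. Green experiments
demonstrate that the pipeline's machinery — preprocessing, encoders,
fusion, training — works and that adaptive fusion exploits
complementary modalities on data *designed* to have that structure;
they are not evidence about accuracy on real sows.

## Desk-scale experiment sizes

The multi-seed fusion experiment (tests and the acceptance script)
uses a reduced configuration chosen as the package's own desk-scale
protocol: 160 pairs per seed split 6:2:2, images resized to 24×24
(patch 8, width 64, depth 2, 2 heads), audio decimated to 1 kHz
(960 samples — the class cues, fundamentals and 8 Hz AM, sit well
below the 500 Hz Nyquist), 64-dimensional fusion, a (2,2,2)-layer
DenseNet with growth 6, and 12 epochs of Adam at learning rate 0.002
with batch 8 (smaller batches give the optimizer enough update steps
to converge within the epoch budget). Ten seeds are run per
experiment; conditions share initial weights and data order, so
per-condition deltas are attributable to architecture alone.

One empirical caveat this protocol surfaces: because the fixed-weight
baseline shares the *learned* projections, it can approximate
concatenation by placing the modalities in complementary subspaces,
so the scalar adaptive weight adds little expressiveness over
`fixed 0.5/0.5` at matched budgets — the two conditions are close to
a statistical dead heat seed by seed, even while the adaptive median
stays on top. A per-dimension weight (`weight_mode = "vector"`) is
the more expressive alternative.

## Known limitations

- The scalar attention weight can collapse toward one modality on
  easy data; the zero-initialized gate mitigates but does not remove
  this. The vector-valued mode is more expressive and less prone to
  collapse.
- Hard-threshold denoising removes fine-scale, modest-amplitude
  texture; isolated artifacts brighter than the anatomy itself survive
  thresholding by design (their coefficients are above any reasonable
  $\lambda$).
- The frequency-domain filter application assumes the clip is long
  relative to the filter's effective impulse response; very short
  clips would show circular-convolution leakage.
- Per-animal grouping of the split (to prevent identity leakage) is
  not implemented; the generator has no identity structure, and how
  the original pairs were grouped across animals is not documented.
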