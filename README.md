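# sowfuse

Non-destructive estrus detection for breeding sows from paired
**thermal-infrared images** of the hindquarters and **vocalization
recordings**. Detecting estrus on time drives the piglets-weaned-per-sow-per-year
(PSY) figure that measures a farm's reproductive efficiency, and both
available non-contact cues are individually unreliable: vulvar-region
warming is masked by hair, stains and ambient drift, while 10–30% of
gilts show *silent* estrus with no distinctive vocalization. `sowfuse`
is aimed at researchers in precision livestock phenotyping who want a
fully reproducible, tested reference implementation of a multimodal
fusion pipeline for this task.

## The method

The pipeline has five stages:

1. **Image preprocessing** — min–max normalization, per-image
   standardization, and wavelet hard-threshold denoising: a 2-D
   orthonormal DWT (default `db4`, 2 levels), thresholding
   `Ŵ = W·1{|W| ≥ λ}` of the detail coefficients with the Donoho
   universal threshold `λ = σ̂√(2 ln n)`, and inverse DWT. Removes
   fine-scale hair/stain texture while preserving the warm region.
2. **Audio preprocessing** — FFT, bin-wise multiplication by the
   magnitude response of a Chebyshev Type-I band-pass prototype
   `|H| = G / √(1 + ε² T_N²(ω/ω_p))` (order 4, ripple 0.5 dB,
   passband 100–4000 Hz), inverse FFT. Zero-phase; removes hum,
   chirps and out-of-band noise.
3. **Feature extraction** — a ViT-style image encoder (patch
   embedding + positional embedding + pre-norm self-attention /
   FFN layers, mean-pooled) and a three-layer 1-D CNN audio encoder
   with a dilated third convolution and global average pooling.
4. **Adaptive cross-attention fusion** — the concatenated features
   pass through a ReLU MLP; a sigmoid output produces an attention
   weight `A ∈ [0,1]` on the image modality, and the fused vector is
   the convex combination `A·proj(X) + (1−A)·proj(Y)`. Fixed-weight
   and concatenation fusion are exact special cases, used as ablation
   baselines.
5. **DenseNet-SE classifier** — the fused vector is reshaped to a
   small feature map and classified by a DenseNet with
   squeeze-and-excitation channel gating after each dense block.

Everything trains end-to-end (Adam, reduce-on-plateau schedule,
2-class cross-entropy) on a small reverse-mode autodiff engine written
for this package and gradient-checked in the test suite. Evaluation
reports precision `P = TP/(TP+FP)`, recall `R = TP/(TP+FN)` and
`F1 = 2PR/(P+R)` as percentages.

Because the original farm recordings are not publicly deposited, the
package ships a **synthetic paired-data generator** (warm-ellipse
thermal images; harmonic-stack vocalizations with hum, chirps and
noise; controllable class effect sizes including a silent-estrus
fraction) so every stage is testable end-to-end. See the methods
vignette (`vignettes/sowfuse-methods.Rmd`) for model details, defaults
and limitations.

## Worked example

```r
library(sowfuse)

# generate a small paired dataset (PNG + WAV + manifest)
spec <- synthetic_spec(n_pairs = 8, seed = 1)
man  <- generate_pairs(spec, "demo")
man[1:3, c("sample_id", "label")]
#>   sample_id label
#> 1 syn0001       1
#> 2 syn0002       0
#> 3 syn0003       1

# audio denoising concentrates power in the vocalization band
clip <- read_wav(man$audio_path[1])
filt <- denoise_audio(clip)
band_power_fraction(clip, c(100, 4000))   # 0.809 before
band_power_fraction(filt, c(100, 4000))   # 0.978 after

# evaluation: counts -> percentages
compute_metrics(confusion_counts(c(1,1,1,0,0,0), c(1,1,0,0,0,1)))
#> # A tibble: 1 × 9
#>      tp    fp    fn    tn     n precision recall    f1 degenerate
#> 1     2     1     1     2     6      66.7   66.7  66.7 FALSE

# F1 recomputed from a printed precision/recall pair
f1_from_pr(98.92, 95.83)
#> [1] 97.35
```

The numbers mean: after band-pass filtering, 97.8% of the clip's power
lies in the 100–4000 Hz vocalization band (up from 80.9%); the toy
confusion matrix (2 TP, 1 FP, 1 FN) gives precision = recall = 66.7%,
and the harmonic mean of precision 98.92% and recall 95.83% is an F1
of 97.35%.

The full experiment — train the classifier under several fusion
conditions on synthetic data across seeds — is one call:

```r
res <- run_fusion_experiment(seeds = 1:10)
dplyr::summarise(dplyr::group_by(res, condition), f1 = median(f1))
```

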