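---
title: "Augmented-regularization registration: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Augmented-regularization registration: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(augreg)
```

## The model

`augreg` performs unsupervised deformable registration: given a fixed image
F and a moving image M on the same voxel grid (assumed linearly
pre-aligned), it predicts a dense displacement field φ₁ such that the
warped image M(φ₁) resembles F. Warping is pull/backward: the output at
voxel p samples the input at p + φ(p), displacements in voxel units,
multilinear interpolation, border clamping for out-of-grid samples.

Training couples three networks.

1. **Registration network** G, a fully convolutional encoder–decoder
   (stride-2 convolutions down, nearest-neighbour upsampling with skip
   concatenation up, LeakyReLU activations, no normalization layers) whose
   final convolution — initialized near zero so the untrained model is a
   near-identity — emits one displacement channel per axis.
2. **Augmented network** A, architecturally identical with its own
   weights, sees (F, M(φ₁)) and predicts a residual field φ₂. Its defining
   constraint is the *MSE-to-zero* penalty: the mean squared magnitude of
   φ₂ itself. The second network therefore cannot keep any deformation "for
   itself" cheaply; minimizing the joint loss pushes the first network to
   absorb the full deformation. At inference the augmented network is never
   evaluated — it is a training-time regularizer, not a cascade stage.
3. **Discriminator** D (optional), four stride-2 convolutions with
   LeakyReLU after the first three, a single output channel, global average,
   sigmoid. Real examples are fixed-image patches, fakes are warped
   moving-image patches; the generator receives the non-saturating
   `-log D(M(φ₁))` feedback.

The aggregate objectives are

```
L_G     = L_adv + α L_sim(F, M(φ₁)) + λ L_smooth(φ₁)
L_A     = L_sim(F, M(φ₁)) + L_sim(F, M(φ₁∘φ₂)) + L_sim(F, φ₂(M(φ₁)))
          + L_mse(φ₂) + L_smooth(φ₁) + L_smooth(φ₂) + L_smooth(φ₁∘φ₂)
L_total = L_G + L_A
```

optimized jointly by Adam (one discriminator step, then one G/A step per
patch pair). `L_sim` is the negative windowed local cross-correlation;
`L_smooth` the mean squared forward-difference gradient of a field.
Composition is defined as `(φ₁∘φ₂)(p) = φ₂(p) + φ₁(p + φ₂(p))`, the unique
order for which a single warp by the composed field approximates warping by
φ₁ and then by φ₂; the identity is exact whenever either argument is the
zero field, and tests bound the single- versus double-resampling gap on
smooth fields.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `cc_window` | 9 | voxels | local-CC cube side; large enough to see structure, small enough to stay local |
| `alpha`, `lambda` | 1, 1 | – | with all loss terms expressed as per-voxel means they share a common scale, so unit weights are a sensible default |
| `a_weights` | 1 × 7 | – | per-term weights of `L_A`; the ablation switches (`use_mse`, `use_extra_sim`) zero specific terms |
| `patch_size` / `stride` | 64 / 32 | voxels | training blocks are cut on a regular grid with a clamped final origin so every voxel is covered; 50% overlap |
| `lr_G`, `lr_D` | 1e-5, 1e-6 | – | reference protocol values, appropriate for long multi-epoch 3D training; the 10:1 ratio keeps the discriminator from outpacing the generator |
| `deform_amplitude` | 12 | voxels | maximum displacement of generated pairs; calibrated so unregistered phantom pairs score mean tissue Dice ≈ 0.7 (band 0.5–0.8), a realistic difficulty |
| `deform_smoothness` | 8 | voxels (σ) | Gaussian smoothing of the white-noise field; keeps generated fields diffeomorphic-like (folding fraction ≈ 0) |

Sums over the image domain are implemented as means throughout so that loss
magnitudes are resolution-independent and the α = λ = 1 defaults remain
meaningful across patch sizes.

### The desk-scale study

The package's reference experiment (`run_ablation()`, also run by
`scripts/acceptance.R` and the acceptance tests) uses 64×64 two-dimensional
phantoms, 20 training pairs, 10 test pairs and 2000 iterations per
configuration, with `lr_G = 1e-3`, `lr_D = 1e-4`. The larger learning rates
are a deliberate study condition: over a 2000-step budget Adam moves each
parameter by at most `iterations × lr`, and the reference rates sized for
hundreds of thousands of 3D patch steps would leave the networks
essentially at initialization. 1e-3 is the conventional Adam rate for 2D
registration networks at this scale; the 10:1 generator:discriminator ratio
is preserved. These sizes keep a full four-mode study within minutes on a
single CPU core while still exhibiting the method's qualitative behaviour:
every mode recovers a large share of the deformation, the adversarially
trained model edges out the plain cascade, the MSE penalty collapses the
residual field (mean |φ₂| drops by roughly a factor of five), and the φ₂
row of the per-field Dice report contributes almost nothing beyond φ₁.

## What the phantoms emulate — and what they do not

`make_phantom()` builds nested smooth-boundary regions (a WM-like core, a
GM-like ring, a CSF-like outer ring, background) by thresholding a randomly
perturbed radial coordinate, assigns distinct tissue-mean intensities, adds
Gaussian noise and a light blur. `make_pair()` warps a phantom by a random
Gaussian-smoothed displacement field scaled to a maximum amplitude, with a
folding check (fields with > 20% non-positive Jacobian are redrawn).

This captures the geometry that drives the method — thin nested tissue
interfaces displaced by smooth deformations — but deliberately omits MR
physics: no bias fields, no Rician noise, no skull or extra-cerebral
anatomy, no partial-volume mixtures, and deformations are draws from a
single smooth random-field family rather than anatomical variability.
Passing the package's tests therefore demonstrates that the training
machinery optimizes what it claims to optimize and reproduces the method's
qualitative orderings at desk scale; it does not certify accuracy on
clinical MRI.

## Numerical choices

* **ε-guards.** The local-CC denominator carries ε = 1e-5: windows with
  (near-)zero variance — flat background — contribute ≈ 0 rather than NaN.
  Discriminator probabilities are clamped to [1e-7, 1−1e-7] before logs.
* **Border policy.** Out-of-grid samples clamp to the border value instead
  of zero-filling, which would inject spurious edges into the CC loss.
  Clamped samples get zero positional gradient.
* **Windows at image borders** are truncated to the in-grid voxels, with
  local means over the actual window size; the brute-force test oracles
  implement the same convention independently.
* **Smoothness differences** at the far boundary are taken as zero; a
  constant field has exactly zero smoothness loss.
* **Initialization.** He-style for hidden convolutions; the field-emitting
  convolution uses sd = 1e-3 so the initial mean displacement is ≪ 0.5
  voxels and early warps stay near the identity.
* **Determinism.** One master seed covers phantom generation, pairing,
  patch shuffling and weight initialization; identically seeded
  single-threaded runs produce identical loss logs.
* **Degenerate inputs.** Non-finite losses abort with the offending term
  named; non-finite sampling positions fall back to the grid origin rather
  than reading out of bounds; empty∩empty Dice is 1 by convention; PCC on
  zero-variance input is an error naming the degenerate argument.

## Design decisions that were genuinely open

* **Residual penalty form.** The augmented regularizer is the mean squared
  *displacement* of φ₂ (distance to the zero field), not the squared
  gradient — a gradient penalty on φ₂ already exists separately as
  `L_smooth(φ₂)`, and only the displacement form expresses "φ₂ should
  vanish", which is the point of the construction.
* **Composition order** was fixed by requiring `warp(M, φ₁∘φ₂) ≈
  warp(warp(M, φ₁), φ₂)`; the alternative order satisfies no such identity.
* **Adversarial labelling** follows the standard non-saturating GAN
  convention (real = fixed patches, fake = warped patches).
* **Discriminator head.** With only the layer count and activations
  prescribed, the last convolution emits a single channel whose global
  average feeds the sigmoid — avoiding an extra dense layer.
* **Pull warping** (sampling at p + φ(p)) is the standard differentiable
  choice for spatial-transformer training; push/forward warping would
  require scatter splatting and is not implemented.
* **Patch grid rule.** Origins at stride multiples plus a clamped final
  origin per axis; the grid rule (full coverage, deterministic axis-major
  order) is the contract, and the patch count falls out of it.
* **Model surface.** The package follows the classic R modelling idiom:
  `augreg()` is the fitting function and returns a classed object with
  `print`/`summary`/`predict`/`plot` methods; `predict` performs
  registration. `residuals`/`coef` have no natural meaning for this model
  and are not provided.

## Known limitations

* No diffeomorphic guarantee: fields are regularized, not constrained;
  `neg_jacobian_fraction()` reports folding but nothing prevents it.
* Global-statistics SSIM is reported by default (a windowed variant exists
  behind a flag); global SSIM saturates faster than windowed SSIM.
* Batch size is one patch pair; there are no learning-rate schedules, no
  multi-resolution pyramid, no affine pre-alignment — inputs are assumed
  linearly aligned.
* 3D support is complete but CPU-bound; the shipped study conditions are
  2D, and full-resolution 3D training is out of scope for a desk-scale run.
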