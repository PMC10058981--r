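# augreg

Unsupervised deformable image registration with an *augmented-regularization*
cascade, in pure R (with Rcpp kernels).

## The problem

Deformable registration aligns a moving image M onto a fixed image F by
estimating a dense displacement field (DDF) φ, so that the warped image M(φ)
matches F voxel by voxel — the workhorse step behind cross-subject brain MRI
analysis, where CSF/GM/WM structures must be brought into correspondence.
Cascades of registration networks refine the field coarse-to-fine but
multiply parameters and inference cost. `augreg` implements an alternative:
the cascade exists **only during training**. A second ("augmented") network
predicts a residual field φ₂ on top of the first network's φ₁, and φ₂ is
penalized toward the zero field, forcing the first network to absorb the
full deformation. Optionally an adversarial discriminator scores warped
patches against fixed-image patches. At test time only the first network
runs.

## The model

Three networks are trained jointly on patch pairs:

* registration network G: φ₁ = G(F, M), a VoxelMorph-style fully
  convolutional encoder–decoder emitting one displacement channel per axis;
* augmented network A: φ₂ = A(F, M(φ₁)), same architecture, own weights;
* discriminator D: four stride-2 convolutions → sigmoid probability that a
  patch comes from the fixed image.

Losses (all image sums taken as per-voxel means):

    L_G  = L_adv + α·L_sim(F, M(φ₁)) + λ·L_smooth(φ₁)
    L_A  = L_sim(F, M(φ₁)) + L_sim(F, M(φ₁∘φ₂)) + L_sim(F, φ₂(M(φ₁)))
           + L_mse(φ₂) + L_smooth(φ₁) + L_smooth(φ₂) + L_smooth(φ₁∘φ₂)
    L_total = L_G + L_A

with L_sim the negative windowed local cross-correlation (window 9),
L_smooth the mean squared forward-difference gradient of a field,
L_mse(φ₂) the mean squared displacement magnitude of φ₂ (its distance to
the zero field — the augmented regularizer), and L_adv = −log D(M(φ₁)).
Field composition is (φ₁∘φ₂)(p) = φ₂(p) + φ₁(p + φ₂(p)), warping is
pull/backward with border clamping. Every building block — warping,
composition, losses, the conv nets, backprop and Adam — is implemented in
the package (R + Rcpp); no deep-learning framework is required.

Since real brain MRI cannot ship with a package, `augreg` includes a
synthetic phantom generator: nested smooth-boundary tissues (CSF/GM/WM-like)
with distinct intensities, deformed by random smooth fields with known
ground truth, calibrated so unregistered pairs score a mean tissue Dice of
roughly 0.5–0.8.

## Worked example

```r
library(augreg)
# training data: 10 synthetic phantom pairs with known deformations
train_pairs <- phantom_dataset(10, phantom_config(), seed = 1)
model <- augreg(train_pairs, mode = "vm_a", iterations = 500,
                lr_G = 1e-3, seed = 1)
summary(model)
#> augreg model (mode vm_a, 500 iterations)
#>   median sim loss, first 10% of iterations:  -0.3268
#>   median sim loss, last 10% of iterations:   -0.4419
#>   final mean |phi2| (voxels):                0.06083

# register a held-out pair (only the first network runs) and evaluate
test_pair <- phantom_dataset(1, phantom_config(), seed = 99)[[1]]
reg <- register_pair(model, test_pair$fixed, test_pair$moving)
warped_seg <- warp_image(test_pair$moving_seg, reg$field)
before <- evaluate_pair(test_pair$fixed, test_pair$moving,
                        test_pair$fixed_seg, test_pair$moving_seg)
after <- evaluate_pair(test_pair$fixed, reg$warped,
                       test_pair$fixed_seg, warped_seg)
round(rbind(before = c(before$dice, ssim = before$ssim, pcc = before$pcc),
            after  = c(after$dice,  ssim = after$ssim,  pcc = after$pcc)), 3)
#>          CSF    GM    WM  ssim   pcc
#> before 0.713 0.737 0.910 0.946 0.947
#> after  0.741 0.803 0.933 0.963 0.965
```

The similarity loss falls as training proceeds; the augmented field shrinks
toward zero (mean |φ₂| ≈ 0.06 voxels) while the registration field carries
the deformation, and registration lifts tissue overlap, SSIM and Pearson
correlation on the held-out pair. A full-scale run uses `mode = "vm_a_gan"`
and more iterations (see `run_ablation()`).

NIfTI I/O (`read_volume`, `write_volume`, `read_field`, `write_field`) and
a command-line wrapper (`inst/cli/augreg.R`, subcommands `simulate`,
`train`, `register`, `evaluate`, `ablate`) cover file-based workflows.

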