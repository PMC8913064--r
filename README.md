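# tumorseg

Detection of bright tumor-like lesions in 2-D grayscale brain images, built
as a fully testable R pipeline: synthetic phantoms with exact ground truth,
median-filter denoising, Canny edge localization, fuzzy c-means (FCM)
intensity segmentation, gray-level co-occurrence matrix (GLCM) texture
features, and a small feed-forward classifier trained by
Levenberg–Marquardt (LM) damped least squares with optional accelerated
particle swarm (APSO) tuning.

## Who this is for

Radiology and image-analysis researchers who want a transparent,
reproducible implementation of the classical soft-computing detection
pipeline — each stage individually callable, seeded, and validated against
independent oracles — rather than a black-box model. Because no clinical
dataset ships with the package, a phantom simulator provides labeled images
with known tumor masks so every claim the pipeline makes can be checked
end-to-end.

## The models at the core

**Segmentation.** FCM minimizes the fuzzy within-cluster sum of squares
over pixel intensities `p_i`, centers `U_j` and memberships `F_ij` with
fuzzifier `m > 1`:

    A = Σ_i Σ_j F_ij^m (p_i − U_j)²

alternating `F_ij = 1 / Σ_k (|p_i−U_j| / |p_i−U_k|)^(2/(m−1))` and
`U_j = Σ_i F_ij^m p_i / Σ_i F_ij^m`, and stopping when
`max_ij |F_ij^(k+1) − F_ij^k| < α`. The tumor mask is the
brightest-center cluster after argmax defuzzification.

**Features.** Symmetric GLCM at horizontal offset (0, 1) over 8 gray
levels; contrast `Σ p(a,b)(a−b)²`, homogeneity `Σ p(a,b)/(1+(a−b)²)`,
correlation `Σ p(a,b)(a−μ)(b−μ)/σ²`, energy `Σ p(a,b)²`, plus first-order
mean, standard deviation and entropy (bits/pixel).

**Classification.** `inputs → 16 tansig units → 1 purelin unit`, trained by
LM: solve `(JᵀJ + λI)Δ = Jᵀe` with an analytically backpropagated Jacobian,
accept steps only when MSE falls. Decisions threshold the output at 0.5 on
the 0/1 label coding. Metrics are reported on the percent scale:
`sensitivity = 100·TP/(TP+FN)`, `specificity = 100·TN/(TN+FP)`,
`accuracy = 100·(TP+TN)/total`.

## Worked example

```r
library(tumorseg)

ph  <- generate_phantom(phantom_spec(seed = 1))   # 128x128, tumor planted
fit <- fcm_cluster(median_filter(ph$image, 3), c = 4, seed = 1)
fit
#> Fuzzy c-means fit: 4 clusters, m = 2, 13 iterations (converged)
#> centers: 0.00396, 0.349, 0.5495, 0.8997

mask <- tumor_mask(fit, ph$image, ph$brain_mask)
dice_overlap(mask, ph$mask)
#> [1] 0.985

extract_features(ph$image, mask)
#> # A tibble: 1 × 7
#>    mean   std entropy_bits contrast correlation energy homogeneity
#>   <dbl> <dbl>        <dbl>    <dbl>       <dbl>  <dbl>       <dbl>
#> 1 0.870 0.162        0.792     3.42     -0.0426  0.558       0.834
```

The recovered centers sit on the four planted intensity classes
(background 0, tissues 0.35 / 0.55, tumor 0.9) despite 5% impulse noise;
the segmented mask overlaps the planted tumor at Dice 0.985; and the
feature row shows the bright, low-entropy texture signature the classifier
learns from. The full pipeline on 60 phantoms:

```r
dataset <- generate_dataset(60, 0.5, phantom_spec(noise_density = 0.05),
                            seed = 1)
result  <- run_pipeline(dataset, pipeline_config(
  split_seed = 1, network = train_config(seed = 1)))
result
#> Tumor-detection pipeline on 60 images (30 train / 30 test)
#> held-out sensitivity 100.0%, specificity 100.0%, accuracy 100.0%
#> mean Dice on tumor images: 0.966
```

Perfect held-out separation is a property of the planted, separable
phantom world, not a clinical claim; see the methods vignette
(`vignettes/tumor-detection-pipeline.Rmd`) for what a green run does and
does not establish.

A command-line front end over the same functions lives at
`inst/cli/tumorseg.R` (verbs: `simulate`, `preprocess`, `segment`,
`features`, `train`, `tune`, `evaluate`, `run`).

## Acceptance script

`scripts/acceptance.R` regenerates the 60-phantom dataset from its `--seed`
argument, runs the complete pipeline (filtering → FCM segmentation → GLCM
features → LM training → held-out evaluation), prints the resulting
metrics, and writes its JSON result file to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
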