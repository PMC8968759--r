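# cauchyvessel

Retinal vessel segmentation from colour fundus photographs, combining a
classical oriented matched filter with a patch-based U-Net.

## The problem and the method

Automatic vessel extraction from fundus images underpins screening for
diabetic retinopathy, glaucoma and hypertensive damage, but vessels are
dark, thin (1–7 px at DRIVE resolution) structures on a red, noisy, and
unevenly lit background — and the red channel in particular carries
almost no vessel contrast. This package implements a hybrid pipeline:

1. **Cauchy matched filter.** The cross-section intensity dip of a vessel
   is modelled by the Cauchy density
   `C(x) = 1 / (πγ[1 + ((x − x0)/γ)²])` (heavier-tailed than the
   classical Gaussian template). A negated, mean-subtracted kernel built
   from this profile (γ = 1, trunk T = 9, length L = 8) is rotated every
   π/12 into a 12-orientation bank; the per-pixel **maximum correlation
   response** over the bank is computed on the CLAHE-enhanced,
   standardized green channel.
2. **Cauchy-G-B feature map.** The response replaces the noisy red
   channel, giving a 3-plane input (response, green, blue), each plane
   min–max rescaled to [0, 1] and zeroed outside the field of view.
3. **Patch-based U-Net.** A 4-down/4-up U-Net (two 3×3 convolutions per
   step, base 32 filters doubling per level, ReLU, 2-class SoftMax head
   reduced to the vessel plane) is trained on 500 overlapped 64×64
   patches per image, flip-augmented ×4, split 90/10, with Adam
   (η₀ = 0.01, shrinking ×0.9 per 10 epochs when the validation loss
   saturates). Test images are tiled without overlap and predictions are
   stitched back.
4. **Evaluation.** Pixel-level Acc/Sen/Spc/Prc inside the FOV
   (`Acc = (TP+TN)/total`, `Sen = TP/(TP+FN)`, `Spc = TN/(FP+TN)`,
   `Prc = TP/(TP+FP)`), an ROC sweep over thresholds τ ∈ {0.01, …, 0.99}
   with trapezoidal AUROC, and a τ-sensitivity table justifying the
   default τ = 0.5.

Because the pipeline needs image data to demonstrate anything, the
package ships a **synthetic fundus-phantom generator**: circular FOV,
red-dominant background, branching vessel trees with Cauchy-profile
cross-sections and known ground-truth masks, written in the DRIVE
directory layout (`images/`, `1st_manual/`, `mask/`). All stages run and
are tested end-to-end with no external download.

## Worked example

```r
library(cauchyvessel)

# a synthetic fundus image with known vessel mask
img <- generatePhantom(phantomSpec(seed = 7))
img
#> FundusImage 'phantom-7': 584 x 565, fov=TRUE, gt=TRUE
mean(gtMask(img)[fovMask(img) == 1])      # vessel fraction of the FOV
#> [1] 0.0473

# the Cauchy-G-B feature map
bank <- buildBank(cauchyParams())          # 12 kernels, 13x13, step pi/12
fm <- buildFeatureMap(img, bank)
p <- featurePlanes(fm)
v <- gtMask(img) == 1 & fovMask(img) == 1
b <- gtMask(img) == 0 & fovMask(img) == 1
mean(p[, , 1][v]) - mean(p[, , 1][b])      # response-plane contrast
#> [1] 0.2885

# scaled-down end-to-end study (minutes on one CPU): train on 10 phantoms,
# evaluate on 2 held-out ones, with the raw-RGB ablation for comparison
st <- phantomStudy(seed = 1)
st$arms[["cauchy-gb"]]$auroc
#> [1] 0.9862
round(st$arms[["cauchy-gb"]]$metrics, 4)
#>    acc    sen    spc    prc
#> 0.9819 0.7576 0.9933 0.8512
st$arms[["rgb"]]$auroc                     # ablation: red kept, no filter
#> [1] 0.9842
```

The numbers say: on held-out phantoms the trained network separates
vessel from background pixels with AUROC ≈ 0.99, and the matched-filter
feature map does at least as well as the raw-RGB ablation — the
mechanism motivating the red-channel replacement.

A command-line interface covers the same pipeline
(`simulate`, `preprocess`, `patches`, `train`, `predict`, `evaluate`,
`roc`); see `runCLI()` or the installed `cauchyvessel` script.

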