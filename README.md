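# plaquefractal

Quantifies the irregularity of atherosclerotic plaque borders on long-axis
B-mode carotid ultrasound images by **box-counting fractal dimension
(FD)** — a unitless measure between 1 (smooth border) and 2 (space-filling
border) that replaces the subjective "regular vs irregular" visual call
with a reproducible number. It is aimed at vascular-imaging researchers
who want a quantitative plaque-morphology endpoint plus the reliability
statistics needed to defend it.

## Method

From a grayscale image the pipeline runs:

1. **Automatic thresholding** by iterative intermeans (IsoData-type): the
   threshold *t* is repeatedly replaced by the mean of the two class mean
   intensities until it converges, and the brighter (echogenic) class
   becomes the plaque mask.
2. **Border extraction** with the Sobel operator: the plaque border is the
   locus of maximal gradient magnitude of the binary mask, which equals
   its 8-connected inner boundary.
3. **Box counting**: grids of side ε cover the border; with N(ε) occupied
   cells (minimum over 10 grid placements per scale),

   FD = − slope of the OLS fit of ln N(ε) against ln ε.

Per patient, **mFD** is the FD of the main (highest-stenosis) plaque and
**gFD** the mean FD over all atherosclerotic segments (undefined when a
calcification shadow hides any border). Validation statistics included:
Spearman rank correlation, ICC(2,1) with 95% CI, Bland–Altman bias and
limits of agreement, repeatability coefficient 1.96·sd(differences), and
within-subject coefficient of variation.

Everything is testable without clinical data through synthetic generators
of known dimension: straight lines (FD 1), Koch curves (ln4/ln3 ≈ 1.2619),
fractional-Brownian-motion graphs (FD = 2 − H), filled squares (FD 2), and
speckled two-region plaque images with exact ground-truth borders.

## Worked example

```r
library(plaquefractal)

# a synthetic far-wall plaque: fBm interface (H = 0.5), speckled
profile <- fbmProfile(0.5, 513, seed = 7, sigma = 0.1)
plaque  <- synthPlaqueImage(profile, 384, 512, noiseAmp = 15, seed = 7)

est <- plaqueBorderFD(plaque$image)
est
#> Box-counting fractal dimension estimate
#>   FD      : 1.2469  (slope -1.2469, intercept 7.580, R^2 0.9986)
#>   scales  : 2, 4, 8, 16, 32, 64, 128 px
#>   counts  : 792, 354, 156, 65, 24, 10, 5
#>   offsets : 10 per scale (seed 0)

fd(boxCountFD(plaque$border))   # FD of the ground-truth border
#> [1] 1.246931
```

The estimate (1.2469) matches the FD of the generator's exact boundary to
four decimals: at this noise level the threshold–Sobel segmentation
recovers the interface pixel for pixel. The R² of 0.999 says the log–log
relation is effectively linear across the seven scales, i.e. the border
behaves like a fractal over that range.

Reliability statistics for a paired re-reading study:

```r
pairs <- synthPairedMeasures(20, seed = 11)
agreementStats(pairs$m1, pairs$m2)
#> Agreement statistics for paired FD measurements
#>   n pairs : 20
#>   ICC(2,1): 0.874  (95% CI 0.713 - 0.948)
#>   bias    : -0.0052  (LoA -0.0403 to 0.0299)
#>   RC      : 0.0351
#>   CV      : 1.13%
```

A command-line front end covering the same pipeline (subcommands `fd`,
`batch`, `synth`, `agree`, `cohort`) is installed at
`inst/scripts/plaquefd.R`; example CSV schemas ship in `inst/extdata/`
(synthetic data).

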