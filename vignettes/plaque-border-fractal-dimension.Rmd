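---
title: "Measuring plaque border irregularity by box-counting fractal dimension"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring plaque border irregularity by box-counting fractal dimension}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(plaquefractal)
```

## The measurement problem

Irregularity of the atherosclerotic plaque surface is an imaging marker of
plaque vulnerability, but visual classification into "regular" versus
"irregular" is subjective and poorly standardized. This package implements
a quantitative alternative: treat the plaque border seen on a long-axis
B-mode ultrasound view as a planar curve and measure its **fractal
dimension (FD)** by box counting. A perfectly smooth border has FD close
to 1; a maximally convoluted, space-filling border approaches 2. The
number is unitless, operator-independent once the region of interest is
fixed, and reproducible.

The pipeline has three stages:

1. **Binarization.** The grayscale image is thresholded with an iterative
   intermeans (IsoData-type) automatic threshold: starting from the global
   mean intensity, the threshold is repeatedly replaced by the average of
   the mean intensity of the two classes it induces, until the update
   falls below 0.5 intensity units. The echogenic (bright) class becomes
   the plaque foreground.
2. **Border extraction.** The plaque border is the locus of highest
   gradient magnitude of the binary mask under the 3x3 Sobel operator.
   On a binary image this locus coincides with the 8-connected inner
   boundary -- every foreground pixel with at least one background pixel
   among its 8 neighbors -- and the package computes that boundary
   directly, which is exact, idempotent and fast. (The equivalence can
   fail only in contrived configurations where opposite background
   neighbors cancel both Sobel kernels simultaneously; such pixels do not
   arise on the boundaries of connected plaque masks.)
3. **Box counting.** The border raster is covered with square grids of
   side $\varepsilon$; $N(\varepsilon)$ is the number of occupied cells.
   For a fractal curve $N(\varepsilon) \propto \varepsilon^{-D}$, so $D$
   is estimated as minus the slope of the ordinary least-squares fit of
   $\ln N(\varepsilon)$ on $\ln \varepsilon$:

$$ \widehat{D} \;=\; -\,\frac{d\,\ln N(\varepsilon)}{d\,\ln \varepsilon}. $$

Per patient, two summary measures are defined: **mFD**, the FD of the
main plaque (the one with the highest degree of stenosis), and **gFD**,
the mean FD over all atherosclerotic segments (common carotid, bulb,
internal carotid, both sides). gFD is reported as undefined whenever any
segment's border is hidden by a calcification shadow, because that
segment's FD cannot be measured; mFD is unaffected unless the main plaque
itself is shadowed.

```{r example}
profile <- fbmProfile(0.5, 513, seed = 7, sigma = 0.1)
plaque <- synthPlaqueImage(profile, 384, 512, noiseAmp = 15, seed = 7)
est <- plaqueBorderFD(plaque$image)
est
```

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `threshold` | automatic | manual intensity threshold (0--255) overriding the intermeans threshold |
| `polarity` | `"auto"` | which class is plaque; `auto` selects the brighter class, matching echogenic plaque on a dark lumen |
| `scales` | powers of 2 | box sides $\varepsilon$ (px), from 2 up to 40% of the larger raster dimension; at least 5 are required for a stable fit |
| `nOffsets` | 10 | grid placements per scale; the count used is the **minimum** over placements, the standard grid-placement bias reduction |
| `seed` | 0 | RNG seed for the random grid offsets; the un-shifted grid is always included |
| `aggregate` | `"min"` | `"mean-fd"` instead fits one FD per grid placement and averages the FDs |
| `minComponent` | 0 (off) | optional removal of foreground components below this pixel count; no despeckling is applied by default |

Convergence of the threshold iteration is declared at an update below 0.5
intensity units -- half the spacing of the 8-bit histogram, so further
iterations cannot move the binarization by a full gray level. Estimates
with a log--log fit $R^2 < 0.9$, or falling outside $[0.9, 2.1]$ (beyond
the plausible range for a planar border), carry a warning flag on the
`FDEstimate` object rather than failing, since both usually indicate a
segmentation problem worth inspecting, not a numerical one.

The `auto` polarity rule (pick the polarity whose foreground mean exceeds
its background mean) provably selects bright-object for any threshold
strictly inside the intensity range; it exists so that a caller can still
force `dark` for atypical material.

## Synthetic validation data

Clinical images cannot ship with the package, so every stage is validated
against synthetic inputs of analytically known dimension:

* **Straight lines and filled squares** pin the two ends of the
  dimension range (1 and 2).
* **Koch curve** iterates have similarity dimension
  $\ln 4 / \ln 3 \approx 1.2619$; iterate 6 rasterized at 2187 px is the
  standard mid-range benchmark.
* **Fractional Brownian motion graphs** with Hurst exponent $H$ have
  dimension $2 - H$, giving a continuously tunable roughness dial that
  mimics how plaque borders vary from smooth ($H$ high) to ragged
  ($H$ low).
* **Plaque-like images** place an fBm profile as a horizontal interface
  (far-wall plaque geometry): echogenic plaque below, dark lumen above,
  with multiplicative uniform speckle-like noise. The generator returns
  the exact boundary raster, so the pipeline can be scored pixel for
  pixel against ground truth.

The fBm generator uses midpoint displacement **with successive random
additions**: at each dyadic level every already-placed point, not only the
new midpoints, receives Gaussian noise with per-level scale
$\sigma\, 2^{-Hl}$. Plain midpoint displacement leaves early-placed points
too smooth at fine scales; with additions, the measured mean-squared
increments scale as $\tau^{2H}$ to good accuracy across
$H \in [0.3, 0.7]$. The base amplitude defaults to $\sigma = 1$ relative
to the unit horizontal span, making the vertical extent comparable to the
span, which keeps the box-counting scale window inside the local
(self-affine) regime where the $2 - H$ law is observable.

Rasterization is isotropic (one scale factor for both axes, the larger
extent mapping to the requested width) and draws one-pixel-thick
8-connected segments, so the raster is a legitimate curve for box
counting at every scale.

### Validation problem sizes

The package's validation experiments use: Koch iterate 6 at 2187 px;
fBm dimension-law runs with $n = 8193$ points (13 dyadic levels)
rasterized at width 512, averaged over 20 seeds per $H$; and end-to-end
pipeline runs on 512x512 plaque images over five roughness levels
($H \in \{0.2, 0.35, 0.5, 0.65, 0.8\}$, amplitude $\sigma = 0.1$ so the
interface fits the frame) with 10 seeds each at noise amplitude 20.
The $n = 8193$ choice follows a convergence study: seed-mean FD
approaches $2 - H$ monotonically as dyadic levels are added, and 13
levels is where the remaining change per doubling drops below the
seed-to-seed scatter.

### Known bias of box counting on rough self-affine graphs

Box counting systematically underestimates the dimension of rough
self-affine graphs: at $H = 0.3$ (true $D = 1.7$) the seed-mean estimate
here is about $1.60$--$1.62$, while at $H = 0.7$ the bias is below
$0.02$. The deficit shrinks as the profile gains dyadic levels but does
not vanish at practical sizes, because the finest scales are limited by
the one-pixel curve thickness and the coarsest approach the global regime
where any graph looks one-dimensional. Restricting the fit to scales
below the self-affine crossover was evaluated and gained less than 0.01,
so the default scale series is used unchanged. Consequently FD values
from this estimator should be compared **within** the method, not read as
absolute Hausdorff dimensions -- exactly how the clinical measures mFD
and gFD are used. Monotonicity in roughness, the property the clinical
application relies on, is preserved: seed-mean FD strictly decreases in
$H$.

### What the synthetic cohort does and does not emulate

`synthCohort()` plants a latent inverse association between main-plaque
FD and HDL cholesterol (default magnitude 0.4) in a cohort whose
marginals match an asymptomatic carotid-stenosis population: 42 patients,
mFD $\sim \mathcal{N}(1.136, 0.039^2)$, log-normal HDL-C with median 41
(IQR 36--47) mg/dL and triglycerides with median 133 (IQR 99--164) mg/dL,
a median of 4 atherosclerotic segments per patient, and a calcified
non-main segment in ~10% of patients (whose gFD is therefore undefined).
`synthPairedMeasures()` emulates a 20-plaque re-reading study with
per-reading noise SD 0.0145, which implies a repeatability coefficient
near 0.04, an ICC near 0.9 and a within-subject CV near 1.3%.

Passing tests on these generators show that the statistics recover what
was planted under the stated noise models. They do **not** show that real
ultrasound segmentation is accurate: the speckle model is multiplicative
uniform noise rather than Rayleigh-distributed, fully developed speckle;
there is no point-spread function, attenuation, or acoustic shadowing;
and the plaque interface is a single-valued horizontal profile, so
overhanging ulcerations are not represented. With two well-separated
tissue levels the intermeans threshold recovers the true interface almost
exactly; real images with low contrast-to-noise will behave worse, which
is why the reliability statistics (ICC, Bland--Altman, repeatability
coefficient, CV) are part of the package rather than an afterthought.

## Agreement and association statistics

For paired measurements of the same plaques (two raters, or two sessions
a month apart):

* **ICC(2,1)** -- single-measure, absolute-agreement, two-way
  random-effects intraclass correlation, the standard model when both
  raters rate every subject and rater effects should count against
  agreement. The 95% interval uses the F-distribution method. The model
  choice matters: a constant offset between raters lowers ICC(2,1) but
  would not lower a consistency-type ICC.
* **Bland--Altman**: bias $= \overline{d}$, limits of agreement
  $\overline{d} \pm 1.96\,s_d$ with the sample SD of the differences, and
  the **repeatability coefficient** $\mathrm{RC} = 1.96\,s_d$ (so RC is
  exactly half the width of the limits). Some texts define RC as
  $2.77\,s_w$ with $s_w = s_d/\sqrt{2}$ the within-subject SD; the two
  are identical to three digits ($1.96\sqrt{2} = 2.772$).
* **Coefficient of variation**: $100 \cdot s_w / \bar{m}$ with $\bar{m}$
  the grand mean of all measurements.

Association with clinical variables uses Spearman rank correlation with
average ranks for ties and the two-sided $t$ approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n - 2$ degrees of freedom; an exact
permutation p-value is available for $n \le 10$ without ties. Missing
values are deleted pairwise per correlation and listwise within a pair
for agreement statistics. No multiplicity correction is applied; the
correlation table reports every test with its $n$ so downstream users can
adjust as they see fit.

```{r agreement}
pairs <- synthPairedMeasures(20, seed = 11)
agreementStats(pairs$m1, pairs$m2)
```

## Numerical and design notes

* Box counts use exact integer cell indices (`floor((pixel + offset) /
  eps)`), so the nested-loop definition and the vectorized implementation
  agree exactly; ties in the OLS never arise because scales are strictly
  increasing.
* The minimum-over-offsets count is never larger than the un-shifted
  grid's count, so adding offsets can only tighten the covering -- the
  direction that reduces grid-placement bias.
* A constant-count series fits the flat line exactly, so its $R^2$ is
  reported as 1 and the FD is 0 (a single pixel is the canonical case).
* Convergence, degenerate and error cases are first-class: constant
  images refuse automatic thresholding (a manual threshold must be
  supplied), empty masks refuse border extraction, rasters whose scale
  series would drop below five scales refuse estimation and suggest
  upsampling.
* Coordinates are 0-based (row, col) with half-open ROIs; image edges are
  handled by replication in both the Sobel operator and the boundary
  definition, so an object flush against the frame edge contributes no
  spurious border there.
* All stochastic steps (grid offsets, every generator) are pure functions
  of their parameters and an explicit seed.

## Limitations

* The exact "Default"/IsoData variant and the box-counting defaults of
  the reference GUI tools are not published in detail; this package's
  intermeans threshold and power-of-two scale series are deterministic,
  documented approximations, and both are overridable. Absolute FD values
  may differ slightly from GUI-derived ones; comparisons should stay
  within one toolchain.
* Box counting underestimates the dimension of very rough borders (see
  above); FD is a ranking instrument here, not an absolute dimension.
* 3-D plaque geometry is out of scope: the measure is defined on a
  single long-axis section.
* Borders hidden by calcification shadows cannot be measured; affected
  patients keep mFD but lose gFD, and the package propagates that rule
  rather than imputing.
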