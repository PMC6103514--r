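---
title: "Methods: image-based prediction of foliar nitrogen in sandalwood"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image-based prediction of foliar nitrogen in sandalwood}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopyN)
library(tibble)
```

## The problem

Sandalwood (*Santalum album*) is nitrogen-sensitive: both deficiency and
excess slow heartwood formation, and conventional diagnosis (leaf sampling
plus combustion analysis) is destructive and slow. canopyN implements an
image-based alternative: fixed field cameras photograph each sapling, the
plant is segmented from a complex background of soil, weeds and other
plants, and foliar total nitrogen is predicted from the segmented canopy's
colour statistics and a shape-based "growth status" indicator. Because the
colour features are themselves estimates derived from an imperfect
segmentation, the package also provides an errors-in-variables estimator
alongside ordinary least squares.

## Segmentation cascade

The cascade exploits two complementary CIELAB channels. The b
(blue–yellow) channel separates green vegetation from soil; the L
(lightness) channel separates the bright target sapling from darker
neighbouring plants. The five steps are:

1. convert the RGB frame to Lab (sRGB companding, D65 white — the standard
   assumption for uncalibrated camera output) and extract b and L;
2. quantize each channel to 256 bins and Otsu-threshold both, recording
   `T_b`, `T_L` and binary masks `I_b`, `I_L`;
3. apply a 7×7 majority filter to `I_b` and zero the background of the
   original frame (`I_b1`);
4. reconvert `I_b1` to Lab and re-binarize its L channel at the *original*
   `T_L` (`I_b2`), removing darker plants that share the plant's b range;
5. majority-filter again, erode twice and dilate twice with a radius-5
   disk, and mask the original frame (`I_b3`).

Numerical conventions, all deliberate and all configurable where the
underlying choice is genuinely open:

* **Otsu** maximizes between-class variance over the 256-bin histogram of
  the quantized channel, splitting at `value <= t` versus `value > t`;
  ties go to the smallest maximizing threshold; a constant channel is an
  error.
* **Polarity.** Which Otsu class is "plant" is not derivable from the
  threshold itself. The defaults — b "high" (vegetation is yellow-shifted
  relative to soil) and L "high" (the target is brighter than competing
  plants) — encode the field situation the cascade targets; both are
  arguments of `seg_config()`. Under polarity "high" foreground is
  strictly above the threshold; under "low" it is `<= t`, so the two
  polarities partition the pixels with exact-threshold pixels in the low
  class.
* **Majority filter.** A median filter on 0/1 input is a majority vote; a
  tie (possible only for even windows) resolves to background, keeping the
  cascade conservative. Borders are handled by edge replication.
* **Morphology.** The disk of radius `r` contains offsets with
  `dx² + dy² <= r²` (centre included). "Erode twice, dilate twice" is
  applied literally in that order — not an opening applied twice. Erosion
  treats out-of-frame pixels as background; dilation clips to the frame.
* **Step 4** cannot resurrect pixels zeroed in step 3: background pixels
  of `I_b1` convert to `L = 0`, and the result is additionally intersected
  with the step-3 mask so this holds under either polarity.

## Growth status

Nitrogen supply affects biomass and hence canopy shape, not just colour.
The growth-status indicators measure how densely the plant fills its
enclosing shape:

$$GS_{MER} = S_p / MER_p, \qquad GS_{MCC} = S_p / MCC_p$$

with `S_p` the plant pixel count and `MER_p`, `MCC_p` the pixel counts of
the minimum enclosing rectangle and the minimum circumscribed circle.
Geometry is computed on pixel centres (0-based, x = column, y = row): the
circle by Welzl's move-to-front algorithm on the convex hull, the
rectangle by rotating calipers over hull-edge orientations (the minimum-
area rectangle has a side collinear with a hull edge). Both are validated
in the test suite against exhaustive oracles — all pair/triple candidate
circles, and every hull-edge orientation evaluated with explicit rotation
matrices.

Design choices:

* "Minimum enclosing rectangle" is read literally as the minimum-**area**
  rotated rectangle; an axis-aligned mode is available
  (`rotated = FALSE`) since the original description does not show the
  rectangle.
* `MER_p` and `MCC_p` are rasterized counts of integer pixel centres
  inside the shape, because the indicator is defined as a pixel ratio. An
  enclosing shape may overhang the frame (e.g. the rotated square around a
  disk near the border); its full lattice count is used so the ratio stays
  geometry-true.
* Degenerate masks (single pixel, collinear pixels) define the enclosing
  count as `max(S_p, lattice count)`, so `GS <= 1` always; ratios are
  clamped to `(0, 1]` by default because boundary rasterization can push
  them marginally above 1.

For a disk these definitions give `GS_MER ≈ π/4 ≈ 0.785` and
`GS_MCC ≈ 1`, which the tests verify together with translation, rotation
and scale invariance.

## Features and screening

Each sample record holds the mean of all nine channels (R, G, B on the
8-bit scale; H, S, I in [0, 1] from the arccos-hue HSI transform; L, a, b
native) over foreground pixels only, plus the two GS ratios and measured
total nitrogen. Means stay on native scales because fitted coefficients
couple to scale; quantization is internal to Otsu. Total nitrogen is
treated as unit-agnostic (the source measurements are printed without
units). `pearson_screen()` reports two-tailed Pearson correlations with
0.05/0.01 flags; the mixed "RLI" system combines the R, L and I channels —
the three strongest single-channel correlates of nitrogen — in that order.

## Model families

Five families, each with an optional growth-status intercept
`a_gs = b0 + b1·GS` (GS either variant):

| family | expression |
|---|---|
| linear | `y = a_gs + Σ a_i x_i` |
| reciprocal | `y = a_gs + Σ a_i / x_i` |
| power | `y = a_gs + a0 Π |x_i|^{a_i}` |
| logarithmic | `y = a_gs + a0 ln|Σ a_i x_i|` |
| exponential | `y = a_gs + a0 exp(Σ a_i x_i / x'_i)` |

The source table prints the reciprocal family with the same expression as
the linear one — an evident typographical duplication; this package
implements it as `Σ a_i / x_i`, consistent with its name, and documents
the assumption. The absolute values in the power and logarithmic families
follow the printed expressions. The exponential normalizers
`x'_i = max(x_i) − min(x_i)` are computed on the modeling subset at fit
time and frozen into the model; they are never recomputed at prediction.

## Estimation

**Least squares.** The parameters entering each family linearly
(`b0`, `b1`, `a0`) are profiled out exactly by linear regression, so the
optimizer searches only the per-channel coefficients; the linear and
reciprocal families reduce entirely to closed form. Nonlinear families use
BFGS/Nelder–Mead from warm starts (log-linearized fits where the residual
sign permits, the linear-fit direction, and seeded random restarts —
deterministic via a local RNG), followed by a Newton refinement with
finite-difference derivatives. Non-convergence is flagged on the result,
never silent.

**Errors-in-variables.** Segmentation error propagates into the colour
means (the package's own accuracy bound is 3% on channel means) and into
GS (5% on pixel counts), so the predictors carry measurement error and
least squares is attenuated. The EIV estimator minimizes

$$\sum_i \left[ \frac{(y_i - f(\xi_i; c))^2}{\sigma_y^2}
 + \sum_j \frac{(x_{ij} - \xi_{ij})^2}{\sigma_j^2} \right]$$

jointly over coefficients `c` and latent true predictors `ξ`. The
algorithm: warm start at the least-squares fit; alternate (a) an exact or
damped Gauss–Newton solve of the latents — a rank-one
(Sherman–Morrison) linear solve per sample, vectorized across samples,
exact in one step for the linear family — with (b) a coefficient refit on
the current latents; then polish the profiled objective `Q(c) = Σ_i
min_ξ [...]` with BFGS and a Newton step, using the envelope-theorem
analytic gradient. The objective is non-increasing across iterations (the
trace is stored and asserted in tests). For straight-line data with equal
error variances this reproduces the closed-form Deming estimator to
better than 1e-6.

**Error variances.** The covariance is taken diagonal — nothing in the
data identifies off-diagonal error structure. By default
`σ_j = 0.03·mean|x_j|` for colour channels and `0.05·mean(GS)` for the GS
predictor (the package's segmentation accuracy bounds, with the pixel-
count bound applied to the pixel-count-derived indicator), and `σ_y²` is
the least-squares residual variance floored at 1e-8. All entries are
overridable via `eiv_sigma()`; zero predictor variances are floored to a
tiny value, in which limit the EIV fit coincides with least squares (a
tested invariant).

**Identifiability.** The logarithmic family is invariant under scaling
`a → k·a` (absorbed as `a0·ln k` into `b0`), so its channel coefficients
are identified only up to scale; recovery tests compare the normalized
coefficient direction and predictions. The other four families are
checked for exact coefficient recovery on noiseless data (to 1e-6) and
for sign recovery at low noise.

## Evaluation and ranking

With residuals `y_i − y'_i`:

* `e̅` — mean residual;
* `δ²` — sum of squared residuals over `n − 1`;
* `mse = e̅² + δ²` and `rmse = √mse`;
* `R² = 1 − Σ(y−y')² / Σ(y−ȳ)²`.

Two deviations from the printed formulas, both deliberate and flagged in
the function documentation: the printed R² omits the squaring of both sums
(the unsquared form is not even sign-stable, and the printed fit statistics
are impossible under it), and every printed "MSE" in the validation tables
equals `√(e̅² + δ²)` rather than `e̅² + δ²` — verified programmatically for
all 14 printed (e̅, δ², MSE) triples — so both quantities are returned,
with the table-compatible one labelled `rmse`.

`rank_models()` ranks candidates on six criteria (modeling R² and |e̅|;
validation R², |e̅|, δ², rmse), 1 = best, ties sharing the lower rank, and
aggregates by sum of ranks (the aggregation used by the original analysis
is unstated; sum-of-ranks is the default and the aggregate function is an
argument). On the seven published candidate models this scheme places the
Lab exponential model second by a whisker behind the RGB exponential —
close to, but not exactly, the published order, which no aggregation of
the six stated criteria reproduces exactly.

## Synthetic fixtures

No field imagery is distributable, so all image-level claims are tested on
rendered scenes with exact ground truth. `render_scene()` paints the scene
directly in Lab — plant (L 65, a −25, b 40), soil (L 45, a 8, b 18) and
optional darker distractor plant (L 30, a −20, b 35), each with Gaussian
jitter (SD 2) — and converts to RGB. Painting in Lab guarantees by
construction the two separations the cascade exploits: plant vs soil in b,
plant vs distractor in L. The default frame is the 1024×768 field-camera
format; tests and the acceptance script render 320×240 scenes with plant
radii of 40–55 px, which preserve the structure at a fraction of the cost.

`generate_samples()` draws true predictors uniformly from per-channel
ranges (defaults are typical green-vegetation bands, e.g. L in [35, 80], a
in [−45, −8] — full native ranges would be botanically meaningless and
push the nonlinear families into overflow), evaluates a known model at the
true values, and adds Gaussian noise to both response and predictors —
exactly the data-generating process the EIV estimator assumes. True values
are retained in `true_*` columns for oracle checks.

What the generator does **not** emulate: illumination gradients and
shadows across the frame, leaf-scale texture, specular highlights,
occlusion between plants, and camera white-balance drift. Passing the
segmentation suite therefore shows the cascade implements its stated
mechanism correctly — not that 5%/3% accuracy holds on arbitrary field
imagery, where those effects dominate.

## Problem sizes and tolerances

The test suite and acceptance script use: 20 seeded 320×240 scenes for the
segmentation bounds; 200 random ≤30-point masks against the geometric
oracles (1e-9); 100 random images against the Otsu oracle (exact); 1000
random straight-line datasets against the Deming closed form (1e-6); 200
Monte-Carlo replicates (n = 60 each, roughly the scale of the original
72-tree field study) for the EIV-vs-LSM bias comparison, with the
published optimal-model coefficients as the generative truth; and 60-
sample noiseless designs for exact interpolation (1e-6). These sizes are
the package's chosen verification scale: large enough for stable
statistics, small enough to run everywhere.

## Known limitations

* One plant per frame: growth status is defined for the whole foreground,
  with no per-component analysis.
* No colour calibration or white-balance correction; the method assumes
  midday imagery as in the original acquisition protocol.
* The published fitted coefficients cannot be re-derived here — the
  original 72-sample dataset was never deposited — so they ship only as a
  reference model for prediction, and all estimator claims are validated
  on synthetic data with known truth.
* Coefficient standard errors are not reported (neither estimator's
  original analysis did); the Monte-Carlo machinery in the test suite is
  the substitute for uncertainty statements.
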