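---
title: "Detecting artificially marbled beef: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting artificially marbled beef: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marblesense)
```

## The problem

Fat injection turns cheap lean beef into a product that visually mimics
premium Wagyu marbling, and such cuts are routinely mislabelled at the
point of sale. The two products differ in how the fat is arranged on the
cut surface: natural Wagyu marbling consists of many small, scattered,
mostly disconnected flecks of varying thickness on bright-red lean,
whereas injected fat forms fewer, elongated, interconnected streaks with
a clear dominant direction, typically on darker red lean. `marblesense`
implements an image-analysis pipeline that exploits exactly these
surface cues to classify a smartphone photograph of a beef surface as
*Wagyu*, *regular* or *fat-injected*.

## The pipeline

1. **ROI masking.** The capture protocol centres the cut inside a black
   elliptical mask. At the working resolution of 960 × 720 pixels
   (inputs at other sizes are resampled bilinearly) the default mask
   spans 75 % of each dimension: a 720-pixel major and 540-pixel minor
   axis centred at (480, 360). A pixel belongs to the ROI when its
   *centre* `(x + 0.5, y + 0.5)` satisfies the ellipse inequality,
   boundary inclusive. This convention is not cosmetic: it is the one
   under which the grid geometry below gives exactly 55 complete
   64 × 64 blocks and 36 complete 80 × 80 blocks, the block counts the
   rest of the system is built around.

2. **Gridding.** The frame is tiled by square blocks anchored at the
   image origin, with half-open windows `[x, x + s) × [y, y + s)`;
   margins that do not fit a whole block are discarded, and only blocks
   entirely inside the ellipse are kept (the ellipse is convex, so
   testing the four corner pixels is exact — this shortcut is verified
   against per-pixel brute force in the test suite). Blocks are the unit
   of feature extraction and classification; the default block side is
   80 pixels, the size that maximised classification performance in the
   size sweep 64–84.

3. **Texture features.** Each block is converted to grayscale
   (Rec. 601 luma, rounded) and described by a uniform local binary
   pattern histogram. At each interior pixel the `P` neighbours on a
   circle of radius `R` are thresholded against the centre
   (`neighbour >= centre` sets the bit, bit *k* weighted `2^k`); codes
   whose circular bit string has at most two transitions are *uniform*.
   For `P = 8` there are 58 uniform codes, mapped in ascending order
   onto bins 0–57, with all other codes pooled in bin 58 — a 59-bin
   histogram, normalised by the number of computed codes
   (`(s − 2R)²` for block side `s`; no padding is used at block
   borders). The default operator is LBP(8, 1); LBP(8, 2) and
   LBP(16, 2) are supported, the latter with the corresponding
   `16 · 15 + 2 + 1 = 243`-bin histogram.

4. **Colour features.** Per block, the mean and population
   (divide-by-N) standard deviation of each channel, in RGB and
   optionally HSV and CIE L\*a\*b\*, every channel rescaled to a common
   0–255 range (H by 255/360; S, V by 255; L\* by 255/100; a\*, b\*
   shifted by +128). HSV uses the hexcone model, L\*a\*b\* the sRGB
   primaries with D65 white. The default feature combination is
   LBP + RGB, i.e. 59 + 6 = 65 values per block; combinations up to
   LBP + RGB + HSV + L\*a\*b\* (77 values) are available.

5. **Scaling and classification.** Features are min–max scaled to
   [0, 1] with bounds learned on the *training split only* and frozen
   thereafter; test values outside the training range are clipped, and
   constant training dimensions map to 0. Blocks are classified by an
   RBF-kernel SVM (`K(x, y) = exp(−γ‖x − y‖²)`), default `C = 64`,
   `γ = 1`, the optimum of a 5 × 5 grid search over
   `C ∈ {16…256} × γ ∈ {0.25…4}` (the refined region of the dyadic
   range `[2⁻⁸, 2⁸]`; grid-search ties are broken toward smaller `C`,
   then smaller `γ`).

6. **Voting.** The image label is the plurality class over its block
   labels. Ties are resolved conservatively in the order
   fat-injected > regular > Wagyu, so an ambiguous image is flagged as
   the suspect class rather than waved through.

### Why one-vs-one

A single binary sign rule cannot separate three classes, so the
three-class machine is realised as the standard one-vs-one construction:
three pairwise RBF C-SVCs whose votes are tallied per block, with 1-1-1
vote ties broken by the same fat-injected > regular > Wagyu priority used
at the image level. The pairwise machines come from libsvm (via e1071)
with a fixed tolerance of 1e-3 and no randomised components, so training
is deterministic for a fixed input order; the package's own one-vs-one
layer exists precisely to control the tie-break, which libsvm's internal
voting does not expose. An independent kernel implementation (kernlab)
serves as a cross-check in the test suite, never as the implementation.

### LBP neighbourhood convention

Neighbour *k* sits at angle `2πk/P` counterclockwise from the +x axis
(y downward). For the unit-radius 8-point operator the diagonal circle
points `(±0.707, ±0.707)` are snapped to the surrounding 3 × 3 pixel
ring — the operator's classical definition at `R = 1` — so no
interpolation is involved; radius-2 configurations sample the exact
circle with bilinear interpolation at constant per-offset weights.
Histograms produced under the opposite circular orientation are
permutations of each other, so the choice does not affect
classification; it is simply fixed once.

## Evaluation metrics

The screening task is one-vs-rest for the fat-injected class. With
`TP` the correctly detected injected items and `FP` the non-injected
items flagged injected, the package reports, at both block and image
level, as percentages:

* misjudgment rate `α = FP / (all truly non-injected)` (Type I error);
* detection rate (recall) `1 − β = TP / (all truly injected)`;
* precision `TP / (all flagged injected)`;
* classification rate `CR` = three-class accuracy (confusion-matrix
  trace over total);
* `F1 = 2·recall·precision / (recall + precision)` for the fat-injected
  class.

Zero-denominator metrics are reported as `NA` with a warning — never
silently as 0 or 100, which would corrupt parameter sweeps.

## The synthetic data generator

No public corpus of Wagyu / regular / fat-injected surface images
exists, so the package ships a seeded generator that renders the three
phenotypes' *contrasts* rather than photorealistic meat:

* a lean background with class-specific colour (bright red for Wagyu,
  mid red for regular, dark red for fat-injected), low-frequency
  mottling, and spatially correlated surface grain (noise drawn at half
  resolution and upsampled — per-pixel white noise would make the
  texture features implausibly fragile under the slightest resampling,
  which no camera image of tissue is);
* near-white anti-aliased elliptical fat primitives: many small
  low-elongation scattered flecks with variable area for Wagyu; sparse
  flecks for regular; few, strongly elongated streaks chained
  end-to-end along a jittered dominant orientation for fat-injected.
  Primitives are added until a per-image target fat fraction of the ROI
  is covered, and the binary mask actually rendered is returned as
  ground truth.

Default parameters (fat fraction 18–32 % Wagyu / 2–7 % regular /
15–28 % injected; 140–260 / 8–25 / 24–48 primitives; elongation up to
3 / 3.5 / 5–12) are free parameters of the generator chosen once to
realise the qualitative contrasts above; they are not measurements of
real beef. Consequences worth stating plainly: the synthetic classes
are *more* separable than real photographs (the end-to-end synthetic
study reaches a higher classification rate than one should expect on
real data), and passing tests demonstrate that the pipeline's machinery
is correct and its robustness trends are directionally right — not that
these accuracy figures transfer to the meat counter.

Capture-condition perturbations mirror the robustness studies: a
seven-level brightness ladder `μ + 1.5kσ, k = −3…3` (the reference
ladder's printed values 72.94 … 176.82 arise at `μ = 98.91`,
`σ = (98.91 − 72.94)/1.5 ≈ 17.31`; for sweeps on synthetic data the
ladder is calibrated to the images' own mean ROI brightness, exactly as
the reference values were to theirs), opaque label rectangles with
text-like strokes at a controlled fraction of the ROI, soft-edged
specular reflections, and a perspective tilt warp (camera rotation
about the horizontal or vertical axis, focal length one image width,
bilinear resampling, near-black fill outside the source frame).

## Numerical and degenerate-input choices

* Population rather than sample standard deviation (at 6 400 pixels per
  block the difference is negligible, but one convention keeps tests
  bit-stable).
* The scaler maps degenerate (constant) dimensions to 0 and clips
  out-of-range test values into [0, 1].
* `vote_image` and the SVM vote share one priority order; both are
  permutation-invariant in their inputs.
* Blocks smaller than `2R + 1` pixels, empty label lists, mismatched
  dimensions and unknown colour spaces raise immediate errors rather
  than producing silent partial results.
* All generator randomness flows from one integer seed per image;
  identical seeds give bit-identical images.

## Study sizes used for validation

The packaged studies follow the reference designs: small-sample
parameter work at 80 images per class (40/20/20) and the large-sample
evaluation at 200 images per class (120/40/40 train/validation/test),
i.e. 600 images and 21 600 grid blocks at 36 blocks per image, with
sensitivity sweeps on 60 test images (20 per class). These sizes are
the package's validation defaults; everything scales linearly in image
count.

## Known limitations

* The CNN comparison arm of the original system is out of scope; the
  package implements the SVM pipeline only.
* No illumination normalisation or glare removal is attempted beyond
  the perturbation studies; the system assumes the capture protocol's
  mask discipline.
* The generator renders surface phenotypes, not packaging, bone, or
  cut-to-cut anatomical variation; robustness numbers under its
  perturbations are qualitative guides, not field performance claims.
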