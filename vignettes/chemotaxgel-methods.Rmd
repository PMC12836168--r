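---
title: "Models and methods behind chemotaxgel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chemotaxgel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(chemotaxgel)
```

chemotaxgel quantifies three things about a four-well collagen hydrogel
chemotaxis chamber: how fast molecules diffuse through the gel, how
viscoelastic the gel is, and whether stromal cells seeded in the outer wells
migrate preferentially toward the tumor-cell well at the center. This
vignette explains the models behind each quantity, the tunable parameters
and their defaults, what the synthetic-data generators emulate, and the
numerical choices that make every result deterministic and testable.

## Chamber geometry

The chamber holds one central well and three outer wells at the vertices of
an equilateral triangle, so every outer well sees the same gradient from the
center. `chamber_layout()` encodes this with an *edge-to-edge* spacing
convention: the default 1460 µm is the clear gel gap between well rims, so
the center-to-center distance is `spacing + diameter` (3090 µm for the
fabricated 1630 µm wells). The equilateral construction automatically makes
any two outer wells farther apart than each is from the center, which is the
design intent: gradients form preferentially between stromal and tumor
wells, not between stromal wells.

Rasters use row-major image coordinates (origin top-left, y down). Pixels
belong to a well disk when their *center* lies inside it — an area-weighted
membership would be slightly more accurate but is not reproducible across
implementations, and determinism matters more here. Quadrant masks assign
pixels by half-open intervals on their center coordinates, and the central
exclusion disk uses `<=` on pixel-center distance; together the four
quadrants plus the disk tile a square crop with no gaps and no overlaps,
which the tests assert per pixel.

## Diffusion: model, fitting, and the forward simulator

Tracer transport away from a loaded well is summarized by the
one-dimensional instantaneous point-source solution

$$I(x, t) = \frac{A_0}{\sqrt{4 \pi D t}}
  \exp\!\left(-\frac{x^2}{4 D t}\right),$$

with $A_0$ the total released amount, $D$ the diffusion coefficient
(µm²/s), and $x$ the distance from the well rim. Profiles are extracted as
four 500 µm rays (north, south, east, west) anchored at the rim pixel,
sampled per pixel and averaged pointwise; each time point is then divided by
its value at $x = 0$. On normalized profiles the model reduces to
$\exp(-x^2 / 4 D t)$ and only $D$ remains. Fitting un-normalized profiles
(with $A_0$ free) is available as a sensitivity check; normalized fitting is
the default because that is how gradient shapes are compared across tracers.

Two numerical choices matter:

* **The fit is one-dimensional and solved globally.** For any candidate $D$
  the optimal amplitude has a closed form, so the residual sum of squares is
  a function of $D$ alone. We scan 201 log-spaced candidates over
  $[10^{-4}, 10^{4}]$ µm²/s and refine the best bracket with Brent's method.
  This has no starting-value sensitivity and no randomness; the same data
  always give the same $\hat D$. A method-of-moments initializer would serve
  a descent-based optimizer, but with an exhaustive 1-D scan there is
  nothing to initialize.
* **Injection-time frames are excluded.** The model is singular at
  $t = 0$; the $t = 0$ frame documents the loaded well and never enters the
  fit.

The well is a disk, not a point. Near the rim at early times a disk source
produces complementary-error-function profiles, and fitting the Gaussian
point-source model to them recovers a coefficient biased low by more than
half — we measured $\hat D / D \approx 0.40$ for the fast tracer at the
standard imaging times. For this reason the synthetic tracer generator's
default engine renders frames directly from the rim-anchored point-source
profile: it is the ground truth *for the fitting procedure*, and the
generate–extract–normalize–fit loop recovers $D$ to numerical precision
(the tests require 0.5%). The finite-difference engine (`engine = "fd"`)
retains the disk physics for studying exactly this model mismatch.

The forward simulator itself is an explicit 5-point finite-difference
scheme with zero-flux boundaries, written in conservative flux form so
total mass is constant to floating-point rounding. The time step defaults
to 0.9 of the stability limit $h^2 / 4D$; an unstable requested step is
refined with a message (or rejected in strict mode). Against an independent
Gaussian-kernel superposition oracle, transects at 10 minutes agree within
2% beyond one well radius at a 10 µm grid. When comparing a simulated
transect with any analytic value, note that the four averaged rays sample
pixels whose distances differ by up to half a pixel from the nominal
radius; in a Gaussian tail that half pixel is worth tens of percent, so the
oracle must average the same four sampled pixels.

Synthetic tracer frames are scaled per frame to the full bit range by
default (as acquisition software displays them). Per-time-point
normalization removes that scale anyway, and per-frame scaling keeps the
16-bit quantization error uniformly small across late, dim frames;
`scale = "stack"` preserves cross-frame amplitudes for un-normalized fits.

## Rheology summaries

Rheometer tables reduce to the standard hydrogel summary: the linear
viscoelastic region is the longest leading strain range in which $G'$ stays
within a tolerance (default 5%, configurable — sweeps rarely state a
criterion) of the low-strain plateau, estimated as the median of the first
three points. Moduli at the 1 Hz reporting frequency are interpolated
log-log because collagen moduli are near power-law in frequency; an exact
table row is returned unchanged. The loss tangent is computed from the
*mean* moduli across replicates (matching how a single printed value is
derived from averaged curves), with per-replicate ratios exposed as an
attribute. The dynamic Young's modulus assumes linear isotropy,
$E' = 2 G' (1 + \nu)$, with $\nu = 0.5$ (near-incompressible hydrated
network), so $E' = 3 G'$; its uncertainty is propagated linearly from the
replicate variability of $G'$: $\mathrm{sd}(E') = 2 (1 + \nu)\,
\mathrm{sd}(G')$. Replicate spread is reported as standard deviation across
the independent runs.

## Segmentation primitives

The confluency chain is: 8-bit conversion (min–max), rolling-ball
background subtraction (radius 6 px, light background), percentile contrast
enhancement (0.35% saturation, normalized), pixel-classifier probability
map, Yen threshold, area fraction.

*Rolling ball* is realized as grayscale morphology with a non-flat ball
(sphere-cap) structuring element: closing for light backgrounds, opening
for dark ones, with the background subtracted so deviations sit on a flat
zero field. Constant images map to constant (zero) output, and the output
never exceeds the deviation from the brightest level — both are asserted
against a brute-force morphology oracle.

*Contrast enhancement* saturates `ceiling(n * s / 200)` pixels at each end
(s in percent) and rescales linearly; rank order is preserved between the
tails. A constant image cannot be stretched and is returned with a warning.

*Yen's threshold* maximizes the maximum-correlation criterion over the
256-bin histogram; ties break to the lowest level so the result is
deterministic, and foreground is *strictly above* the threshold, compared
on the same 8-bit quantization the histogram used. The implementation is
tested against an independent exhaustive maximization on 50 seeded images
(and was cross-checked against scikit-image's `threshold_yen` during
development).

*Fixed-threshold binarization* uses `>=` so masks are bit-reproducible; the
migration chain binarizes probability maps at 0.5.

## The stand-in pixel classifier

Interactive, externally trained segmentation tools cannot be reproduced
bit-exactly from a methods section, so the package ships a fully scripted
stand-in whose contract is the same: a per-pixel foreground probability in
[0, 1]. It is a logistic model over a fixed feature bank: raw intensity;
per scale (1, 2, 4 px) the Gaussian smoothing, gradient magnitude, and
Laplacian of Gaussian; and *local-energy* features — the windowed standard
deviation of the smoothed image — plus their ratios to the total local
energy. The energy ratios are the load-bearing features: per-image contrast
normalization destroys absolute amplitude, so a blank field of amplified
sensor noise and a sheet of cell texture can only be told apart by the
*spatial scale* of their fluctuations (white noise loses almost all energy
under smoothing; correlated intracellular texture does not). Training
samples pixels from labeled synthetic tiles spanning the coverage range,
including a blank and a confluent tile.

Predictions apply a confidence-sharpening multiplier (default 6) to the
logistic score. This leaves the 0.5 decision boundary untouched but pushes
boundary-zone pixels toward their majority side, so probability maps are
near-binary — the regime the downstream thresholding assumes, and the
behavior observed of the original interactive maps. Without it, Yen's
entropic criterion systematically assigns the whole boundary-transition
shoulder to the minority class, which costs about ten percentage points of
area at intermediate coverage; with it, recovery on full-format fixtures is
within about 1.5 points. Setting `sharpness = 1` restores raw logistic
probabilities.

## Migration quantification

Each frame is cropped 1:1 around the analyzed well, classified, binarized
at 0.5, and split into NW/NE/SW/SE quadrants after excluding a central
disk. The default exclusion radius is the segmented well-body radius at the
first frame times 1.05 (falling back to the layout's well radius when the
first frame is empty), and all four quadrant fractions share the analyzable
(annulus) area as denominator, so the exclusion choice never rescales
comparisons between wells.

The directional summary is the bias index: with $p$ the share of migrated
area in the quadrants facing the attractant and $e$ the share of analyzable
area those quadrants cover, the index is $(p - e)/(1 - e)$ when $p \ge e$
and $(p - e)/e$ otherwise — 0 under direction-blind spreading, +1 when all
area faces the attractant, −1 when none does. Which quadrants "face" the
center is registered from the chamber geometry (`facing_quadrants()`), not
hard-coded, because the facing pair differs per well and orientation.

Inference compares terminal bias indices between arms with a two-sided
label-permutation test: exact enumeration when the number of relabelings is
at most 10⁴ (70 for 4 + 4 wells, 252 for 5 + 5), seeded Monte Carlo with
the add-one correction otherwise. With five wells per arm the smallest
attainable two-sided p-value is 2/252 ≈ 0.008. Classical ANOVA/post-hoc
machinery is deliberately left to standard routines; the permutation test
is the package's own inferential tool because it stays exact at the small
replicate counts the synthetic experiments use.

## The synthetic-data generators

The generators define the study conditions under which the pipeline is
validated; their defaults were chosen once, from the assay's stated
conditions where available and from field-typical magnitudes otherwise.

**Tracer stacks** render the point-source field at the imaging times 0–40
minutes (see above) with optional multiplicative Gaussian noise.

**Migration movies** come from a biased persistent random walk. Agents
start uniformly on their well's rim; each 30-minute step (matching the
imaging interval, so steps and frames align 1:1) the heading is the
weighted circular mean of the previous heading (weight = persistence, 0.5)
and the local attractant gradient direction (weight = κ · |∇C| / (|∇C| +
g½), with g½ the median non-zero gradient magnitude — a saturating,
receptor-like response), plus von Mises noise (concentration 3, sampled
with the Best–Fisher rejection method); displacement is 15 µm per step
(within the 10–40 µm/h range of mesenchymal cells in collagen). The default
chemotactic bias κ = 2 represents a strongly chemotactic population;
κ = 0 is the unbiased control. The attractant field is quasi-static — the
diffusion field of an albumin-like attractant (D = 0.6009 µm²/s) at 24 h,
computed once — which suffices for testing the quantifier; the simulator
does not model self-generated (sink-type) gradients, matrix remodeling, or
durotaxis. Rendered cells are 40 µm anti-aliased disks on a light
background (a spread fibroblast at the 20 µm/px rendering scale), with the
exact boolean mask stored per frame.

**Confluency images** place randomly oriented ellipses until the union
reaches the target coverage within half a percentage point, then render
them as darker, textured regions on a smoothly shaded light background with
white sensor noise. Semi-axes default to 15–35 px: the camera format
(1496 × 1495 px) frames a single ~1.6 mm well, about 1.1 µm/px, so spread
stromal cells of 40–100 µm map to exactly that range. Cell speckle is
spatially correlated (Gaussian-blurred at σ = 1.2 px) because intracellular
granularity is structured while sensor noise is white — the cue the
classifier depends on after normalization.

What passing these simulation-based tests shows — and what it does not:
they demonstrate that the quantification chain is unbiased and powered on
images whose ground truth is known and whose artifacts (shading, sensor
noise, boundary ambiguity) are modeled. They cannot certify performance on
real brightfield micrographs, whose cell morphology, debris, and focus
drift the generators do not emulate; on real data the classifier should be
retrained on labeled frames from the same acquisition.

## Problem sizes and determinism

Validation uses full-format confluency fixtures (1496 × 1495 px), 10 µm
finite-difference grids for the kernel-agreement checks, 20 seeded
two-arm migration experiments (5 wells per arm, 60 agents per well, 3
simulated days) for detection power, and 100 null experiments for type-I
calibration. Every stochastic step — agent walks, noise, pixel sampling,
Monte-Carlo permutations — flows from one explicit seed; consecutive
experiment seeds are internally strided so replicate wells of nearby seeds
share no random draws. All fits and thresholds are deterministic given
their inputs.

## Known limitations

* The point-source model ignores well geometry; fitted coefficients from
  early times or rim-adjacent distances inherit that approximation
  (relevant whenever $\sqrt{4 D t}$ is small against the well radius).
* Log-log interpolation of moduli assumes local power-law behavior between
  grid frequencies.
* The pixel classifier is linear in its feature bank; real tissue imagery
  usually needs the retraining noted above, or a richer classifier behind
  the same probability-map contract.
* Agent motility parameters are field-typical, not calibrated to any
  specific cell line; conclusions from the simulator are about the
  quantification pipeline, not about cells.
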