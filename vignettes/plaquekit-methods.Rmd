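---
title: "Methods: intracoronary OCT morphometry, artifact correction, and agreement statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: intracoronary OCT morphometry, artifact correction, and agreement statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plaquekit)
```

# What the package computes

Intravascular optical coherence tomography (OCT) images a coronary artery as
a stack of axial cross-sections ("a pullback"). The clinically decisive
quantities in each frame are geometric: the lumen area, the angles subtended
by lipid pools and calcium deposits about the lumen center (lipid/calcium
arc), and the radial distance from the lumen boundary to the underlying
lipid pool (fibrous-cap thickness, FCT). Combinations of these define plaque
phenotypes — most importantly the thin-cap fibroatheroma (TCFA, FCT
minimum below 75 µm), the canonical high-risk lesion — and high-risk flags
(minimum lumen area < 3.5 mm², maximal lipid arc > 180°, FCT < 75 µm).

`plaquekit` implements this measurement pipeline on per-frame segmentation
label masks, a histogram-matching correction of artifact-darkened sectors, a
rule-based two-step plaque classifier, the agreement/noninferiority
statistics battery used to validate automated readers against experts, a
synthetic phantom generator with analytic ground truth, and a desk-scale
segmentation training harness. No clinical data ships with the package:
every empirical statement in its test suite is computed on phantoms at test
time.

# Geometric conventions

One convention is used everywhere: pixel coordinates are 0-based with x =
column and y = row, origin at the top-left pixel center; angles are in
degrees, counterclockwise from the +x axis with +y pointing down the image;
in-plane pixel spacing is isotropic (anisotropic calibration is rejected,
not resampled). The default measurement grid uses 360 angular bins of 1°;
printed arcs in this field are reported at ~1° precision, so 1° bins keep
quantization error below reader variability.

# Morphometry on label masks

Masks code each pixel as one of: background, lumen, wall/fibrous tissue,
lipid, calcium, fibrous cap, guidewire shadow, bifurcation, guide catheter,
stent (codes 0–9, frozen in `oct_classes()`).

* **Lumen area** is the pixel count of the lumen class times the pixel area.
* **Arcs** are measured on 1° wedges about the lumen centroid: an angle
  "sees" a tissue iff at least one pixel of that class falls in its wedge.
  The total arc is the count of such angles; the maximal arc is the longest
  circular run (wrap-around joined). The headline "lipid arc" for risk
  flags is the maximal contiguous arc; the total is also reported for
  mean-change analyses, since both framings are in clinical use.
* **FCT** at an angle with lipid present is the radial distance from the
  outermost lumen pixel to the innermost lipid pixel in the wedge, in µm.
  Angles crossing guidewire shadow are excluded (no tissue signal exists
  there). FCT is *undefined* — never zero — where no cap-over-lipid exists.
  This lumen-to-lipid definition is robust to mask sources that lack an
  explicit cap class; when a cap class is present it is used as a
  consistency check (a > 2 px median disagreement warns).

Because pixel centers strictly inside the lumen are below the true boundary
radius and lipid pixel centers are beyond the pool's inner boundary, the
per-angle FCT estimate is one-sided: never below the true thickness and
above it by at most about one pixel. Taking the minimum over ~100 angles
lands within half a pixel of truth on phantoms.

**Thresholds are strict comparisons exactly as printed** (`< 3.5 mm²`,
`> 180°`, `< 75 µm`), with no epsilon. An undefined FCT yields a FALSE
thin-cap flag: thinness is not asserted without a measurement.

**Lesions** are maximal runs of plaque-bearing frames, bridging plaque-free
gaps of at most 2 frames (configurable; the clinical lesion definition is
not standardized). Lesion FCT is summarized both as the minimum over frames
and as the mean of per-frame minima. Frames flagged in-guide-catheter or
in-stent are carried through but never measured; gating comes from metadata
flags or from catheter/stent mask classes, with single-frame gaps inside
gated runs filled.

# Artifact correction

Gas bubbles and signal dropout multiply tissue intensity by a factor well
below one over an angular sector, which makes dark wall mimic lipid.
Correction works in lumen-centered polar coordinates:

1. **Detection.** Every angle is summarized by its surface peak — the
   maximum intensity in a 12 px band beyond the lumen boundary. In OCT the
   luminal tissue interface is strongly reflective regardless of the tissue
   behind it (lipid hides behind a bright cap, calcium behind bright
   tissue), so a darkened surface peak indicates an artifact rather than
   tissue. Sectors of 5° are scored by the 80th percentile of their angles'
   peaks (tolerant of one boundary angle); a sector is flagged when its
   score falls 3 MADs below the sector median, or when its band intensities
   are stochastically darker than the pooled clean sectors (one-sided
   Kolmogorov–Smirnov distance > 0.3) *and* its surface peak is below half
   the median (the guard keeps legitimately dark tissue from ever being
   "corrected"). Guidewire-shadow sectors are pre-excluded. A frame whose
   median surface peak is below 60 of 255 is declined as fully corrupted —
   there is no reference left to match against — and passed through with a
   warning.
2. **Histogram matching.** Each flagged region's intensities are remapped by
   monotone quantile mapping onto a reference distribution. The reference is
   the profile-matched half of the clean sectors: clean sectors whose
   shape-normalized radial profile is closest to the region's. A
   multiplicative artifact leaves the normalized profile invariant, so this
   selects reference tissue of the same composition. (Matching against *all*
   clean sectors — the simpler choice — measurably injects lipid-dark values
   into recovered wall when the frame carries a large lipid pool, inflating
   the downstream lipid arc by tens of degrees; profile matching removes
   this failure mode.)
3. **Retransform.** The corrected polar band is resampled back to Cartesian
   and blended over a 2° angular feather; pixels outside flagged regions and
   the feather are bit-identical to the input. Correction applies to
   intensities only; label masks are re-segmented afterwards, never
   histogram-matched. The operation is idempotent to within one intensity
   level.

What this cannot do: tangential signal dropout destroys the surface
reflection itself and is indistinguishable from a genuinely thin cap by any
per-frame intensity rule; such frames are the acknowledged failure mode of
intensity-based correction.

# Two-step plaque classification

Step 1 separates low-risk (normal, adaptive and pathological intimal
thickening) from higher-risk (fibrocalcific, thick- and thin-cap
fibroatheroma) segments; step 2 refines higher-risk classes from plaque
component measurements. The default classifier is a measurement cascade
(first match wins):

1. maximal lipid arc ≥ 90° and FCT defined → **TCFA** if FCT_min < 75 µm
   (strict), else **ThCFA**;
2. maximal calcium arc ≥ 90° → **fibrocalcific**;
3. any lipid → **PIT**;
4. intimal thickness ≥ 300 µm → **AIT** if ≤ 600 µm else **PIT**;
5. otherwise **NORMAL**.

Only the 75 µm thin-cap threshold is a fixed clinical constant; the
remaining thresholds are consensus-style stand-ins exposed in
`classification_params()`. Fibroatheroma deliberately takes precedence over
fibrocalcific when both criteria are met, because the FCT-bearing phenotypes
drive the risk outputs. Lesion class is the worst member frame under the
severity order TCFA > ThCFA > fibrocalcific > PIT > AIT > NORMAL.
Unanalyzable frames receive no class — never a silent NORMAL.

# Agreement statistics

* **ICC** is fixed to the two-way random-effects, absolute-agreement,
  single-measurement form ICC(A,1) — the standard reading of "ICC for
  absolute agreement" with two raters on the same frames. It is computed
  from the ANOVA mean squares; the confidence interval is the
  McGraw–Wong F-based construction (cross-checked to 10 decimal places
  against an independent implementation), and the p value is the
  F test of ICC = 0.
* **Bland–Altman** uses d = x − y, limits of agreement mean(d) ± 1.96·sd(d)
  with the sample (n−1) standard deviation. "Within limits" counts strictly
  inside differences; reported percentages use print-style half-up rounding
  to one decimal (e.g. 1140 of 1218 → 93.6).
* **Noninferiority** is the Wald-type asymptotic test of
  H0: p1 ≤ p0 − margin with margin 0.1 at one-sided α = 0.025:
  z = (p̂1 − p̂0 + margin − cc) / SE with the Wald standard error and the
  sample-size continuity correction cc = (1/n1 + 1/n0)/2. Several
  continuity-correction conventions exist for two-proportion Wald tests;
  the implemented form is stated here precisely so it can be swapped.
  With cc the test is conservative: at the H0 boundary its simulated
  rejection rate stays below nominal. Degenerate proportions (SE = 0) map
  to z ∈ {−∞, 0, +∞} by the sign of the numerator.
* **Paired t, Wilcoxon signed-rank** (zero-exclusion convention) **and
  χ²** (no continuity correction) delegate to base R. No multiple-testing
  adjustment is applied anywhere: the battery reports exploratory p values.

# The phantom generator

`phantom_spec()` states a simple but OCT-like world: a dark lumen (circular,
elliptic, or perturbed by low-order sinusoids), a bright speckled wall
annulus, lipid pools as low-signal diffuse-border regions behind a brighter
cap band, calcium as low-signal sharp-border regions, guidewire-shadow
wedges (near-zero signal behind a bright point reflector), and smoothed
multiplicative gamma speckle. All randomness flows from a single seed; the
global RNG state is untouched. Defaults: 512×512 frames at 10 µm/px (µm
thresholds land on integer pixel counts), lumen radius 120 px (≈4.5 mm²
lumen), wall 80 px, one 120° lipid plaque with a 6 px (60 µm, TCFA-range)
cap, speckle variance 0.05 with 4 px grain.

Ground truth is analytic: lumen area in closed form (πr², πab, or
πR₀²(1+Σaₖ²/2) for the perturbed boundary), arcs as exact circular-interval
arithmetic (shadow wedges subtracted, because shadowed tissue is invisible
to any angular measurement), FCT as the stated cap thickness.

What the phantom does **not** emulate: depth-dependent attenuation and
focus, catheter optics and non-uniform rotation, tangential dropout,
thrombus, layered or healed plaque, macrophages, real speckle statistics.
A green phantom test therefore establishes the *geometric* correctness of
the measurement code and the *behavioral* contracts of correction and
training — not clinical performance on patient images.

`phantom_corrupt()` applies bubble/dropout attenuation or shadow zeroing as
a separate post-processing step and returns the injected regions, so
detector accuracy can be scored against ground truth.

# Desk-scale segmentation training

No deep-learning framework is available in this environment, so the
trainable segmenter is a compact multinomial MLP (two hidden layers, 48/24
units) over per-pixel features of the lumen-centered polar image: an
11-sample radial profile window, five radial derivatives (border sharpness
separates sharp calcium from diffuse lipid), smoothed center intensities,
angular context, normalized radius, the cumulative mean from the center
outward, local radial standard deviation, and the raw intensity. Intensities
are standardized by the frame's bright-tissue level (95th percentile) for
gain invariance. The harness — the part with a measurable contract — is
faithful: patient-level 14:1:1 split with no leakage; hybrid loss = mean
per-class (1 − soft Dice) + pixelwise cross-entropy with equal weights (the
weighting is exposed, none is published); Adam with step-decay learning
rate (0.01, halved every 8 epochs); a class-balancing frame sampler
(inverse frequency of the rarest class a frame contains); polar
augmentations — circular roll and flips applied jointly to image and mask,
intensity jitter (gain 0.95–1.05, bias ±4 on the 8-bit scale) to the image
only.

The phantom training cohort guarantees class coverage: every patient
carries a lipid plaque and about half carry calcium (typical cohort
prevalence). With rarer calcium the patient-level split of a 12-patient
cohort can strand all calcium in the held-out partitions, which is a
degenerate training set, not a hard case. Pixels are sampled stratified by
class (120 per present class per step, 40 steps per epoch), so each Adam
step sees a balanced batch.

On 12 phantom patients and 20 epochs (≈10 s on one CPU) the held-out Dice
is ≈0.999 (lumen), ≈0.98 (wall), ≈0.96 (lipid), ≈0.99 (calcium); a
label-shuffled negative control collapses the plaque classes toward chance.
These numbers validate the training loop, loss, sampler and split — they say
nothing about performance on clinical images, which requires a real backbone
and real data.

# Numerical choices and degenerate inputs

* Bilinear interpolation for intensities, nearest-neighbour for labels
  (labels must never blend); bilinear convexity bounds every interpolated
  value by the input range.
* The polar radial extent defaults to the distance from the lumen center to
  the farthest frame corner, so no tissue is clipped.
* A mask without lumen pixels is an unanalyzable frame and errors
  explicitly; a plaque-free pullback yields an empty lesion list; absent
  tissue yields 0° arcs and undefined (NA) FCT; zero-variance inputs make
  ICC/t/Wilcoxon undefined (NA), never 0.
* Ties in the quantile mapping are broken by average ranks, which keeps the
  mapping monotone and the identity mapping exact to within one intensity
  level on 8-bit data.
* Reports serialize numbers at full precision (JSON) and embed the run
  configuration verbatim; reruns with the same configuration are
  byte-identical.

# Known limitations

The rule-based intensity segmenter (`segment_frame_rules()`) is a phantom
stand-in for a trained network, used to exercise the pipeline end to end;
it has no claim on clinical images. The DICOM support is a minimal
explicit-VR little-endian grayscale subset sufficient for round-tripping the
package's own exports. Stent and catheter structures are gated, not
measured. The classifier's AIT/PIT intimal-thickness branch requires an
intimal thickness supplied by the caller; mask-derived intima measurement is
not implemented.
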