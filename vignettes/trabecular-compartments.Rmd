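---
title: "Standardized trabecular compartment analysis in the mouse proximal tibia"
author: "tibiamorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standardized trabecular compartment analysis in the mouse proximal tibia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tibiamorph)
```

## The problem

Morphometric analysis of trabecular bone in the murine proximal tibia
depends on *where* the volume of interest (VOI) is placed. The
epiphyseal-metaphyseal region comprises four compartments progressing from
proximal to distal: epiphyseal bone, growth-plate cartilage, fine newly
formed primary spongiosa, and mature secondary spongiosa. Studies
conventionally place the metaphyseal VOI at a fixed offset (commonly
0.125-0.25 mm in mice) distal to the growth plate. But the length of the
primary spongiosa responds strongly to anabolic treatment, so a fixed
offset samples *different* compartments in different treatment groups — a
confound that can masquerade as, or mask, a biological effect.

tibiamorph addresses this by locating the three transitional interfaces
along the tibial long axis (z = 0 at the proximal end, z increasing
distally):

* `Z_eg` — epiphyseal bone / growth plate,
* `Z_gp` — growth plate / primary spongiosa,
* `Z_ps` — primary / secondary spongiosa,

and anchoring every VOI on these landmarks: the epiphyseal VOI extends
0.25 mm proximally from `Z_eg`, the mixed primary-secondary VOI 1 mm
distally from `Z_gp`, and the secondary-spongiosa VOI 1 mm distally from
`Z_ps`. All intervals are half-open, `[ref + offset, ref + offset +
height)`, so adjacent VOIs sharing a reference never share a slice, and
slice counts are `round(height / voxel)` (1 mm at 5 µm is exactly 200
slices).

## The landmark model: regional probability distributions

A classifier assigns each transverse slice a probability vector over the
four compartments (softmax of its logits). Stacked along z, these form a
probability profile `P(z, C)` with `C = 0..3` ordered
proximal-to-distal. Because the anatomy is ordered, each interface is the
z position where the probabilities of the two adjacent compartments are
equal:

* `Z_eg = min z` with `P(z, 0) = P(z, 1)`, scanned proximal to distal;
* `Z_ps` is found scanning distal to proximal for `P(z, 2) = P(z, 3)`;
* `Z_gp` is the crossing of `P(z, 1) = P(z, 2)` inside the interval
  bounded by `Z_eg` and `Z_ps`.

Numerical choices, all deliberate:

* **Smoothing.** Raw profiles are smoothed with a centered rolling median
  (window 0.05 mm, converted to an odd number of slices, shrinking
  symmetrically at the edges). The median suppresses single-slice label
  noise without displacing the crossing. Rows are re-normalized after
  filtering — column-wise medians need not sum to one; the correction is
  negligible but keeps the profile a distribution.
* **Sub-slice interpolation.** Profiles are discrete in z; the crossing is
  located at the first sign change of the probability difference in the
  scan direction, with the sub-slice position linearly interpolated from
  the two bracketing differences (an exact zero at a slice yields that
  slice's position). This removes a half-voxel bias.
* **First crossing in scan direction, with a dominance margin.** Residual
  noise can produce multiple equalities; the first crossing in the stated
  scan direction matches the min-z definition of each landmark and is
  deterministic. A sign change only qualifies if the probability
  difference reaches magnitude 0.2 within twice the smoothing window on
  the far side — at a genuine interface the entered compartment comes to
  dominate, whereas an equality wobble from a few misclassified slices
  (both probabilities hovering near 0.45) never does. If no crossing
  qualifies, the bare first crossing is used; `crossing_margin = 0`
  restores the unqualified rule.
* **Absent compartments.** A compartment whose smoothed probability never
  reaches 0.5 anywhere (i.e. is never the majority class) is declared
  absent. In aged animals the primary spongiosa may vanish; then `Z_gp`
  and `Z_ps` do not exist and the growth-plate/secondary interface `Z_gs`
  (crossing of `P(z,1) = P(z,3)`) is reported instead. More than two
  absent compartments aborts with a diagnostic.

## The slice classifier

The classification recipe is cross-entropy loss optimized by mini-batch
stochastic gradient descent (learning rate 1e-3, batch size 64), with
majority voting to aggregate multiple annotators (ties broken toward the
lower class code, i.e. the more proximal compartment, with a warning) and
bone-level 5-fold cross-validation — folds split over bones, never slices,
so slices of one animal cannot leak across the train/validation boundary.

The built-in backbone, `feature_baseline`, is a multinomial logistic
(softmax) model over 13 per-slice descriptors: bone-area fraction,
medullary bone-area fraction (after removing the cortical shell),
connected-component count, a mean 2D object-thickness proxy, a
low-attenuation band score that captures non-calcified cartilage, and an
8-bin radial mean-intensity profile. It is fully deterministic for a fixed
seed, trains in seconds, and suffices for landmark recovery on phantoms;
the `backbone` field of `train_config()` is the hook for heavier
convolutional models, which are outside this package's scope.

Slices are prepared by the standard chain: Otsu threshold over the whole
volume (256-bin histogram, strict `>` comparison, ties toward the lower
threshold), retention of the largest 26-connected component, cropping to
the volume-level 3D bounding box of that mask, per-volume min-max
normalization to [0, 1], and bilinear resizing to 384 × 384.
Normalization is per-volume rather than per-slice: per-slice scaling would
destroy the cartilage/bone contrast along z that separates the growth
plate from the bony compartments.

## Morphometry

`local_thickness()` implements the inscribed-sphere definition: the
thickness at a point of a phase is the diameter of the largest sphere
entirely inside that phase containing the point. The implementation is the
standard fast scheme — exact Euclidean distance transform, distance-ridge
reduction (spheres contained in a neighbour's sphere are pruned), then
sphere painting with the largest radius winning. Two conventions matter:

* spheres are *open* — a voxel at exactly distance r from a centre is not
  inside, since the nearest background voxel sits at that distance;
* the volume border is background — spheres may not extend outside the
  grid, so values within half a structure-thickness of the border are
  biased low. The 20 µm depth binning reports edge bins like any other;
  the 3D summaries simply average over the VOI.

From the trabecular and medullary masks, `morphometry_3d()` reports
BV/TV = 100·|trabecular|/|medullary| (%), Tb.Th (µm) as the mean local
thickness of the trabecular phase, and Tb.Sp (µm) as the mean local
thickness of the background phase *restricted to the medulla* — the
cortical shell and the exterior never count as separation. (The bounding
region for Tb.Sp is a genuine convention choice; the medullary restriction
matches standard practice and the magnitudes reported for mouse tibiae.)

`morphometry_profile()` bins the VOI along z into half-open 20 µm bins and
reports per-bin B.Ar/T.Ar plus Tb.Th/Tb.Sp as means of the *3D* thickness
maps (computed once on the whole VOI) restricted to each bin. Two exact
identities follow and are asserted in the test suite: per-bin trabecular
counts sum to the 3D count, and the medullary-volume-weighted mean of
per-bin B.Ar/T.Ar equals the 3D BV/TV.

## Alignment

`align_tibia()` standardizes orientation before VOI extraction: the first
principal component of the bone-mask voxel coordinates is mapped to +z;
the sign is chosen so the end with the larger cross-sectional area (the
epiphysis) is proximal, comparing voxel counts in equal-length windows at
either end (overridable with `flip_proximal`). The in-plane rotation is
fixed by the tibial ridge within the proximal 65-75% segment of the bone
length. The per-slice ridge direction is the furthest mask point from the
slice centre; to make this robust on noisy masks we use the centre of the
*filled silhouette* (the bone-mask centroid is dragged toward the ridge's
own mass) and the angular centroid of all points within 2 voxels of the
maximal radius rather than the single furthest voxel. The mean ridge
direction is rotated onto +x and the volume resampled once (trilinear;
masks nearest-neighbour). Near-isotropic masks (eigenvalue ratio < 1.2)
are rejected: the principal axis is undefined.

## The synthetic phantom

Real annotated scans are not distributable, so validation runs on a
synthetic tibia: a tapered cortical tube (15% distal taper gives the
proximal-end rule something to detect; a 0.12 mm longitudinal ridge breaks
rotational symmetry) whose medulla is divided into the four compartments,
with sinusoidally undulating interfaces, a cartilage band at
growth-plate level with attenuation between marrow and bone (so global
thresholding assigns it to background, as for non-calcified tissue),
Gaussian point-spread blur, and additive noise.

Trabecular microarchitecture is an excursion set of a smoothed Gaussian
random field. Thresholding a standardized field at the (1 − BV/TV) normal
quantile fixes the volume fraction; the kernel width is chosen from the
Rice crossing-rate formula — the mean foreground chord along a line is
`2·sqrt(2)·pi·sigma·p·exp(t²/2)` — with an empirical chord-to-thickness
factor (1.05 − 0.64·BV/TV, measured once on reference fields) converting
the chord scale to inscribed-sphere thickness. The generator is calibrated
to within 0.03 of the target BV/TV and two voxels of the target Tb.Th,
which the test suite verifies with the package's own morphometry.

Default tissue targets follow untreated adult C57BL/6 values: epiphysis
BV/TV 0.33 / Tb.Th 70 µm, primary spongiosa 0.40 / 35 µm, secondary
spongiosa 0.12 / 50 µm; compartment heights 0.5 / 0.1 / 0.3 / 1.2 mm. The
default voxel size is 5 µm; validation cohorts use the 10 µm `"coarse"`
preset and unit-scale checks a 20 µm `"test"` preset (whose texture
targets are coarsened to stay above two voxels).

Ground-truth labels are *region-occupancy* labels: every medullary voxel
in a compartment's z-range carries that compartment's code, and the
microarchitecture lives in a separate trabecular mask. The true landmarks
are then derived from the labels by the annotator slice rules: `Z_ps` is
the distal face of the distal-most slice in which primary spongiosa
traverses the medulla in an uninterrupted anterior-posterior stripe
(operationalized as one 8-connected component touching both the
anterior-most and posterior-most medullary rows), `Z_gp` likewise for the
cartilage band, and `Z_eg` is the proximal face of the proximal-most slice
showing any cartilage. With flat interfaces these rules give exactly the
cumulative compartment heights.

What the phantom does **not** emulate: beam hardening, ring artifacts and
polychromatic physics; anisotropic plate/rod architecture (the random
field is isotropic); cortical porosity; the gradual calcification gradient
at the chondro-osseous junction. Passing the phantom suite therefore
demonstrates the correctness of the pipeline's geometry, detection rules
and statistics under controlled conditions — not classifier performance on
real scans, which requires real annotated data.

## Statistics

* **Equivalence (TOST).** Landmark agreement is tested with paired two
  one-sided t-tests at a ±0.05 mm bound: `p_tost = max(p_lower, p_upper)`,
  equivalence when `p_tost <= 0.05`. Pairing is per bone (both sources
  annotate the same scans). In `model_vs_raters_equivalence()` all
  pairwise source comparisons within one landmark form the Bonferroni
  family, and the model passes when equivalent to at least two raters.
  Zero-variance differences inside the bound report p = 0 with a
  degeneracy flag rather than failing.
* **ICC.** `icc()` is the two-way random-effects, absolute-agreement,
  single-measure ICC(2,1) from the mean-squares decomposition — the
  standard choice when raters are interchangeable. Intra-operator ICC is
  the same function applied to a subjects × repeats matrix.
* **Group comparisons.** One-way ANOVA with Tukey HSD post hoc for 3D
  summaries, and per-20 µm-bin ANOVA with Games-Howell post hoc (Welch
  statistics, Welch-Satterthwaite df, studentized range with sqrt(2)
  scaling) for depth profiles. Post hoc tests are emitted *only* when the
  omnibus test is significant at 5%. Shapiro-Wilk (per group) and
  classical Levene (centered on means) are reported as diagnostics and
  never gate execution. For two groups with equal sample variances and
  sizes, Games-Howell coincides with Tukey — a coincidence the test suite
  checks to 1e-6.
* **Significance colors.** Depth-resolved p-values map to four bands:
  blue (p > 0.05), light blue (0.01 < p ≤ 0.05), orange
  (0.001 < p ≤ 0.01), red (p ≤ 0.001); boundaries are inclusive on the
  upper edge of each band, so p = 0.01 is orange.

## Validation studies and problem sizes

`landmark_validation_study()` is the end-to-end check: 20 training and 10
held-out phantoms at 10 µm in a 1.2 mm lateral field (a tight
proximal-tibia crop keeps the runs minutes-scale; the phantom default
remains 1.5 mm), heights and texture targets jittered per bone. The
feature-baseline classifier is trained on the training cohort, profiles
are predicted, smoothed and crossed on the held-out bones, and detections
are compared with phantom truth: the suite requires all three landmarks
within ±0.05 mm on at least 90% of bones and paired TOST equivalence at
the 0.05 mm bound for each landmark.

`fixed_offset_comparison_study()` reproduces the reference-level artifact:
two phantom groups identical except for primary-spongiosa height (0.1 vs
0.4 mm — a surrogate for an anabolic response that displaces `Z_ps`
distally). In the VOI at a fixed 0.125 mm offset distal to `Z_gp`, the
lengthened primary spongiosa of the second group leaks in and inflates the
bone area fraction by several percentage points; the `Z_ps`-anchored VOI
samples structurally equivalent secondary spongiosa in both groups and
shows gaps below two percentage points. The assertion is on effect sizes,
not p-values: with such clean phantoms a t-test on the fixed-offset VOI is
astronomically significant, while tiny systematic differences could
produce spurious significance in the anchored VOI despite being
biologically meaningless.

Other suite scales, chosen to keep the default run minutes-scale while
leaving no operation untested: local-thickness oracle equivalence on a
random 40³ mask (the oracle brute-forces nearest-background distances and
paints every sphere), ANOVA type-I calibration with 1000 null replicates
(4 groups × 5), TOST boundary behaviour with 2000 replicates.

## Known limitations

* The substitute trabecular/medullary segmentation (per-slice Otsu +
  cortical-shell removal) is a geometric rule, not a learned model; on
  blurred, noisy data it under-segments thin trabeculae. Supply external
  masks from a dedicated segmentation model when available — the pipeline
  prefers them.
* The feature-baseline classifier is designed for the phantom's contrast
  regime; real scans with cartilage bridges, fused physes or strong
  metaphyseal flare will need a stronger backbone behind the same
  interface.
* Landmark semantics assume the four compartments appear in anatomical
  order along +z; volumes must be aligned (or generated aligned) before
  profile prediction.
* Tb.Sp at the VOI faces is biased low by the border-as-background rule;
  compare like with like (same VOI heights) across groups.
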