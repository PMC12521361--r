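# tibiamorph

Standardized trabecular compartment analysis for micro-CT scans of the
mouse proximal tibia.

## What it does

The epiphyseal-metaphyseal region of the murine tibia divides, proximal to
distal, into four compartments: epiphyseal bone, growth-plate cartilage,
primary spongiosa and secondary spongiosa. Where a morphometric volume of
interest (VOI) is placed among these compartments changes the numbers that
come out of it, and the conventional practice — a fixed offset distal to
the growth plate — samples *different* compartments in different treatment
groups whenever the primary spongiosa lengthens or shrinks.

tibiamorph implements a slice-wise analysis that removes this confound:

1. **Classify** each transverse slice into one of the four compartments
   (a deterministic multinomial-logistic baseline over 13 slice
   descriptors is built in; the interface accepts heavier backbones).
2. **Detect landmarks** from the per-slice class-probability profile
   `P(z, C)`: each transitional interface is the z where the probabilities
   of the adjacent compartments cross,

   * `Z_eg = min z : P(z,0) = P(z,1)` (epiphysis / growth plate),
   * `Z_gp = min z : P(z,1) = P(z,2)` (growth plate / primary),
   * `Z_ps = min z : P(z,2) = P(z,3)` (primary / secondary),

   after rolling-median smoothing (window 0.05 mm), with sub-slice linear
   interpolation of the crossing and directional scanning (`Z_eg`
   proximal→distal, `Z_ps` distal→proximal, `Z_gp` between them).
3. **Extract standardized VOIs** anchored on the landmarks (secondary
   spongiosa: `[Z_ps, Z_ps + 1 mm)`; mixed primary-secondary:
   `[Z_gp, Z_gp + 1 mm)`; epiphyseal: `[Z_eg − 0.25 mm, Z_eg)`), after
   PCA-based rigid alignment of the tibia to the global axes.
4. **Measure morphometry**: BV/TV (%), Tb.Th and Tb.Sp (µm) via a fast 3D
   local-thickness algorithm (inscribed-sphere definition), both for the
   whole VOI and depth-resolved in 20 µm bins.
5. **Compare statistically**: paired TOST equivalence of landmarks
   (±0.05 mm bound, Bonferroni-corrected), ICC(2,1) rater agreement,
   one-way ANOVA + Tukey HSD for 3D summaries, per-bin ANOVA +
   Games-Howell with a four-band significance color code for profiles.

A synthetic tibia-phantom generator with voxel-level ground truth
(compartment labels, trabecular masks, true landmark positions,
controllable BV/TV, trabecular thickness, interface tortuosity, noise and
misalignment) makes the whole pipeline testable without animal data.

## Worked example

```r
library(tibiamorph)

# a coarse (10 um) phantom with known ground truth
spec <- phantom_preset("coarse", seed = 31)
ph   <- generate_phantom(spec)
ph$truth$true_landmarks
#> <landmark_set>
#>   Z_eg: 0.4900 mm
#>   Z_gp: 0.6000 mm
#>   Z_ps: 0.9000 mm

# secondary-spongiosa VOI anchored on Z_ps, using the truth masks
voi <- extract_voi(ph$volume, ph$truth$true_landmarks, voi_spec("secondary"),
                   masks = list(trab = ph$truth$trabecular_mask,
                                med  = ph$truth$medullary_mask))
morphometry_3d(voi$masks$trab, voi$masks$med, spec$voxel_size_mm)
#> <morphometry_result> BV/TV 13.06%  Tb.Th 49.2 um  Tb.Sp 125.5 um
```

The phantom was generated with target BV/TV 0.12 and Tb.Th 50 µm in the
secondary spongiosa; the recovered 13.1% / 49.2 µm are within the
generator's calibration tolerance, and the landmarks sit at the cumulative
compartment heights (the 0.49 mm `Z_eg` reflects the ±0.02 mm interface
undulation).

The end-to-end validation — train the slice classifier on 20 phantoms,
detect landmarks on 10 held-out phantoms, compare against truth:

```r
study <- landmark_validation_study(n_train = 20, n_test = 10,
                                   voxel_size_mm = 0.010, seed = 101)
study$hit_rate          # fraction of bones with all landmarks within 0.05 mm
#> [1] 1
study$tost$Z_ps$p_tost  # paired TOST vs truth at the 0.05 mm bound
#> [1] 1.32e-07
```

## Command line

A thin CLI over the same functions is installed at `exec/tibiamorph`:

```sh
tibiamorph phantom --out phantom_dir --preset coarse --seed 1
tibiamorph landmarks --profile profile.csv --voxel 0.005 --out lm.json
tibiamorph run --config config.yaml
```

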