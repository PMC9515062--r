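---
title: "Automatic fiducial marker localization: model, assumptions and design choices"
author: "fidloc authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic fiducial marker localization: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fidloc)
```

## The problem

A reattachable fiducial skin marker carries eight spherical features
distributed over two parallel planes, four per plane, arranged so that every
feature has a unique pattern of distances to the others. Because the marker
can be clipped on and off a skin-mounted plate in a reproducible pose, a CT
or MRI scan acquired days before an intervention can be registered to
intra-interventional tracking or ultrasound data: all that is needed at
intervention time is the rigid transform from the marker's canonical frame
to the image, estimated automatically from the image alone.

`fidloc` implements that estimator as a classic fitting function,
`localize_marker(volume, geometry)`, together with the assessment statistics
used to characterize such markers (point prediction error, clipping
precision, target registration error), file I/O for the common volume
formats, and a fully ground-truthed synthetic phantom generator so that
every stage of the pipeline is testable without any scanner data.

## The localization model

Localization is a three-part procedure; each part is exposed as its own
function so it can be tested and replaced independently.

**1. Candidate detection** (`detect_candidates()`). The volume is reduced to
a handful of bright-blob candidates:

* *Background suppression.* Voxels below an adaptive threshold — the 99.5th
  intensity percentile, raised to a 300 HU floor when the intensity range
  looks HU-like (contains values below −200) — are set to the volume
  minimum. A percentile cutoff is robust to field-of-view changes because
  the marker occupies far less than 0.5 % of any realistic scan. If the
  subsequent labeling still finds more components than `max_candidates`
  (default 500), the pipeline tightens the percentile (quartering the
  admitted tail) and retries up to three times; every effective threshold is
  reported in the fit object.
* *Edge response.* The gradient magnitude of the Gaussian-smoothed volume,
  with derivative scale σ = d/6 mm for feature diameter d, computed with
  per-axis voxel conversion so anisotropic grids are handled correctly.
  Spherical features produce a strong shell of gradient at radius ≈ d/2.
* *Binarization and labeling.* The foreground is the set of suppression
  survivors lying inside the hole-filled strong-edge shell, where "strong"
  is an automatic two-class (Otsu) threshold on the nonzero edge responses.
  Intensity alone would admit isolated bright noise voxels; edges alone give
  hollow shells; the intersection gives solid, compact components.
  Components are labeled with 26-connectivity, components touching the
  volume boundary are discarded (a feature must be completely captured to be
  usable), and each component is then *refined to its partial-volume-
  corrected size*: the raw thresholded component carries a halo of partial
  voxels that inflates its voxel count, while the occupancy integral
  Σ(v − bg)/peak estimates the true number of occupied voxels independently
  of slice thickness, because the intensity integral of a blurred sphere is
  conserved. The brightest voxels up to that count form the refined
  component, so the voxel-count volume entering the pruning rule is
  comparable with the true feature volume on any grid. Centroids are
  intensity-weighted world coordinates, which is what buys sub-voxel
  accuracy at 3–5 mm slices.
* *Volume pruning.* Candidates smaller than 0.6 × the true feature volume
  (π d³/6) are discarded for both modalities; candidates larger than 2 × the
  true volume are discarded for MRI only — CT metal features may bloom
  arbitrarily bright, MRI spots may not.

**2. Correspondence** (`match_candidates_to_geometry()`). The marker's 28
pairwise distances are unique by construction (validated, not assumed, at
tolerance τ), so correspondence reduces to distance-pattern matching:

* *Iterative exclusion*: each candidate is scored by how many of its
  distances to other candidates match any canonical distance within τ;
  while more than eight candidates remain, the lowest-scoring one is
  dropped and the rest rescored. Ties break deterministically (largest
  deviation from the expected feature volume, then lowest mean intensity,
  then lowest label id), which makes matching invariant to candidate input
  order.
* *Ordering*: the eight survivors are assigned to canonical feature indices
  by the one-to-one assignment minimizing the total L1 discrepancy between
  the sorted candidate and canonical distance signatures (an 8 × 8
  assignment solved exactly by branch and bound).
* *Verification*: a Horn fit must reach a fiducial registration error (FRE)
  at most `fre_threshold`; otherwise all 8-subsets of the best ≤ 16
  candidates are searched (12 870 subsets, pre-filtered by a cheap
  sorted-distance comparison), and the consistent subset with minimal FRE
  wins. If nothing passes, the fit reports `no_consistent_subset` or
  `high_residual` — never a silently wrong pose.

**3. Pose estimation** (`horn_absolute_orientation()`). The closed-form
unit-quaternion solution of the absolute-orientation problem: the optimal
rotation is the principal eigenvector of the 4 × 4 matrix assembled from the
cross-covariance of the centered point sets; the translation follows from
the centroids. No scale, no reflection. The FRE is the RMS residual over
the eight features. The test suite checks this solver against an
independent numerical least-squares oracle (multi-start BFGS with a
Gauss-Newton polish) on hundreds of random problems.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `percentile` | 0.995 | — | marker ≪ 0.5 % of volume; self-raised on overflow |
| `tau` | max(1, 0.75 · max spacing) | mm | centroid error scales with slice thickness |
| `fre_threshold` | max(1, voxel diagonal) | mm | accept residuals at the sampling scale |
| `max_candidates` | 500 | — | guards the labeling stage against noise floods |
| `max_exhaustive` | 16 | — | 12 870 subsets keep the fallback below a second |
| geometry `tol` (τ for validation) | 1.0 | mm | ≈ one in-plane voxel; matching tolerance must exceed centroid error |

The Euler-angle convention used by `to_euler_angles()` and the rotational
clipping precision is intrinsic Z-Y-X in degrees. The convention is not
dictated by the statistics themselves; it is fixed, documented, and all
computations go through rotation matrices, so any other convention can be
layered on top.

## Assessment statistics

*Point prediction error (PPE).* Six marker poses `T_1..T_6`, mechanically
arranged point-symmetrically around a symmetry point, are applied to a
virtual target `P` in the marker frame; the PPE is the RMS deviation of the
six transformed points about their mean. The divisor 6 is part of the
definition (`point_dispersion_rms()` is the clearly named generalized-n
variant). The statistic is reference-free: no manual annotation enters, so
it is not inflated by inter-observer variability or image resolution.

*Repeatability error* applies the same formula to six repeat localizations
of one fixed pose, isolating scan-to-scan jitter from station geometry.

*Clipping precision.* ε_trans is the mean absolute deviation of the scalar
reference-to-holder distances about their mean — implemented literally on
the scalar distances. Being scalar, it is blind to tangential shifts, so
the package also provides `clipping_translation_precision_vector()` (mean
norm of the 3-vector deviations), clearly named and separate. ε_rot
averages the L2 norms of the Euler-angle vectors about their component-wise
mean; angle series are unwrapped relative to the first sample beforehand,
because component-wise means are ill-defined across the ±180° cut, and a
series still spanning more than 180° after unwrapping is an error rather
than a silently wrong average. Reported "±" spreads are sample (n − 1)
standard deviations.

*Target registration error (TRE)* is the Euclidean distance between
registered and independently marked target positions, summarized as mean ±
sample sd. The CT-to-ultrasound chain that produces registered positions is
assembled with `compose_chain()` from the marker-to-CT pose (inverted), the
constant sensor-holder-to-marker offset, and the tracking and ultrasound
calibration transforms, which enter as given inputs.

## The synthetic phantom study

`phantom_spec()` reproduces a six-station assessment phantom: stations on a
circle of radius 100 mm around the symmetry point in the z = 0 plane at 60°
steps (stations i and i+3 antipodal), with the *angle* variant tilting each
station toward the symmetry axis (default 30°). Published drawings of such
phantoms fix the 100 mm station radius but not numeric target coordinates,
so the package places its virtual targets on the symmetry axis at depths
25, 50, 75, 100, 150 and 175 mm below the station plane — a spread that
brackets realistic intervention depths — and derives their marker-frame
coordinates from the ideal station poses. By construction every ideal pose
maps each target to one common world point, so the ideal PPE is exactly
zero and everything measured on rendered series is attributable to the
localization pipeline. The target at 100 mm depth is always index `"P100"`
for comparability between the plane and angle phantoms.

`render_marker_volume()` renders bright spheres with exact supersampled
partial-volume occupancy (default 4³ sub-samples per voxel, bounding the
per-voxel occupancy error by 1/64), an optional Gaussian point-spread
(default FWHM 0.8 mm), additive Gaussian noise, and for MRI an optional
smooth multiplicative bias field. Intensity defaults are HU-like for CT
(background 40, feature 3000, noise sd 15 — steel spheres bloom far beyond
soft tissue) and arbitrary-units for MRI (background 100, feature 1000,
noise sd 20). Every stochastic element takes an explicit seed; nothing
defaults to wall-clock state.

What the generator deliberately does *not* emulate: anatomical background
and organs, CT reconstruction physics (beam hardening, streak artifacts),
MRI geometric distortion, and marker mounting play. Passing tests on
rendered volumes therefore demonstrate the correctness and the sampling
behaviour of the pipeline — not its robustness to in-vivo artifacts, which
only scanner data can show. The deposited scanner volumes of the original
assessment study are the natural benchmark for that; they are not shipped
with the package.

## Marker geometries

The exact canonical feature coordinates of the physical marker are
configuration data, not algorithm. The package ships four documented
default geometries (`3_15`, `3_20`, `5_20` CT; `6_20` MRI) whose centroids
were generated once by randomized search under the structural invariants:
two parallel planes 10 mm apart, four features per plane in asymmetric
quadrilaterals, minimum pairwise distance exactly the named 15 / 20 mm, all
28 pairwise distances mutually separated by more than τ = 1 mm, and all 8
distance signatures distinct at τ. The three 20 mm configurations share one
centroid layout — the features are exchangeable spheres on one platform —
and differ in feature diameter and modality. Any other marker is supplied
as a YAML config (`read_marker_geometry()`), and validation is always run:
a geometry with two equal distances is rejected as ambiguous rather than
silently accepted.

## Numerical choices and degenerate inputs

* Voxel indices are 0-based and continuous, with the world position of
  index (0,0,0) at the *center* of the first voxel; the world frame is LPS
  in millimetres. NIfTI (RAS) input is flipped on read.
* DICOM slice spacing is measured from inter-slice positions; disagreeing
  SpacingBetweenSlices or SliceThickness tags warn (measured value wins),
  non-uniform positions (a missing slice) and inconsistent orientations are
  errors. Slice thickness equal to slice spacing is the supported
  acquisition; gaps under-sample features and are flagged.
* Two features closer than a voxel merge into one candidate; the merged
  blob fails the distance configuration and is rejected by the matcher —
  documented behaviour rather than a guess.
* Collinear point sets do not determine a rotation and are rejected by the
  Horn solver.
* `reslice()` slab-averages along z with nearest-neighbour slab boundaries
  for non-integer thickness ratios; total intensity × volume is conserved
  up to the partial trailing slab.
* Gimbal-locked Euler extraction (|pitch| ≈ 90°) warns and returns the
  non-separable angle combination in the first component.

## Problem sizes used in the shipped tests

The test suite and the acceptance script run entirely on rendered volumes
at the study's voxel geometries (0.98 × 0.98 mm in-plane with 0.6 | 1 | 3 |
5 mm slices for CT; 0.5 × 0.5 × 1.0 and 0.4 × 0.4 × 4.0 mm for MRI).
Pose-recovery coverage is 4 configurations × 4 slice thicknesses × 24
random poses at zero noise; matcher robustness uses 500 simulated candidate
constellations with 4 volume-plausible distractors (and 100 with a missing
feature); noise robustness uses 40 rendered seeds at 10 % of the feature
contrast; the phantom-series tests average 3 phantom orientations per slice
thickness. These sizes were chosen as the smallest that exercise every
code path with stable statistics.

## Known limitations

* The pipeline assumes bright features on a darker background; inverted
  contrast would need a new modality profile.
* The volume-pruning rule uses the partial-volume-corrected component volume; features imaged
  at extreme partial volume (feature diameter well below slice thickness)
  can fall below the 0.6 × cutoff and are then reported as
  `insufficient_candidates` rather than guessed at.
* The exhaustive fallback caps the candidate pool at 16; pathologically
  cluttered scenes beyond that report failure rather than search further.
* Physical assessment quantities (clipping precision of a real plate, TRE
  against tracked ultrasound) depend on hardware experiments; the package
  implements the statistics and verifies them on hand-computable examples
  and synthetic chains only.
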