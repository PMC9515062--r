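# fidloc

Automatic localization of a reattachable eight-sphere fiducial skin marker
in CT and MRI volumes, with the assessment statistics and synthetic phantom
study that characterize it.

## The problem

Marker-based registration is the workhorse of image-guided interventions:
a fiducial marker visible in pre-interventional CT/MRI provides the rigid
link between the image and intra-interventional tracking or ultrasound
data. A *reattachable* skin marker — eight spherical features uniquely
distributed over two parallel planes, clipped onto a skin-mounted plate in
a reproducible pose — lets imaging happen days before the intervention.
What remains to be computed automatically at intervention time is the
rigid transform from the marker's canonical frame to the image.

`fidloc` estimates that transform in three stages:

1. **Detection** — a self-adjusting filter pipeline (percentile background
   suppression, Gaussian-derivative edge response at scale d/6, Otsu-based
   binarization, 26-connected labeling) reduces the volume to bright-sphere
   candidates, pruned by the physical-volume rule: discard candidates below
   0.6 × the true feature volume (π d³/6), and for MRI also above 2 × it.
2. **Correspondence** — the marker's 28 pairwise distances are unique
   (validated at tolerance τ), so candidates that fit no known distance
   configuration are iteratively excluded, the surviving eight are ordered
   by nearest distance signature (exact 8 × 8 assignment), and the result
   is verified by its fit residual, with an exhaustive subset fallback.
3. **Pose** — Horn's closed-form unit-quaternion solution of the
   absolute-orientation problem, `argmin_{R,t} Σᵢ ‖R sᵢ + t − tᵢ‖²` with
   det R = +1, no scale; the RMS residual is the fiducial registration
   error (FRE).

The assessment side implements the *point prediction error*
`PPE = sqrt(Σᵢ₌₁⁶ ‖pᵢ − p̄‖² / 6)` for six point-symmetric marker poses
applied to a virtual target, the repeatability error (same statistic on
repeat scans), the clipping precision `ε_trans = (1/n) Σ |lᵢ − l_mean|`
and `ε_rot = (1/n) Σ ‖θᵢ − θ_mean‖₂`, and the target registration error,
plus a ground-truthed synthetic generator reproducing the six-station,
100 mm-radius point-symmetric phantom geometry at four CT slice
thicknesses (0.6 | 1 | 3 | 5 mm) and the two MRI voxel geometries.

## Worked example

```r
library(fidloc)

geo  <- marker_geometry("3_15")          # 3 mm spheres, >= 15 mm apart, CT
pose <- rigid_transform(rotation_about_axis("z", 25) %*%
                        rotation_about_axis("x", 10), c(5, -3, 2))
scene <- render_marker_volume(geo, pose, render_profile("CT", noise_sd = 0),
                              spacing = c(0.98, 0.98, 1))

fit <- localize_marker(scene$volume, geo)
fit
#> Fiducial marker localization (3_15, CT)
#>   status: success (direct matching), FRE 0.0140 mm
#>   translation (5.00, -3.00, 2.00) mm, Euler z-y-x (25.00, -0.00, 10.00) deg
```

The fit recovered the simulated pose: translation (5, −3, 2) mm and the
25° / 10° rotations are reproduced to hundredths of a millimetre and
degree, and the FRE of 0.014 mm says the eight detected centroids agree
with the rigidly transformed canonical geometry at the hundredth-millimetre
level. `coef(fit)` returns the 4 × 4 marker-to-image matrix,
`predict(fit, points)` maps marker-frame points (e.g. a planned target)
into the image, `residuals(fit)` gives the per-feature errors, and a
failed localization carries an explicit status
(`insufficient_candidates`, `no_consistent_subset`, `high_residual`)
rather than a silently wrong pose.

A full phantom assessment is two calls:

```r
spec   <- phantom_spec("plane")          # 6 stations, 100 mm, point-symmetric
series <- make_phantom_series(spec, geo, render_profile("CT"), c(0.98, 0.98, 1))
fits   <- lapply(series$volumes, localize_marker, geometry = geo)
point_prediction_error(lapply(fits, `[[`, "transform"),
                       series$virtual_targets["P100", ])
#> [1] 0.02105915
```

A PPE of 0.021 mm at the 100 mm target (with the default noise seed) says
the six station poses, each estimated independently from its own rendered
scan, agree on the position of a deep target to a fiftieth of a
millimetre.

## Command line

A thin wrapper over the same functions ships at `inst/cli/fidloc`:

```sh
fidloc simulate --out study/ --geometry 3_15 --seed 7
fidloc localize --volume study/station_1.mha --geometry 3_15 --out report.json
fidloc assess   --manifest study/manifest.json --out ppe.csv
fidloc validate-geometry my_marker.yaml
fidloc metrics  --clipping clip.csv
```

Exit codes: 0 success, 2 localization failure, 1 I/O error. Every chosen
threshold and seed is echoed into the JSON/CSV reports.

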