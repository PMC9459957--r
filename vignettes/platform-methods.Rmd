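---
title: "Methods: turntable LiDAR scanning, reconstruction and phenotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: turntable LiDAR scanning, reconstruction and phenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoscan)
```

## The measurement model

The platform couples a 2D phase-correlation LiDAR with a stepper-driven
turntable. The scanner sweeps a vertical fan of beams (70° aperture, 0.0833°
angular resolution, 70–300 cm working range); the specimen rotates beneath it
in steps of 0.1° (a worm-and-wheel train of 10,000 motor steps × ratio 36
gives 360,000 steps per revolution, i.e. 0.001° of mechanical resolution).
One vertical sweep at a fixed disc angle is a *profile*; the profiles over a
rotation form the scan.

Each return is a pair (s, θ): range along the beam and beam elevation. The
reconstruction chain maps it into the disc frame (origin at the disc centre
O, disc surface z = 0) through four homogeneous transforms:

1. **Sensor plane**: p′ = (−s cos θ, 0, s sin θ, 1) in the vertical scan
   plane X′Z′ (`polar_to_sensor_plane()`).
2. **Sensor tilt**: rotation by the tilt φ about the Y′ axis
   (`tilt_transform()`). Because the fan lives in the X′Z′ plane, this is a
   pure pitch: tilting a return at beam angle θ equals the untilted return
   at θ + φ. We deliberately model the tilt as a Y′ rotation rather than an
   X′ rotation: only a pitch of the scan fan is observable in the profile of
   a vertical target (an X′ roll leaves every beam's horizontal component
   unchanged), and the calibration procedure below depends on exactly that
   observability. The same reasoning fixes the translation matrix's third
   row to the standard [0 0 1 h] form.
3. **Sensor-to-disc translation** by (d, 0, h): d is the horizontal distance
   from the sensor origin to O, h the signed height of the sensor above the
   disc surface (`sensor_to_disc_translation()`).
4. **Disc rotation** by the turntable angle ϕ about the vertical axis
   (`disc_rotation()`).

All four are rigid motions; the suite verifies isometry to 1e-9 cm and that
`reconstruct_profile()` equals a single composed-matrix application.

Units are centimeters and degrees at every interface. The one exception is
the noise polynomial (below), whose distance argument is in meters.

## Platform calibration

`calibrate_from_target()` estimates (d, h, φ) from a profile of a 40 × 4.5 cm
low-reflectance planar target standing vertically through O:

* the sensor-plane returns are split into a dominant near-vertical line (the
  target face) and the remaining returns by a deterministic RANSAC with
  iteratively trimmed total-least-squares refinement (orthogonal regression,
  because range noise acts along the beam, not along one axis). The trimming
  band shrinks toward 3× the fit RMS, so on noiseless data the fit converges
  to the exact line;
* φ is the signed angle between the fitted line and the Z′ axis;
* after de-tilting by φ the target line is vertical at x = −d;
* h anchors the disc surface: every return from the turntable surface
  de-tilts to exactly z = −h, so h is minus the lowest de-tilted z among
  returns within 25 cm of the disc axis. The simulated calibration scene
  therefore includes the turntable surface itself
  (`build_target(include_disc = TRUE)`), as it is in view during a real
  calibration sweep.

This estimator is exact (machine precision) on noiseless scans whenever the
target base region is inside the scan fan and in range — the physical
prerequisite of the procedure. When no beam reaches the disc surface
(sensor nearly level with the disc at long range, or the base outside the
aperture), h is not identifiable from the profile at all; the function then
falls back to the lowest target return, which is only accurate to the beam
spacing (~0.15 cm at 1 m). Calibration studies in the tests sample
geometries from the identifiable domain: d ∈ [70, 300] cm, h ∈ [−50, 50] cm,
φ ∈ [−5°, 5°], with the base corner's elevation within ±30° of the fan
centre and at least one disc return present.

## The scanner simulator

`simulate_scan()` ray-casts parametric triangle-mesh scenes (Möller–Trumbore
without backface culling, compiled): the 5.5 cm reference cube, the planar
calibration target, and maize-like seedlings (tapered stem cylinder, ribbon
leaves with parabolic droop, optional pot; total height constrained to the
10–40 cm seedling range; every triangle carries an organ label that becomes
per-return ground truth). For a profile at disc angle ϕ the scene is rotated
by −ϕ and intersected with rays from the sensor origin, so a noiseless scan
reconstructs exactly onto the generating surface (point-to-mesh distance
below 1e-6 cm in the tests).

Range noise is Gaussian along the beam with standard deviation

σ(d) = 0.0639 d³ + 0.1139 d² + 0.0473 d + 0.0589,

with d in meters and σ in centimeters. That unit reading is a deliberate
choice: over the 0.7–3 m working range it yields σ ≈ 0.06–3 cm, the only
scale consistent with a sub-millimetre dispersion near minimum range. Each
profile is acquired `repeat_count` times (default 100) and averaged, so the
effective dispersion is σ(d)/√100; per-repeat draws outside the working
range count as missed, and a beam missed in more than half of the repeats is
dropped (never zero-filled). Scattering at grazing incidence degrades the
measurement; rather than model the radiometry, we inflate σ by
1/cos(incidence) capped at 3. Intensity is cosmetic plumbing — a Lambertian
cosine with a (70/d)² falloff, clipped to [0, 1]. All randomness is governed
by the scanner's `rng_seed`: identical seeds give bit-identical profiles.
Thin-structure dropouts emerge from geometry alone: a leaf ribbon subtending
less than the beam spacing collects fewer returns per unit area than the
stem, which the suite asserts.

## Cube metrology

Accuracy is assessed by scanning the reference cube and measuring its 12
edges (`measure_cube_edges()`): sequential RANSAC plane segmentation with
total-least-squares refinement recovers the top and the four side faces;
each corner is the intersection of its three adjacent planes, with the
unscannable bottom face taken as the disc surface z = 0; edge lengths are
corner-to-corner distances. Horizontal edges are assigned to the X or Y axis
by orientation (U* on the top face, D* on the bottom), vertical edges are
L1–L4. The default plane-inlier tolerance (0.1 cm) matches ~3× the
per-point noise of a repeat-averaged scan at ~1 m; pass `inlier_tol_cm` to
adapt it to other conditions. The plane-intersection definition of the edge
endpoints replaces what is otherwise a manual measurement in a point-cloud
viewer, and makes the procedure deterministic and testable.

`error_report()` summarises a 12-edge set: individual errors
|m − Ref|/Ref × 100 (absolute value, so over- and under-estimates both count
positive), per-axis means, overall accuracy as the unweighted mean of the
three axis means, and the absolute error √(Σ(m−m̄)²/(N(N−1))) with N = 12.
`fit_precision_polynomial()` recovers the cubic precision curve from
(distance, dispersion) pairs such as those produced by
`dispersion_experiment()`, which repeats the zero-incidence single-face
distance measurement (142 repetitions by default) across distances.

## Traits

After statistical outlier removal (`remove_outliers()`, defaults k = 20
neighbours, 2 standard deviations — the customary settings for clouds of
this density) and Z-axis cropping of the pot
(`crop_pot()`; the cut height is per-scan information, not a fixed
constant), two scalar traits are computed:

* **height** = max z over the cloud (disc surface is z = 0);
* **volume** = 2.5×10⁻³ cm³ × (occupied voxel count) on an axis-aligned grid
  anchored at the cloud minimum (`voxel_volume()`). The coefficient is taken
  at face value as the experimentally calibrated value; the accompanying
  "25 cm" voxel distance is dimensionally inconsistent with it (it would
  give 1.5625×10⁴ cm³ per voxel) and is treated as a typo. By default the
  voxel edge is the coefficient's cube root (~0.136 cm), the matched choice
  under which the estimate converges to the geometric volume for densely
  sampled solids; both edge and coefficient are configurable. Surface-only
  scans of course measure an envelope count, not a solid volume — the
  growth-series test checks the monotone pattern, not absolute values.

## Organ classification

The stem/leaf classifier works on per-point descriptors
(`extract_features()`): normalized height, radial distance to the estimated
stem axis (horizontal centroid of the bottom 10% height slab), the local
eigenvalue family over a spherical neighbourhood (linearity (λ1−λ2)/λ1,
planarity (λ2−λ3)/λ1, sphericity λ3/λ1, verticality of both the principal
direction — near 1 on a stem — and of the normal — near 1 on a horizontal
blade), and local density. This eigenvalue/height/radial family is the
standard geometric descriptor set for organ-level point-cloud segmentation
and is this package's own choice. Points with fewer than 3
neighbours get sentinel features and, at prediction time, inherit the label
of the nearest classified point.

Scans are split plant-wise 60/20/20 into train/tune/validate
(`split_dataset()`), after routing into early (≤ 3 leaves) and late stages.
A Random Forest (`ranger`) is tuned over {50, 100, 200} trees × depth
{8, 16, unlimited} by tune-set accuracy — the tuning split exists precisely
to select these hyperparameters, which no fixed setting suits across point
densities. Finally `ring_filter()` sweeps a fixed-radius virtual ring up the
stem axis and relabels any stem-labeled point outside it as leaf; it never
touches leaf labels, hence is idempotent and can only raise stem precision.
The default ring radius is 0.0015 in the cloud's native units — the value
the platform's processed clouds were filtered with. Read in centimeters,
1.5 mm would be implausibly thin for a maize stem, so the value is best
treated as unit-ambiguous: the synthetic benchmark uses a radius matched to
the simulated stem instead (0.5 cm against a 0.35 cm stem base radius), and
the radius is overridable everywhere via `radius`/`--ring-radius`.

## What the synthetic benchmark does and does not show

The simulator emulates the scanner geometry, the calibrated range-noise
curve, repeat averaging, occlusion and thin-structure dropout. It does not
emulate reflectance- and texture-dependent deflection, mixed pixels at
edges, leaf curl/twist beyond the parabolic midrib, wind, or registration
drift. Classification accuracy on seeded synthetic seedlings (the suite
requires a mean of at least 85% over validation plants) therefore
demonstrates that the descriptor–forest–ring pipeline is correctly built and
separates the geometry it is given; it is not a claim about accuracy on real
potted maize, which only runs against field data can make.

## Numerical choices and problem sizes

* Deterministic RANSAC everywhere (fixed internal seeds), TLS refinement,
  trimming bands floored at 1e-9 so exact data stays exact.
* Degenerate inputs: empty profiles reconstruct to empty clouds; empty
  clouds have volume 0 and no height; missed beams are dropped; clouds too
  small to filter are returned unchanged with a warning.
* Test problem sizes, chosen to exercise the conditions at sensible cost:
  cube round trips at 1° turntable step and full beam resolution (~16k
  points); seedling scans at 2–3° steps and 0.25° beam resolution (~5k
  points per plant); 100 random calibration geometries; a 20-plant
  classification benchmark (11/4/5 split); 200k–600k-point solids for voxel
  convergence.
* The acceptance script recomputes the error-table quantities from the
  bundled 12-edge reference measurement set at run time.

## Known limitations

* Beams are ideal rays — no divergence, no multi-echo.
* `measure_cube_edges()` assumes the cube rests flat on the disc (bottom
  face = z = 0) and needs the top and all four side faces resolvable.
* h is unidentifiable from a calibration scan whose fan never reaches the
  disc surface; the fallback is only beam-spacing accurate (see above).
* The OSF-style archive reader is layout-tolerant and fixture-tested only;
  campaign folders in the wild may need the file-role patterns adjusted.
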