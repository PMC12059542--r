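---
title: "Bubble-cloud localization and robot calibration: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bubble-cloud localization and robot calibration: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Histotripsy destroys tissue mechanically: focused ultrasound pulses
cavitate endogenous gas into an ellipsoidal "bubble cloud" of roughly
4 x 4 x 8 mm at the transducer focus. When treatments are guided by
cone-beam CT (CBCT) rather than diagnostic ultrasound, the system relies
on a chain of coordinate registrations ending at the assumption that the
bubble cloud forms exactly at the transducer's theoretical (CAD-model)
focal point. In practice it does not: each transducer carries a small,
stable 3D offset between the theoretical and actual cavitation location.
histocal implements the calibration-correction workflow that measures
this offset: a layered agar phantom in which a single bubble cloud
becomes visible as layer mixing, an automated algorithm that localizes
the cloud centroid from a pre/post-treatment CBCT pair, a four-cloud
joint estimator that stabilizes the offset measurement, and a synthetic
CBCT simulator so the whole chain can be exercised and validated without
a C-arm.

## The phantom and its simulator

The physical phantom is a 5 x 5 x 2.5 cm agar block of 11 alternating
layers: six plain agar and five doped with barium sulfate. Plain agar
(1.5% in water) is nearly water-equivalent on CT, so the barium layers
carry the contrast; `phantom_spec()` defaults encode this as intensities
15 / 400 / 0 (plain / barium / water, arbitrary units). Mechanical
disintegration mixes the layers, and the mixed region's mean CT number
moves toward the local average, which is what makes a single cloud
visible in the difference image.

`build_phantom()` draws per-layer thicknesses uniformly from 3-4 mm
(plain) and 1-1.5 mm (barium) and, because those ranges can overfill the
25 mm mold, rescales the stack to the mold depth when needed (the
physical analog is pouring slightly thinner layers; the ~3-4.6 mm barium
period is preserved). A per-layer jitter (default 0.25 mm) models
manufacturing variability between phantoms. The stack is blurred by a
Gaussian reconstruction PSF (default SD 0.5 mm).

`apply_treatment()` blends each voxel toward the *homogenized value* --
the mean of the untreated volume over a 10 mm Z window at the treatment
XY footprint -- with weight `m(t) * s(x)`, where `s` is a smoothstep of
the normalized ellipsoid distance (1 inside 80% of the radii, 0 at the
boundary) and `m(t) = 1 - exp(-t / tau)` is the saturating mixing
fraction. `tau = 11.6` s makes the 20 s / 5 s mixing ratio equal the
observed 122.9 / 52.5 ratio of treatment-zone intensities at those
durations. Zero-mean Gaussian heterogeneity noise (default SD 58, i.e.
0.15 x the barium/plain contrast) models uneven mixing; its SD doubles
when a second barium layer falls inside the cavitation core, emulating
barium powder seeding cavitation -- this is what reproduces the observed
higher intensity change when treating *between* layers versus *on* a
layer. A treatment whose ellipsoid touches a barium layer also has its Z
semi-axis dilated by 1.25, the mechanism behind the greater Z
variability of single-cloud localization. The beam-path extension toward
the transducer seen at long durations is available (`tail_length_mm`)
but off by default: an always-on half-weight tail would bias the Z
centroid by about half the tail length relative to the treatment-center
ground truth, contradicting the sub-1.5 mm agreement of automated and
manual localization reported for 20 s treatments.

`acquire_scan()` models each CBCT acquisition: a small rigid settling
shift of the phantom in the water bath (uniform +/-1 mm, +/-0.5 deg by
default) and additive Gaussian intensity noise (SD 8). Pre and post
scans get independent noise streams; the pre scan defines the plan
frame. `generate_pair()` wires these together and attaches the
ground-truth treatment centers. Ground truth is the *treatment center*,
not the intensity centroid, so every localization error budget includes
the physics of the contrast mechanism, not just the optimizer.

The default grid is 0.47 mm/voxel -- the reconstruction pitch of the
reference C-arm protocol -- over a 60 x 60 x 35 mm field (about
128 x 128 x 75 voxels). Keeping this pitch matters because the
algorithm's constants are voxel-denominated (5-voxel filter kernel,
1-voxel SD, +/-2- and +/-4-voxel seed perturbations).

### What the simulator does not emulate

Polychromatic CT artifacts (beam hardening, scatter, rings), the water
bath and phantom walls, projection-domain noise correlations, acoustic
propagation and cavitation physics, and operator variability in seed
selection. Passing tests therefore demonstrate correctness of the
algorithm and realistic behavior under the modeled noise; they bound,
but do not measure, performance on clinical C-arm data. The translation
experiment in particular assumes perfectly aligned robot and CBCT axes,
so its residuals are an idealized lower bound.

## The localization algorithm

`localize_single()` chains four stages:

1. **Rigid registration** (`register_rigid()`): the pre volume is
   registered to the post volume by minimizing the mean squared error
   over overlapping voxels, with trilinear interpolation, a 3-level
   block-mean pyramid, and a derivative-free Nelder-Mead simplex at each
   level. An exhaustive +/-2 mm translation grid at an extra-coarse
   level seeds the simplex inside the global basin (the layered phantom
   has strong local minima one layer period apart in Z). We use
   Nelder-Mead rather than gradient descent because it needs no metric
   gradients, is deterministic, and is robust in this 6-parameter
   small-displacement regime; each level optimizes the *offset* from the
   incumbent so the initial simplex edge is a fixed 0.1 mm / 0.05 deg.
   Convergence: relative MSE change below 1e-6 or the per-level
   iteration budget (400/300/100 coarse-to-fine, with one fine-level
   restart). The registered pre is resampled onto the post grid, so all
   intermediate coordinates live in the post-scan frame and the final
   centroid is mapped back to the plan (pre-scan) frame through the
   estimated transform.
2. **Difference image** (`difference_image()`): the absolute voxel-wise
   difference, smoothed by a separable Gaussian (5-voxel kernel, 1-voxel
   SD per axis) to stabilize the optimization.
3. **XY search** (`optimize_xy()`): a 4 x 4 x 30 mm cuboid ROI --
   slightly wider than the nominal cloud and ~3x its height, so all
   treated layers are encompassed and the cost is only weakly
   Z-sensitive -- is moved in the layer plane to maximize the mean
   difference intensity inside it. The cost samples the volume on a
   lattice of pitch equal to the voxel spacing anchored to the cuboid
   center, making it continuous in the center. Nelder-Mead runs from 7
   starts (seed, +/-2 voxels in X, +/-2 in Y, +/-4 in Z); the winner is
   the highest converged cost, ties broken toward the unperturbed seed.
4. **Z localization** (`z_profile()` + `locate_z()`): the central third
   of the cuboid footprint is averaged over X and Y to a 1D column,
   which is scanned from both ends for the first sample above the
   column mean. If the bracketed extent reaches the expected 8 mm cloud
   height, the Z coordinate is the midpoint of the crossings; below
   8 mm -- the cloud sitting between barium layers, where mixing does
   not delineate its ends -- the intensity-weighted centroid (first
   image moment) is used. The moment is computed over the detected
   supra-threshold span, not the full 30 mm window: like the midpoint
   rule it then uses only the bracketed cloud, and sub-threshold
   structure elsewhere in the window (an adjacent treatment zone, a
   bright layer remnant) cannot drag the centroid. We adopted this
   reading after finding that a full-window moment biases the
   translation experiment's Z residuals beyond the sub-0.3 mm regime
   the method is known to achieve.

Numerical choices worth knowing: out-of-bounds samples return a
configurable background (default 0) so ROIs may poke past a cropped
volume edge; the simplex tolerance (1e-6 relative on cost, 200
evaluations per start) sits well below the acceptance granularity; all
tie-breaks are deterministic, so identical inputs give bit-identical
results.

## The four-cloud calibration estimator

A single cloud's Z estimate inherits the layer-phase sensitivity above.
The calibration pattern places four clouds 10 mm apart in Y (fresh
phantom areas) and 1 mm apart in Z (each cloud samples a different layer
phase). `localize_pattern()` proceeds in three stages: per-cloud
single localization (sharing one registration) whose average deviation
initializes a shared offset; a joint Nelder-Mead over a single (X, Y)
offset applied to all four rigidly co-moving ROIs, maximizing the mean
ROI cost; and a joint Z step that shifts each cloud's Z profile by its
known 1 mm stagger, averages the four aligned profiles, and applies the
unchanged dual Z rule to the average. The joint-Z-by-profile-averaging
step is our resolution of how "optimized together" extends to Z: it is
the minimal joint extension of the single-cloud rule, and averaging
four phase-staggered profiles is precisely what cancels the per-phase
Z wobble. The reported offset is the average measured centroid minus
the average planned centroid, signed per axis (measured - planned),
with the Euclidean norm alongside.

Seeding: the operator of the physical workflow picks the seed manually
at the *observed* cloud center on the post scan. The automated stand-in
(`find_observed_seed()`) takes the brightest difference voxel near the
planned target, with a search window kept below half the 10 mm pattern
spacing so a large transducer offset cannot alias the pick onto a
neighboring cloud.

## Experiments and their designs

* `run_duration_experiment()` treats at 5-30 s, on and between layers,
  measures visibility (mean filtered |difference| inside the nominal
  4 x 4 x 8 mm ellipsoid) and applies the balanced duration-group
  normalization to isolate the position effect.
* `run_translation_experiment()` creates a reference cloud on a barium
  layer and a second cloud at the planned 1-6 mm translation along the
  tested axis plus a fixed 10 mm lateral offset, so adjacent clouds
  never merge (the same non-overlap trick as the calibration pattern;
  non-overlapping adjacent treatments were feasible in the physical
  experiment too). Both clouds are localized from one registered pair;
  the measured translation is the signed centroid-difference component
  along the planned axis, pooled into the mean residual error per axis.
* `run_mad_experiment()` runs replicate calibration sessions with one
  fixed injected offset and compares the per-axis mean absolute
  deviation of the joint estimator (n sessions) against the single-cloud
  estimator (4n clouds).
* `run_offsets_experiment()` injects per-"transducer" offsets spanning
  roughly +/-4 mm and reports median, IQR, and recovery bias.

Default replicate counts are the study design (10 per translation cell,
4 calibration sessions, 6 sessions per transducer); configs scale down
for quick runs. Every replicate row records the derived seed that
regenerates it, and a fixed master seed makes reports byte-identical.

Problem sizes: the test suite and the acceptance script run the full
translation design (180 scan pairs at 128 x 128 x 75 voxels), the
4-session calibration comparison, 12 single-cloud phantoms, and a
2-transducer x 6-session recovery study; together these complete in
about 10 minutes on one core, which we consider the practical desk
scale for routine revalidation.

## Known limitations

* Only axis-aligned volumes are supported; oblique CBCT exports must be
  resampled upstream.
* The registration capture range is the +/-2 mm grid plus simplex
  expansion; bath shifts beyond ~3 mm or rotations beyond ~2 deg are
  outside the validated regime.
* The simulator's contrast model is piecewise-constant-plus-noise; it
  does not reproduce beam hardening near the barium layers, so absolute
  visibility values are in arbitrary units and only their ratios and
  orderings are meaningful.
* The single-cloud Z estimate remains the weakest axis by construction
  (layer-phase sensitivity); the four-cloud estimator exists precisely
  to average it out, and patterns other than the fixed 4-cloud design
  are untested.
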