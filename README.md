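# histocal

Bubble-cloud localization and robot-to-focal-point calibration for
CBCT-guided histotripsy.

Histotripsy focuses ultrasound pulses to cavitate tissue into an
ellipsoidal "bubble cloud" (~4 x 4 x 8 mm). When the therapy is guided
by cone-beam CT, targeting accuracy rests on knowing where the cloud
actually forms relative to the robot arm — and each transducer carries a
small, stable 3D offset between its theoretical (CAD-model) focal point
and the real cavitation location. histocal measures that offset: it
localizes single bubble-cloud treatment zones from pre/post-treatment
CBCT scans of a layered agar phantom, and estimates the transducer
offset from a fixed four-cloud calibration pattern. A synthetic
layered-phantom CBCT simulator with known ground truth makes the whole
workflow testable without a C-arm.

## What it computes

For a registered pre/post pair, the treated region appears in the
Gaussian-filtered absolute difference image `G * |post − pre∘T|`, where
`T` is the rigid transform minimizing the mean squared error between the
scans. A 4 x 4 x 30 mm cuboid ROI is moved in the layer plane by a
multi-start Nelder–Mead simplex to maximize the mean difference
intensity; the Z coordinate comes from a dual rule on the ROI's central
column profile — the midpoint of the first threshold crossings from both
ends when the bracketed extent reaches the expected 8 mm cloud height,
the intensity-weighted centroid (first image moment) of the bracketed
span otherwise.

The calibration offset is `mean(measured centroids) − mean(planned
centroids)` over the four-cloud pattern (10 mm Y / 1 mm Z spacing), with
the four ROIs optimized jointly as a rigid set. Accuracy metrics follow
the study conventions:

* **MRE** (mean residual error): `(1/(6n)) Σ_j Σ_i (d_ij − j)`, the
  signed pooled mean of measured-minus-planned translations;
* **MAD** (mean absolute deviation): `(1/n) Σ |x_i − mean(x)|`, the
  replicate variability of an offset estimator;
* visibility: mean filtered |difference| inside the nominal
  4 x 4 x 8 mm ellipsoid, with a balanced duration-group normalization.

## Worked example

Simulate one 20 s treatment at (0, 0, 1) mm in a default phantom, then
localize it from the noisy, shifted scan pair:

```r
library(histocal)

pair <- generate_pair(treatments = treatment_spec(c(0, 0, 1)), rng_seed = 7)
res  <- localize_single(pair$pre, pair$post, seed_mm = c(0, 0, 1))
res
#> <localization_result> centroid (plan frame): (0.190, 0.084, 0.998) mm
#>   cost 13.14 | Z extent 8.46 mm | Z method: boundary_midpoint
glance(res)
#> # A tibble: 1 x 7
#>    x_mm   y_mm  z_mm  cost z_extent_mm z_method          improved
#>   <dbl>  <dbl> <dbl> <dbl>       <dbl> <chr>             <lgl>
#> 1 0.190 0.0835 0.998  13.1        8.46 boundary_midpoint TRUE
```

The ground-truth center was (0, 0, 1) mm (`pair$truth`), so this
localization is off by (0.19, 0.08, 0.00) mm — well inside the 1.5 mm
margin within which the automated algorithm matches manual segmentation.
The detected 8.5 mm Z extent exceeds the 8 mm threshold, so the
boundary-midpoint branch fired. `tidy(res)` lists all seven simplex
starts with their converged costs.

Calibration against a four-cloud pattern, and the synthetic experiments,
follow the same shape:

```r
pat <- calibration_pattern(c(0, -15, -1.5))        # 10 mm Y / 1 mm Z steps
off <- localize_pattern(pre, post, pat)            # offset_result
rep <- run_translation_experiment(experiment_config("translation"))
autoplot(rep)                                      # measured vs planned strip plot
```

Experiment reports are tibbles (`rep$data`, `rep$summary`) with one row
per replicate carrying the seed that regenerates it; `autoplot()`
methods draw the standard summary figures. Volumes read and write NIfTI
(`.nii`/`.nii.gz`) and NRRD, and a thin command-line front end lives at
`inst/cli/histocal.R` (`simulate`, `register`, `localize`, `calibrate`,
`experiment` subcommands).

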