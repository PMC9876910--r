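# hipcal

Patient-individual calibration of the hip-plane magnification factor for
digital templating in total hip arthroplasty, from one antero-posterior
and one lateral radiograph with a single spherical calibration marker.

## The problem

Templating hip implants on an a.p. pelvis radiograph requires knowing the
magnification of the *hip plane* — the plane parallel to the detector
through both hip-joint centres. For an object at height *H* above the
detector with source-detector distance *S*, the intercept theorem gives
the calibration factor (percent, 100 = life size)

    F = 100 · S / (S − H).

A marker ball taped to the patient is rarely *in* the hip plane, which is
why single-marker calibration is unreliable. The bi-planar method solves
this with two orthogonal views of the same marker:

1. **A.p. view** — the marker's projected ellipse (long axis *k*, centre
   displacement *h*) yields its height above the detector,

       H_ECM = S − sqrt( r²(1 + 2S²/k²) + (2rS/k)·sqrt(r²S²/k² + h²) ),

   with the measured displacement recalibrated by fixed-point iteration
   (it is itself a magnified length).
2. **Lateral view** — the same construction calibrates the horizontal
   marker-to-hip-plane distance `d_cal`.
3. **Correction** — patient rotation α = asin(c_cal / m_cal) (from the
   mismatch of the projected hip centres) and the marker's lateral offset
   `i_cal` are removed:

       y_corr = (d_cal ± sin(α)·i_cal) / cos(α)
       H_Hip  = H_ECM − y_corr,   F_Hip = 100·S / (S − H_Hip).

The package implements the full landmark→F_Hip pipeline with automatic
direction resolution for offset and rotation, a standard-model simulation
of the error an *uncorrected* analysis would make, and an exact pinhole
forward projector that generates synthetic ground-truth cases and serves
as the geometric oracle for the closed-form inversion.

## Worked example

Generate a synthetic case with known ground truth — patient rotated 20°
toward the source during the lateral exposure, marker offset 30 mm to the
patient's right — under the exact pinhole forward model, then calibrate:

```r
library(hipcal)
setup <- device_setup(sdd_mm = 1150, marker_radius_mm = 12.5)
case <- project_scene(scene3d(alpha_deg = 20, i_true = 30, i_side = "right",
                              facing = "left",
                              rotation_direction = "toward_source"),
                      setup, fidelity = "full_pinhole")
fit <- hip_calibration(case$ap, case$lateral, setup)
summary(fit)
```

```
Bi-planar hip-plane calibration
  hip-plane calibration factor F_Hip: 123.40
  hip-plane height H_Hip:             218.09 mm
  patient rotation:                   18.49 deg (toward source)

Device: S = 1150 mm, r = 12.5 mm
Raw measurements (mm):
  lateral: a = 198.925  b = 37.937  c = 71.164  d = 142.241
  a.p.:    h = 43.196  i = 42.003  k = 35.023  m = 185.174
Marker solutions:
  a.p.:    H_ECM = 328.445 mm, F_ap = 139.9784 (3 passes)
  lateral: H = 380.807 mm, F_lat = 149.5074 (4 passes)
Calibrated distances (mm):
  d_cal = 95.140  c_cal = 47.599  i_cal = 30.007  m_cal = 150.058
Correction:
  alpha = 18.4939 deg (toward source), offset toward source
  x = 9.518  y = 104.658  y_correction = 110.357 mm
Hip plane: H_Hip = 218.088 mm, F_Hip = 123.4022 (5 outer iterations)
```

The ground truth of the scene is `case$truth$F_Hip = 123.4495`: despite
the severe pose error the corrected estimate is off by 0.05 factor points
(0.04%), of which the residual is the depth-magnification coupling that
the trigonometric correction deliberately ignores (the `trig_model`
fidelity, which embodies exactly the assumed measurement model,
round-trips to the truth at machine-level precision — see the vignette).

The uncorrected error this removes is substantial: for the standard model
(`standard_model()`, reference factor 123.45),

```r
rotation_error(standard_model(), 30, c(0, 20, 60))[, c(1, 2, 5, 6)]
#>   rotation_deg offset_mm absolute_error relative_error
#> 1           30         0       2.214643       1.793966
#> 2           30        20       3.672692       2.975055
#> 3           30        60       6.486048       5.254008
threshold_scan(standard_model(), 1.5)
#>  i0 i20 i60
#>  26  18  10
```

i.e. at 30° rotation with 60 mm offset an uncorrected analysis errs by
6.5 factor points, and the clinically relevant error of 1.5 is reached at
26°/18°/10° rotation for offsets of 0/20/60 mm.

A thin CLI wraps the same functions: `exec/hipcal calibrate|simulate|synth|recover`
(measurement schema documented in `?read_measurements`).

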