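---
title: "Bi-planar calibration of the hip plane: model, corrections and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bi-planar calibration of the hip plane: model, corrections and simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hipcal)
```

## The problem

Digital templating for total hip arthroplasty is performed on an
antero-posterior (a.p.) pelvis radiograph. Because a point-source X-ray
magnifies objects in inverse proportion to their distance from the source,
the template must be scaled by the magnification of the *hip plane* — the
plane parallel to the detector through both hip-joint centres. For a flat
object at height $H$ above the detector and source-detector distance $S$,
the intercept theorem gives the calibration factor as a percentage,

$$F = \frac{100\,S}{S - H},$$

with $F = 100$ meaning life size. The difficulty is that $H_{Hip}$ is not
observable in a single radiograph: a marker ball taped to the patient sits
somewhere near, but not in, the hip plane, and single-marker calibration is
known to be unreliable for exactly that reason.

The bi-planar method implemented here uses **two** approximately orthogonal
radiographs (one a.p., one lateral) with a **single spherical marker** of
known radius $r$ that stays fixed to the patient. The a.p. image yields the
marker's height above the detector, the lateral image yields the marker's
horizontal distance from the hip plane; subtracting the second from the
first gives the hip-plane height and hence its factor.

## Marker height from its projected ellipse

A sphere projects as an ellipse. In the plane spanned by source, sphere
centre and central beam, the two tangent rays delimit the ellipse's long
axis $b$, and the ellipse centre lies a distance $a$ from the image centre.
Inverting that geometry gives the closed-form height

$$H = S - \sqrt{r^2\!\left(1 + \frac{2S^2}{b^2}\right) +
  \frac{2 r S}{b}\sqrt{\frac{r^2 S^2}{b^2} + a^2}}.$$

`marker_height()` evaluates this; on the central beam ($a = 0$) it is the
exact inverse of the tangent-cone projection, off axis it is a close
approximation (quantified below). The measured displacement $a$ is itself a
*projected*, i.e. magnified, length. `marker_height_iterative()` therefore
alternates height computation with recalibration of the displacement,
$a_{n} = a_0\,(S - H_n)/S$, until the marker-plane factor changes by less
than `tol` between passes. The update always starts from the raw measured
$a_0$, so the fixed point solves the self-consistency condition directly.
At least one pass is always performed; with $a = 0$ the pass is the
identity, so the solver agrees with the closed form. The default tolerance
is $10^{-4}$ factor points, far below clinical relevance; convergence is
contractive and takes two to six passes in practice, so `max_iter = 100`
is a formality.

```{r}
setup <- device_setup(sdd_mm = 1150, marker_radius_mm = 12.5)
marker_height_iterative(setup, long_axis = 35, displacement = 10)
```

## From landmarks to measurements

Both images are reduced to scalars by an explicit landmark construction
(`derive_ap()`, `derive_lateral()`), with all coordinates in detector-plane
millimetres and the origin at the central beam:

* a.p. view (x = patient left-right, patient right at negative x by
  default): $h = |OP|$ (direct image-centre-to-marker distance), $i$ its
  horizontal component (the **lateral offset** of a misplaced marker,
  with the patient side it points to), $m$ the horizontal inter-hip
  distance.
* lateral view (x = antero-posterior, +x the direction the patient faces):
  $a = |AB|$, $c$ the horizontal mismatch of the two projected hip centres
  (zero in a perfect lateral), and $d$ the horizontal distance between the
  hip-centre construct (the midpoint construction through the projected
  hip centres) and the marker centre.

## Correcting patient rotation and marker offset

Patient rotation by $\alpha$ during the lateral exposure and lateral marker
offset $i$ both distort the measured $d$. The rotation angle follows from
the calibrated hip-centre mismatch,

$$\alpha = \operatorname{asin}(c_{cal} / m_{cal}),$$

and the corrected marker-to-hip-plane distance is

$$y_{corr} = \frac{d_{cal} \pm \sin(\alpha)\, i_{cal}}{\cos(\alpha)},$$

where the sign is the product of two direction signs (+1 toward the
source, -1 away) for the offset and the rotation. Finally

$$H_{Hip} = H_{ECM} - y_{corr}, \qquad
  F_{Hip} = \frac{100\,S}{S - H_{Hip}}.$$

Two direction resolutions are needed and neither is a measured number:

* **Offset direction.** Whether the a.p. offset points toward or away from
  the lateral source depends on the offset side and on which way the
  patient faces; the mapping is the standard side/facing table
  (`offset_direction_lateral()`): offset toward the patient's right is
  toward the source exactly when the patient faces left (source at the
  patient's right).
* **Rotation direction.** The magnitudes $c$ and $m$ cannot distinguish
  rotation toward from rotation away from the source. The method's inputs
  do contain the information, though: rotation toward the source brings
  the hip on the side the patient faces forward in the image. We therefore
  infer the direction from which hip projects anteriorly combined with
  `facing`, and expose `rotation_direction =` as an explicit override for
  cases where the operator knows the pose. At $\alpha = 0$ (perfect
  overlay) the direction is undefined and inert; it is set to
  `toward_source` and a note is recorded on the fit.

### Calibration planes for the derived distances

Each measured distance must be divided by the factor of the plane it lives
in, and only the marker is directly calibrated. The package uses:

* $d$ and $c$ — the lateral marker factor $F_{lat}$ (the marker is the only
  calibrated object in the lateral view; the hip depth there is unknown);
* $h$, $i$ — the a.p. marker factor $F_{ap}$;
* $m$ — lies in the hip plane, whose factor is the quantity being solved
  for. `hip_calibration()` therefore wraps an outer fixed point around the
  correction: initialise with $F_{ap}$, calibrate $m$, re-derive $\alpha$
  and $F_{Hip}$, and iterate to the same $10^{-4}$ tolerance. This mirrors
  the inner displacement recalibration and converges in a handful of
  passes.

Calibrating $c$ at the marker plane is an assumption (the true hip depth in
the lateral view is unknowable from these inputs); it is also exactly what
the round-trip measurement model assumes, so it introduces no error there,
and under the full pinhole model its effect is part of the reported
residual.

## The standard-model error simulation

To quantify what the correction buys, `standard_model()` fixes a set of
empirically plausible measurements ($S = 1150$, $r = 12.5$, $k = 35$,
$h = 10$, $d = 110$, $m = 150$ mm). `reference_factor()` computes the
zero-error hip-plane factor (123.45 for these settings). For rotation
$\alpha$ and offset $i$, both toward the source, the true distance behind a
measured $d$ is $y_{rot} = (d + i \sin\alpha)/\cos\alpha$, so an
uncorrected analysis errs by $F_{ref} - F_{rot}$ (absolute, factor points)
and $100\,(F_{ref} - F_{rot})/F_{ref}$ (relative, percent). In this recipe
$d = 110$ is treated as the true calibrated marker-to-hip distance; the
lateral-view quantities $a$, $b$ play no role, and $c$ is always simulated
as $m \sin\alpha$, never an input. `error_table()` evaluates the grid of
rotations 0-30 degrees by offsets 0/20/60 mm, `format_error_table()`
renders it at the report precision (absolute errors 3 decimals, relative
1 decimal, rounded half-up — base `round()`'s half-even rule would differ
on several cells), and `threshold_scan()` locates the first rotation whose
unrounded error reaches a threshold. Note the scan uses unrounded errors:
with a 1.0 threshold and 20 mm offset the first grid row at or above the
threshold is 14 degrees (row 13 reaches only 0.987).

```{r}
m <- standard_model()
rotation_error(m, 30, c(0, 20, 60))
threshold_scan(m, 1.5)
```

`correct_rotation()` applied with the true pose inverts this simulated
error exactly — the simulation and the correction are the same
trigonometry traversed in opposite directions, and a cross-module test
verifies the two agree to $10^{-6}$ when both are run at a tightened
tolerance ($10^{-10}$; at the default $10^{-4}$ the agreement is limited
by the iteration residual itself).

## The synthetic-data generator

`scene3d()` + `project_scene()` build ground-truth 3D scenes (hip centres,
marker position, pose) and project them into paired landmark sets, with
two fidelities:

* **`trig_model`** — the trigonometric measurement model the correction
  assumes: one magnification per view (marker plane laterally, marker/hip
  planes in a.p.), rotated marker-to-hip projection
  $d\cos\alpha \mp i\sin\alpha$, and marker ellipse axes generated by
  numerically inverting the closed-form height equation (`uniroot` on the
  long axis, so the iterative solver recovers the true height exactly).
  Under this fidelity the corrected pipeline must round-trip to the truth
  up to its convergence tolerances; the suite checks a maximum relative
  error below 0.1% over 100 seeded cases with rotations up to 30 degrees
  and offsets up to 60 mm.
* **`full_pinhole`** — exact per-point pinhole projection with
  depth-dependent magnification and exact tangent-cone marker shadows
  (`project_sphere()`). This deliberately breaks the idealisations of the
  trigonometric model (the depth-magnification coupling of $d$ and $c$,
  the ellipse-centre vs point-projection distinction), so residual
  recovery errors under rotation are *reported*, not asserted; at zero
  rotation recovery is still required to be better than 0.1%.

`project_sphere()` doubles as the independent geometric oracle for the
closed-form inversion: over marker heights 100-500 mm and radial positions
0-200 mm the iterative solver recovers exact-projection heights to within
0.5 mm (the closed form is exact only on the central beam; whether it is
the exact off-axis inverse is not claimed, hence a tolerance target rather
than an identity).

Scene defaults emulate a typical standing pelvis pair and reproduce
measured values close to the standard model (inter-hip distance 150 mm,
marker 110 mm anterior of the hip plane and 95 mm below hip-centre height,
hip plane 218.445 mm above the a.p. detector, inter-hip midpoint 315 mm
above the lateral detector, a.p. beam centred 7.2 mm from the marker:
together these give $h \approx 10$, $a \approx 200$ and ellipse axes near
35 mm). The random generator draws uniformly from ranges around those
values (rotation 0-30 degrees, offset 0-60 mm, inter-hip 135-165 mm,
marker distance 80-140 mm, hip height 170-270 mm) with side, facing and
rotation direction drawn uniformly; every case carries its integer seed
and regenerates bit-identically. The rotation pivot defaults to the
inter-hip midpoint and may be set to the marker; in the pinhole model the
pivot matters because the central beam stays where the radiographer aimed
it, while the trigonometric model is pivot-invariant by construction.

What the generator does **not** emulate: landmark identification noise,
ellipse-fitting error, detector tilt, finite focal spots, scatter, and
anatomy that violates the symmetric two-hip-centre model. Passing
round-trip tests therefore demonstrates that the algebra inverts its own
measurement model and that the exact-geometry residuals are small — not
that clinical measurements of real radiographs reach that precision.

## Numerical choices and degenerate inputs

* Angles are degrees at every interface and radians internally; lengths mm;
  factors percent.
* Convergence is always tested on calibration factors (tolerance $10^{-4}$
  by default, every solver takes `tol`); non-convergence raises an error
  carrying the last iterate.
* Degenerate perfect lateral ($c = 0$): $\alpha = 0$, the rotation
  direction is inert and noted on the fit. A marker on the central beam
  ($i = 0$): offset direction likewise inert and noted.
* Coincident hip landmarks in the a.p. view ($m = 0$) are rejected as
  degenerate anatomy; a calibrated $c$ exceeding the calibrated $m$ is
  rejected as gross mis-landmarking; a computed hip plane outside
  $[0, S)$ is rejected as inconsistent geometry.
* Problem sizes: the whole suite runs deterministic closed-form geometry;
  the heaviest checks are the 100-case round-trip batch and the
  31 x 3 error grid, a few seconds in total.

## Limitations

The correction addresses exactly two use errors — patient rotation in the
lateral view and lateral marker offset — under the assumption that the
remaining geometry is ideal. The full-pinhole fidelity quantifies the
first-order idealisation (depth-magnification coupling): residuals grow
with rotation and offset but stay within a few tenths of a percent for
clinically plausible poses, and vanish at zero rotation. Anything pixel- or
image-related (landmark detection, DICOM handling, templating overlays) is
out of scope; the package starts from landmark coordinates in millimetres.
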