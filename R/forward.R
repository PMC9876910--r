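#' Exact pinhole projection of the spherical marker
#'
#' Tangent-cone geometry: in the plane containing the source, the sphere
#' centre and the central beam, the two rays tangent to the sphere hit the
#' detector at the ends of the projected ellipse's long axis. Returns that
#' long axis and the displacement of its midpoint from the central beam --
#' the two quantities an observer measures on the radiograph. Serves as
#' the independent geometric oracle for the closed-form height inversion.
#'
#' @param setup A [device_setup()].
#' @param height_mm Height of the sphere centre above the detector plane,
#'   mm (`>= 0`; the sphere must stay clear of the source).
#' @param radial_mm In-plane distance of the sphere centre from the
#'   central beam axis, mm (`>= 0`).
#' @return List with `long_axis` and `displacement`, both mm.
#' @examples
#' setup <- device_setup(1150, 12.5)
#' project_sphere(setup, height_mm = 328.48, radial_mm = 0)
#' @export
project_sphere <- function(setup, height_mm, radial_mm = 0) {
  setup <- as_device_setup(setup)
  S <- setup$sdd_mm
  r <- setup$marker_radius_mm
  check_scalar(height_mm, "height_mm", lower = 0)
  check_scalar(radial_mm, "radial_mm", lower = 0)
  if (height_mm + r >= S)
    stop("sphere intersects the source plane (height ", height_mm,
         " + r ", r, " >= S ", S, ")")
  D <- sqrt(radial_mm^2 + (S - height_mm)^2)
  if (D <= r)
    stop("sphere encloses the X-ray source")
  phi <- atan2(radial_mm, S - height_mm)
  th <- asin(r / D)
  if (phi + th >= pi / 2)
    stop("tangent ray parallel to the detector: the sphere shadow does ",
         "not close on the image")
  x1 <- S * tan(phi - th)
  x2 <- S * tan(phi + th)
  list(long_axis = x2 - x1, displacement = (x1 + x2) / 2)
}

# long axis consistent with the measurement model: the axis for which the
# closed-form height equation, evaluated at the *calibrated* displacement
# (the true radial position), returns exactly `height_mm`
solve_long_axis <- function(setup, height_mm, radial_true_mm) {
  S <- setup$sdd_mm
  r <- setup$marker_radius_mm
  if (height_mm <= 0 || height_mm >= S - r)
    stop("marker height must lie in (0, S - r) for the measurement model")
  f <- function(ax) height_formula(S, r, ax, radial_true_mm) - height_mm
  stats::uniroot(f, lower = 2 * r * (1 + 1e-12), upper = 1e3 * S,
                 tol = 1e-12)$root
}

#' Ground-truth 3D scene for the forward simulator
#'
#' Describes patient anatomy and pose in a patient-centred frame: hip
#' centres separated by `m_true` on the left-right axis, the marker
#' `d_true` mm anterior of the hip plane, offset `i_true` mm toward one
#' side and `marker_drop` mm below hip-centre height. The pose is a
#' rotation of `alpha_deg` about the vertical axis during the lateral
#' exposure (the a.p. exposure is taken unrotated); `facing` fixes which
#' patient side is toward the lateral source. Heights place the anatomy
#' between detector and source per view: the hip plane `hip_height_ap` mm
#' above the a.p. detector and the (unrotated) inter-hip midpoint
#' `hip_height_lat` mm above the lateral detector. `ap_beam_offset` is the
#' vertical distance between the marker centre and the a.p. central beam
#' (the beam is centred near the marker at the pubic symphysis).
#'
#' Defaults emulate a typical standing pelvis pair: they reproduce
#' measured values of about `m = 150`, `d = 110`, `h = 10`, `a = 200` and
#' marker ellipse axes of about 35 mm under the default device.
#'
#' The rotation pivot defaults to the inter-hip midpoint; with
#' `pivot = "marker"` the patient rotates about the marker instead, which
#' shifts the hips relative to the (fixed) central beam in the full
#' pinhole fidelity.
#'
#' @param m_true Inter-hip distance, mm (`> 0`).
#' @param d_true Marker anterior distance from the hip plane, mm (`> 0`).
#' @param i_true Marker lateral offset magnitude, mm (`>= 0`).
#' @param i_side Side the marker is offset toward.
#' @param alpha_deg Patient rotation during the lateral exposure, degrees.
#' @param rotation_direction Rotation toward or away from the source.
#' @param facing Direction the patient faces relative to the lateral
#'   source.
#' @param hip_height_ap,hip_height_lat Heights above the respective
#'   detectors, mm.
#' @param marker_drop Vertical drop of the marker below hip-centre height,
#'   mm.
#' @param ap_beam_offset Vertical marker-to-beam distance in the a.p.
#'   view, mm.
#' @param pivot Rotation pivot.
#' @return Object of class `"scene3d"`.
#' @examples
#' scene3d(alpha_deg = 20, i_true = 30)
#' @export
scene3d <- function(m_true = 150, d_true = 110, i_true = 0,
                    i_side = c("right", "left"), alpha_deg = 0,
                    rotation_direction = c("toward_source",
                                           "away_from_source"),
                    facing = c("left", "right"),
                    hip_height_ap = 218.445, hip_height_lat = 315,
                    marker_drop = 95, ap_beam_offset = 7.2,
                    pivot = c("hip_midpoint", "marker")) {
  i_side <- match.arg(i_side)
  rotation_direction <- match.arg(rotation_direction)
  facing <- match.arg(facing)
  pivot <- match.arg(pivot)
  check_scalar(m_true, "m_true", lower = 0, strict_lower = TRUE)
  check_scalar(d_true, "d_true", lower = 0, strict_lower = TRUE)
  check_scalar(i_true, "i_true", lower = 0)
  check_scalar(alpha_deg, "alpha_deg", lower = 0, upper = 90,
               strict_upper = TRUE)
  check_scalar(hip_height_ap, "hip_height_ap", lower = 0, strict_lower = TRUE)
  check_scalar(hip_height_lat, "hip_height_lat", lower = 0,
               strict_lower = TRUE)
  check_scalar(marker_drop, "marker_drop", lower = 0)
  check_scalar(ap_beam_offset, "ap_beam_offset", lower = 0)
  structure(list(m_true = m_true, d_true = d_true, i_true = i_true,
                 i_side = i_side, alpha_deg = alpha_deg,
                 rotation_direction = rotation_direction, facing = facing,
                 hip_height_ap = hip_height_ap,
                 hip_height_lat = hip_height_lat,
                 marker_drop = marker_drop, ap_beam_offset = ap_beam_offset,
                 pivot = pivot),
            class = "scene3d")
}

#' @export
print.scene3d <- function(x, ...) {
  cat("3D scene: m =", x$m_true, " d =", x$d_true, " i =", x$i_true,
      paste0("(", x$i_side, ")"), " alpha =", x$alpha_deg, "deg",
      gsub("_", " ", x$rotation_direction), "\n")
  cat("  facing", x$facing, "; heights a.p./lat:", x$hip_height_ap, "/",
      x$hip_height_lat, "mm; pivot", x$pivot, "\n")
  invisible(x)
}

#' Project a 3D scene into paired landmark sets
#'
#' Produces the a.p. and lateral landmark sets an observer would measure
#' on the radiographs of a [scene3d()], together with the ground truth,
#' under one of two forward models:
#'
#' * `"trig_model"` -- the trigonometric measurement model the correction
#'   algorithm assumes: in-image distances are true lengths scaled by a
#'   single per-view magnification (marker plane for the lateral view and
#'   the marker/hip planes in the a.p. view), the rotated marker-to-hip
#'   distance is `d cos(alpha) -/+ i sin(alpha)`, and marker ellipse axes
#'   are generated by numerically inverting the closed-form height
#'   equation. The calibration pipeline inverts this model exactly (up to
#'   its convergence tolerances), which makes it the round-trip oracle.
#' * `"full_pinhole"` -- exact per-point pinhole projection with
#'   depth-dependent magnification and tangent-cone marker projection
#'   ([project_sphere()]). This quantifies the idealisations of the
#'   trigonometric model instead of hiding them; residual recovery errors
#'   under this fidelity are reported, not asserted against theory.
#'
#' @param scene A [scene3d()].
#' @param setup A [device_setup()].
#' @param fidelity Forward model, see above.
#' @return Object of class `"synthetic_case"`: list with `scene`, `setup`,
#'   `fidelity`, `ap` ([ap_landmarks()]), `lateral`
#'   ([lateral_landmarks()]) and `truth` (list with `H_Hip`, `F_Hip`,
#'   `H_ECM`, `alpha_deg`, `rotation_direction`, `i`, `d`, `m`).
#' @examples
#' case <- project_scene(scene3d(alpha_deg = 10, i_true = 20), device_setup())
#' hip_calibration(case$ap, case$lateral, case$setup)
#' @export
project_scene <- function(scene, setup = device_setup(),
                          fidelity = c("trig_model", "full_pinhole")) {
  stopifnot(inherits(scene, "scene3d"))
  setup <- as_device_setup(setup)
  fidelity <- match.arg(fidelity)
  S <- setup$sdd_mm
  r <- setup$marker_radius_mm

  s_face <- if (scene$facing == "left") 1 else -1   # patient right toward source?
  s_side <- if (scene$i_side == "right") 1 else -1
  s_rot <- if (scene$rotation_direction == "toward_source") 1 else -1
  s_off <- s_side * s_face                           # offset toward source sign
  psi <- s_rot * scene$alpha_deg * pi / 180
  m2 <- scene$m_true / 2

  H_ECM_true <- scene$hip_height_ap + scene$d_true
  if (H_ECM_true >= S - r)
    stop("impossible geometry: marker height above the a.p. detector (",
         H_ECM_true, " mm) reaches the source")
  F_hip_true <- factor_from_height(S, scene$hip_height_ap)
  F_ap_true <- factor_from_height(S, H_ECM_true)

  # lateral lab frame, origin on the central beam at the unrotated inter-hip
  # midpoint: e1 = anterior image axis, e2 = vertical, e3 = toward source
  # (height above lateral detector = hip_height_lat + e3)
  rot2 <- function(v1, v3) c(v1 * cos(psi) - v3 * sin(psi),
                             v1 * sin(psi) + v3 * cos(psi))
  pts0 <- list(hip_mid = c(0, 0, 0),
               right_hip = c(0, 0, s_face * m2),
               left_hip = c(0, 0, -s_face * m2),
               marker = c(scene$d_true, -scene$marker_drop, s_off * scene$i_true))
  piv <- if (scene$pivot == "hip_midpoint") pts0$hip_mid else pts0$marker
  pts <- lapply(pts0, function(p) {
    v <- rot2(p[1] - piv[1], p[3] - piv[3])
    c(piv[1] + v[1], p[2], piv[3] + v[2])
  })
  z_lat <- function(p) scene$hip_height_lat + p[3]
  if (z_lat(pts$marker) <= 0 || z_lat(pts$marker) >= S - r)
    stop("impossible geometry: marker height above the lateral detector is ",
         signif(z_lat(pts$marker), 6), " mm")

  if (fidelity == "trig_model") {
    # single-magnification measurement model; the marker plane calibrates
    # the whole lateral image, marker/hip planes calibrate the a.p. image
    F_lat_true <- factor_from_height(S, z_lat(pts$marker))
    d_proj <- pts$marker[1] - pts$hip_mid[1]    # = d cos(a) -/+ i sin(a)
    if (d_proj < 0)
      stop("impossible geometry for the measurement model: the rotated ",
           "marker projects posterior of the hip-centre construct")
    radial_lat <- sqrt(d_proj^2 + scene$marker_drop^2)
    b <- solve_long_axis(setup, z_lat(pts$marker), radial_lat)
    B <- c(d_proj, -scene$marker_drop) * F_lat_true / 100
    C <- c((pts$right_hip[1] - pts$hip_mid[1]) * F_lat_true / 100, 0)
    D <- c((pts$left_hip[1] - pts$hip_mid[1]) * F_lat_true / 100, 0)

    radial_ap <- sqrt(scene$i_true^2 + scene$ap_beam_offset^2)
    k <- solve_long_axis(setup, H_ECM_true, radial_ap)
    P <- c(-s_side * scene$i_true, -scene$ap_beam_offset) * F_ap_true / 100
    y_hip_ap <- (scene$marker_drop - scene$ap_beam_offset) * F_hip_true / 100
    Q <- c(-m2 * F_hip_true / 100, y_hip_ap)
    R <- c(m2 * F_hip_true / 100, y_hip_ap)
  } else {
    proj_point <- function(inplane, z) inplane * S / (S - z)
    # lateral view
    mk <- pts$marker
    mk_inplane <- c(mk[1], mk[2])
    radial <- sqrt(sum(mk_inplane^2))
    sph <- project_sphere(setup, z_lat(mk), radial)
    u <- if (radial > 0) mk_inplane / radial else c(1, 0)
    B <- sph$displacement * u
    b <- sph$long_axis
    C <- proj_point(c(pts$right_hip[1], pts$right_hip[2]),
                    z_lat(pts$right_hip))
    D <- proj_point(c(pts$left_hip[1], pts$left_hip[2]),
                    z_lat(pts$left_hip))
    # a.p. view (unrotated patient; x = patient left-right, right negative)
    mk_ap <- c(-s_side * scene$i_true, -scene$ap_beam_offset)
    radial_ap <- sqrt(sum(mk_ap^2))
    sph_ap <- project_sphere(setup, H_ECM_true, radial_ap)
    u_ap <- if (radial_ap > 0) mk_ap / radial_ap else c(1, 0)
    P <- sph_ap$displacement * u_ap
    k <- sph_ap$long_axis
    y_hip <- scene$marker_drop - scene$ap_beam_offset
    Q <- proj_point(c(-m2, y_hip), scene$hip_height_ap)
    R <- proj_point(c(m2, y_hip), scene$hip_height_ap)
  }

  structure(list(
    scene = scene, setup = setup, fidelity = fidelity,
    ap = ap_landmarks(c(0, 0), P, Q, R, marker_long_axis_mm = k),
    lateral = lateral_landmarks(c(0, 0), B, C, D, marker_long_axis_mm = b,
                                facing = scene$facing),
    truth = list(H_Hip = scene$hip_height_ap, F_Hip = F_hip_true,
                 H_ECM = H_ECM_true, alpha_deg = scene$alpha_deg,
                 rotation_direction = scene$rotation_direction,
                 i = scene$i_true, d = scene$d_true, m = scene$m_true)
  ), class = "synthetic_case")
}

#' @export
print.synthetic_case <- function(x, ...) {
  cat("Synthetic case (", x$fidelity, ")\n", sep = "")
  cat(sprintf("  truth: F_Hip = %.4f  H_Hip = %.3f mm  alpha = %.2f deg  i = %.1f mm\n",
              x$truth$F_Hip, x$truth$H_Hip, x$truth$alpha_deg, x$truth$i))
  if (!is.null(x$seed)) cat("  seed:", x$seed, "\n")
  invisible(x)
}

#' Generate a random synthetic case
#'
#' Draws a plausible anatomy/pose uniformly from the given ranges (seeded,
#' hence reproducible bit-for-bit), builds the [scene3d()] and projects it
#' with [project_scene()]. Side, facing and rotation direction are drawn
#' uniformly from their levels.
#'
#' @param seed Integer seed; identical seeds yield identical cases. The
#'   caller's RNG state is left untouched.
#' @param setup A [device_setup()].
#' @param fidelity Forward model passed to [project_scene()].
#' @param alpha_range,offset_range,m_range,d_range Ranges (min, max) for
#'   rotation (degrees), lateral offset, inter-hip distance and marker
#'   anterior distance (mm).
#' @param hip_height_range,lat_height_range,drop_range,ap_beam_offset_range
#'   Ranges (mm) for hip-plane height above the a.p. detector, inter-hip
#'   midpoint height above the lateral detector, marker vertical drop and
#'   a.p. beam-to-marker vertical distance.
#' @param pivot Rotation pivot for the scene.
#' @return A `"synthetic_case"` with the seed recorded in `$seed`.
#' @examples
#' case <- generate_case(seed = 1)
#' hip_calibration(case$ap, case$lateral, case$setup)$F_Hip - case$truth$F_Hip
#' @export
generate_case <- function(seed, setup = device_setup(),
                          fidelity = c("trig_model", "full_pinhole"),
                          alpha_range = c(0, 30), offset_range = c(0, 60),
                          m_range = c(135, 165), d_range = c(80, 140),
                          hip_height_range = c(170, 270),
                          lat_height_range = c(270, 360),
                          drop_range = c(60, 120),
                          ap_beam_offset_range = c(0, 15),
                          pivot = "hip_midpoint") {
  check_scalar(seed, "seed")
  fidelity <- match.arg(fidelity)
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  u <- function(range) stats::runif(1, range[1], range[2])
  scene <- scene3d(
    m_true = u(m_range), d_true = u(d_range), i_true = u(offset_range),
    i_side = sample(c("right", "left"), 1),
    alpha_deg = u(alpha_range),
    rotation_direction = sample(c("toward_source", "away_from_source"), 1),
    facing = sample(c("left", "right"), 1),
    hip_height_ap = u(hip_height_range),
    hip_height_lat = u(lat_height_range),
    marker_drop = u(drop_range),
    ap_beam_offset = u(ap_beam_offset_range),
    pivot = pivot)
  case <- project_scene(scene, setup, fidelity)
  case$seed <- seed
  case
}

#' @rdname generate_case
#' @param n Number of cases; seeds are `seed, seed + 1, ..., seed + n - 1`.
#' @export
generate_cases <- function(n, seed, ...) {
  stopifnot(n >= 1)
  lapply(seq_len(n), function(j) generate_case(seed + j - 1L, ...))
}

#' Parameter-recovery report over synthetic cases
#'
#' Runs the calibration pipeline on each synthetic case and compares the
#' recovered hip-plane factor with the ground truth of the generating
#' scene.
#'
#' @param cases A list of `"synthetic_case"` objects (or a single case).
#' @param apply_correction Passed to [hip_calibration()]; `FALSE` measures
#'   the naive uncorrected method.
#' @param tol Convergence tolerance passed to [hip_calibration()].
#' @param file Optional path; if given the per-case table is written as
#'   CSV.
#' @return A `data.frame` of class `"recovery_report"`, one row per case
#'   (`seed`, `fidelity`, `alpha_true`, `i_true`, `F_Hip_true`,
#'   `F_Hip_est`, `abs_error` in factor points, `rel_error_pct`).
#'   `summary()` prints bias and maximum absolute relative error per
#'   fidelity.
#' @examples
#' rep <- recovery_report(generate_cases(5, seed = 42))
#' summary(rep)
#' @export
recovery_report <- function(cases, apply_correction = TRUE, tol = 1e-4,
                            file = NULL) {
  if (inherits(cases, "synthetic_case")) cases <- list(cases)
  stopifnot(length(cases) >= 1)
  rows <- lapply(cases, function(case) {
    fit <- hip_calibration(case$ap, case$lateral, case$setup, tol = tol,
                           apply_correction = apply_correction)
    data.frame(seed = if (is.null(case$seed)) NA_real_ else case$seed,
               fidelity = case$fidelity,
               alpha_true = case$truth$alpha_deg,
               i_true = case$truth$i,
               F_Hip_true = case$truth$F_Hip,
               F_Hip_est = fit$F_Hip,
               abs_error = fit$F_Hip - case$truth$F_Hip,
               rel_error_pct = 100 * (fit$F_Hip - case$truth$F_Hip) /
                 case$truth$F_Hip)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("recovery_report", "data.frame")
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}

#' @export
summary.recovery_report <- function(object, ...) {
  for (fid in unique(object$fidelity)) {
    sub <- object[object$fidelity == fid, ]
    cat(sprintf("%s: n = %d, bias = %+.5f factor points, max |rel| = %.5f%%\n",
                fid, nrow(sub), mean(sub$abs_error),
                max(abs(sub$rel_error_pct))))
  }
  invisible(object)
}
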