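#' Bi-planar hip-plane calibration
#'
#' Computes the patient-individual calibration factor of the hip plane
#' (`F_Hip`) from one antero-posterior and one lateral radiograph carrying
#' a single spherical calibration marker. This is the main function of the
#' package; everything else feeds it or checks it.
#'
#' The workflow:
#' 1. Reduce both landmark sets to scalar measurements
#'    ([derive_ap()], [derive_lateral()]).
#' 2. Solve the marker height in each view with displacement
#'    recalibration ([marker_height_iterative()]); the a.p. solution is
#'    the marker height above the detector `H_ECM`, each solution also
#'    yields the marker-plane factor of its view (`F_ap`, `F_lat`).
#' 3. Calibrate the projected distances: `d` and `c` with the lateral
#'    marker factor (the marker is the only calibrated object in that
#'    view), `i` with the a.p. marker factor, and `m` with the hip-plane
#'    factor itself via an outer fixed point initialised at `F_ap`.
#' 4. Estimate the patient rotation `alpha = asin(c_cal / m_cal)` and its
#'    direction, resolve the offset direction, and correct the
#'    marker-to-hip-plane distance
#'    (`y_correction = (d_cal +/- sin(alpha) i_cal) / cos(alpha)`).
#' 5. `H_Hip = H_ECM - y_correction` and
#'    `F_Hip = 100 S / (S - H_Hip)`.
#'
#' @param ap An [ap_landmarks()] object.
#' @param lateral A [lateral_landmarks()] object.
#' @param setup A [device_setup()] object (same marker in both views).
#' @param tol Convergence tolerance on calibration factors, both for the
#'   per-view marker solvers and the outer hip-plane fixed point.
#' @param max_iter Iteration cap for each fixed point.
#' @param rotation_direction `"auto"` (infer from the landmarks, the
#'   default) or an explicit override `"toward_source"` /
#'   `"away_from_source"`.
#' @param apply_correction If `FALSE` the rotation/offset correction is
#'   skipped and `y_correction = d_cal` (the naive uncorrected method);
#'   used to quantify the error the correction removes.
#' @return An object of class `"hip_calibration"` with `print`, `summary`,
#'   `coef` and `as.data.frame` methods.
#'   Key elements: `F_Hip`, `H_Hip`, `H_ECM`, `alpha_deg`, `y_correction`,
#'   per-view solutions `solution_ap` / `solution_lat`, calibrated
#'   measurements, iteration diagnostics and `notes`.
#' @examples
#' setup <- device_setup(1150, 12.5)
#' ap <- ap_landmarks(c(0, 0), c(0, 10.004), c(-92.6, 109.8), c(92.6, 109.8),
#'                    marker_long_axis_mm = 35)
#' lat <- lateral_landmarks(c(0, 0), c(151.5, -130.8), c(0, 0), c(0, 0),
#'                          marker_long_axis_mm = 35, facing = "left")
#' fit <- hip_calibration(ap, lat, setup)
#' fit
#' @export
hip_calibration <- function(ap, lateral, setup = device_setup(),
                            tol = 1e-4, max_iter = 100L,
                            rotation_direction = c("auto", "toward_source",
                                                   "away_from_source"),
                            apply_correction = TRUE) {
  rotation_direction <- match.arg(rotation_direction)
  setup <- as_device_setup(setup)
  S <- setup$sdd_mm
  notes <- character()

  m_lat <- derive_lateral(lateral)
  m_ap <- derive_ap(ap)

  sol_lat <- marker_height_iterative(setup, m_lat$b, m_lat$a, tol = tol,
                                     max_iter = max_iter, view = "lateral")
  sol_ap <- marker_height_iterative(setup, m_ap$k, m_ap$h, tol = tol,
                                    max_iter = max_iter,
                                    view = "antero-posterior")
  H_ECM <- sol_ap$height_H
  F_lat <- sol_lat$factor_percent
  F_ap <- sol_ap$factor_percent

  d_cal <- m_lat$d / (F_lat / 100)
  c_cal <- m_lat$c / (F_lat / 100)
  i_cal <- m_ap$i / (F_ap / 100)

  offset_dir <- if (m_ap$offset_side == "none") {
    notes <- c(notes, "marker on the central beam (i = 0): offset direction undefined, set toward_source (inert)")
    "toward_source"
  } else {
    offset_direction_lateral(m_ap$offset_side, m_lat$facing)
  }

  # outer fixed point: m lies in the hip plane, so its calibration factor
  # is the quantity being solved for
  F_hip <- F_ap
  outer_n <- 0L
  repeat {
    m_cal <- m_ap$m / (F_hip / 100)
    rot <- estimate_rotation(c_cal, m_cal, m_lat$anterior_hip, m_lat$facing)
    rot_dir <- if (rotation_direction == "auto") rot$direction else rotation_direction
    corr <- if (apply_correction) {
      correct_rotation(d_cal, i_cal, rot$alpha_deg, offset_dir, rot_dir)
    } else {
      list(x = 0, y = d_cal, y_correction = d_cal)
    }
    H_Hip <- H_ECM - corr$y_correction
    if (H_Hip < 0 || H_Hip >= S)
      stop("inconsistent geometry: computed hip-plane height (",
           signif(H_Hip, 6), " mm) outside [0, S); check the measurements")
    F_new <- factor_from_height(S, H_Hip)
    outer_n <- outer_n + 1L
    if (abs(F_new - F_hip) < tol || outer_n >= max_iter) {
      not_conv <- abs(F_new - F_hip) >= tol
      F_hip <- F_new
      if (not_conv)
        stop("hip-plane factor fixed point did not converge within ",
             max_iter, " iterations")
      break
    }
    F_hip <- F_new
  }
  if (m_lat$anterior_hip == "none")
    notes <- c(notes, "perfect hip overlay (c = 0): rotation direction undefined, set toward_source (inert)")

  structure(list(
    setup = setup,
    measurements = list(ap = m_ap, lateral = m_lat),
    solution_ap = sol_ap,
    solution_lat = sol_lat,
    H_ECM = H_ECM,
    F_ap = F_ap,
    F_lat = F_lat,
    d_cal = d_cal, c_cal = c_cal, i_cal = i_cal, m_cal = m_cal,
    alpha_deg = rot$alpha_deg,
    rotation_direction = rot_dir,
    offset_direction = offset_dir,
    x = corr$x, y = corr$y, y_correction = corr$y_correction,
    H_Hip = H_Hip,
    F_Hip = F_hip,
    outer_iterations = outer_n,
    apply_correction = apply_correction,
    notes = notes
  ), class = "hip_calibration")
}

#' @export
print.hip_calibration <- function(x, digits = 4, ...) {
  cat("Bi-planar hip-plane calibration\n")
  cat(sprintf("  hip-plane calibration factor F_Hip: %.*f\n", 2, x$F_Hip))
  cat(sprintf("  hip-plane height H_Hip:             %.*f mm\n", digits - 2, x$H_Hip))
  cat(sprintf("  patient rotation:                   %.*f deg (%s)\n",
              digits - 2, x$alpha_deg, gsub("_", " ", x$rotation_direction)))
  if (!x$apply_correction)
    cat("  (rotation/offset correction disabled)\n")
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' Detailed summary of a hip-plane calibration
#'
#' @param object A `"hip_calibration"` fit.
#' @param ... Unused.
#' @return The fit, invisibly; prints all intermediate quantities
#'   (raw and calibrated measurements, per-view marker solutions,
#'   rotation/offset correction, iteration counts).
#' @export
summary.hip_calibration <- function(object, ...) {
  x <- object
  print(x)
  cat("\nDevice: S =", x$setup$sdd_mm, "mm, r =", x$setup$marker_radius_mm, "mm\n")
  cat("Raw measurements (mm):\n")
  cat(sprintf("  lateral: a = %.3f  b = %.3f  c = %.3f  d = %.3f\n",
              x$measurements$lateral$a, x$measurements$lateral$b,
              x$measurements$lateral$c, x$measurements$lateral$d))
  cat(sprintf("  a.p.:    h = %.3f  i = %.3f  k = %.3f  m = %.3f\n",
              x$measurements$ap$h, x$measurements$ap$i,
              x$measurements$ap$k, x$measurements$ap$m))
  cat("Marker solutions:\n")
  cat(sprintf("  a.p.:    H_ECM = %.3f mm, F_ap = %.4f (%d passes)\n",
              x$H_ECM, x$F_ap, x$solution_ap$n_iterations))
  cat(sprintf("  lateral: H = %.3f mm, F_lat = %.4f (%d passes)\n",
              x$solution_lat$height_H, x$F_lat, x$solution_lat$n_iterations))
  cat("Calibrated distances (mm):\n")
  cat(sprintf("  d_cal = %.3f  c_cal = %.3f  i_cal = %.3f  m_cal = %.3f\n",
              x$d_cal, x$c_cal, x$i_cal, x$m_cal))
  cat("Correction:\n")
  cat(sprintf("  alpha = %.4f deg (%s), offset %s\n", x$alpha_deg,
              gsub("_", " ", x$rotation_direction),
              gsub("_", " ", x$offset_direction)))
  cat(sprintf("  x = %.3f  y = %.3f  y_correction = %.3f mm\n",
              x$x, x$y, x$y_correction))
  cat(sprintf("Hip plane: H_Hip = %.3f mm, F_Hip = %.4f (%d outer iterations)\n",
              x$H_Hip, x$F_Hip, x$outer_iterations))
  invisible(x)
}

#' @export
coef.hip_calibration <- function(object, ...) {
  c(F_Hip = object$F_Hip, F_ap = object$F_ap, F_lat = object$F_lat)
}

#' One-row data frame of all calibration quantities
#'
#' @param x A `"hip_calibration"` fit.
#' @param row.names,optional,... Passed for S3 compatibility; unused.
#' @return A one-row `data.frame` with raw measurements, intermediate and
#'   final quantities, suitable for tabulating batches of cases.
#' @export
as.data.frame.hip_calibration <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  data.frame(
    a = x$measurements$lateral$a, b = x$measurements$lateral$b,
    c = x$measurements$lateral$c, d = x$measurements$lateral$d,
    h = x$measurements$ap$h, i = x$measurements$ap$i,
    k = x$measurements$ap$k, m = x$measurements$ap$m,
    H_ECM = x$H_ECM, F_ap = x$F_ap, F_lat = x$F_lat,
    d_cal = x$d_cal, c_cal = x$c_cal, i_cal = x$i_cal, m_cal = x$m_cal,
    alpha_deg = x$alpha_deg,
    rotation_direction = x$rotation_direction,
    offset_direction = x$offset_direction,
    x = x$x, y_correction = x$y_correction,
    H_Hip = x$H_Hip, F_Hip = x$F_Hip,
    n_iter_ap = x$solution_ap$n_iterations,
    n_iter_lat = x$solution_lat$n_iterations,
    n_iter_hip = x$outer_iterations,
    row.names = row.names
  )
}
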