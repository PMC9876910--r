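#' Standard model for the rotation/offset error simulation
#'
#' A set of empirically plausible mean measurements for a standing pelvis
#' radiograph pair, used to quantify how much error uncorrected patient
#' rotation and marker offset would introduce into the hip-plane factor.
#' `d` is treated as the true (already calibrated) horizontal distance of
#' the marker from the hip plane; `a`, `b` and the lateral-view factor are
#' carried for completeness but do not enter the error computation, and
#' `c` is always simulated as `m * sin(alpha)`, never an input.
#'
#' @param sdd_mm Source-detector distance `S`, mm.
#' @param marker_radius_mm Marker radius `r`, mm.
#' @param k,h A.p. marker measurements: projected ellipse long axis and
#'   direct image-centre-to-marker distance, mm.
#' @param d Marker-to-hip-plane horizontal distance, mm (calibrated).
#' @param a,b Lateral-view marker measurements, mm (not used by the error
#'   recipe).
#' @param m Inter-hip distance, mm.
#' @return Object of class `"standard_model"`.
#' @examples
#' standard_model()
#' @export
standard_model <- function(sdd_mm = 1150, marker_radius_mm = 12.5,
                           k = 35, h = 10, d = 110,
                           a = 200, b = 35, m = 150) {
  setup <- device_setup(sdd_mm, marker_radius_mm)
  for (nm in c("k", "h", "d", "a", "b", "m"))
    check_scalar(get(nm), nm, lower = 0)
  structure(list(setup = setup, k = k, h = h, d = d, a = a, b = b, m = m),
            class = "standard_model")
}

#' @export
print.standard_model <- function(x, ...) {
  cat("Standard model (mm): S =", x$setup$sdd_mm,
      " r =", x$setup$marker_radius_mm, "\n")
  cat("  a.p.:    k =", x$k, " h =", x$h, " m =", x$m, "\n")
  cat("  lateral: b =", x$b, " a =", x$a, " d =", x$d, "\n")
  invisible(x)
}

# marker height and reference factor of the standard model
reference_state <- function(model, tol = 1e-4) {
  stopifnot(inherits(model, "standard_model"))
  sol <- marker_height_iterative(model$setup, model$k, model$h, tol = tol,
                                 view = "antero-posterior")
  H_ECM <- sol$height_H
  list(H_ECM = H_ECM,
       F_ref = factor_from_height(model$setup, H_ECM - model$d),
       solution = sol)
}

#' Reference hip-plane factor of the standard model
#'
#' The hip-plane calibration factor at zero rotation and zero offset:
#' the marker height `H_ECM` is solved from the a.p. measurements
#' (`k`, `h`) with displacement recalibration, then
#' `F = 100 S / (S - (H_ECM - d))`.
#'
#' @param model A [standard_model()].
#' @param tol Convergence tolerance for the marker height solver.
#' @return The reference factor in percent (numeric scalar) with the
#'   marker height attached as attribute `"H_ECM"`.
#' @examples
#' round(reference_factor(standard_model()), 2)  # 123.45
#' @export
reference_factor <- function(model, tol = 1e-4) {
  st <- reference_state(model, tol = tol)
  structure(st$F_ref, H_ECM = st$H_ECM)
}

#' Hip-plane factor error caused by uncorrected rotation and offset
#'
#' For patient rotation `alpha` and marker lateral offset `i` (both toward
#' the source), the true marker-to-hip-plane distance behind a measured
#' `d` is `y_rot = (d + i sin(alpha)) / cos(alpha)`, so the true factor is
#' `F_rot = 100 S / (S - (H_ECM - y_rot))` while an uncorrected analysis
#' reports the reference factor. The absolute error is
#' `F_ref - F_rot` (factor points, non-negative) and the relative error is
#' `100 * absolute / F_ref` (percent).
#'
#' @param model A [standard_model()].
#' @param rotation_deg Rotation angle(s) in degrees, `[0, 90)`. Vectorised.
#' @param offset_mm Lateral offset(s) `i` in mm, `>= 0`. Recycled against
#'   `rotation_deg`.
#' @param tol Convergence tolerance for the marker height solver.
#' @return A `data.frame` with columns `rotation_deg`, `offset_mm`,
#'   `F_reference`, `F_rotated`, `absolute_error`, `relative_error`.
#' @examples
#' rotation_error(standard_model(), 30, c(0, 20, 60))
#' @export
rotation_error <- function(model, rotation_deg, offset_mm, tol = 1e-4) {
  stopifnot(is.numeric(rotation_deg), is.numeric(offset_mm))
  if (any(!is.finite(rotation_deg)) || any(rotation_deg < 0) ||
      any(rotation_deg >= 90))
    stop("`rotation_deg` must lie in [0, 90)")
  if (any(!is.finite(offset_mm)) || any(offset_mm < 0))
    stop("`offset_mm` must be non-negative")
  n <- max(length(rotation_deg), length(offset_mm))
  rotation_deg <- rep_len(rotation_deg, n)
  offset_mm <- rep_len(offset_mm, n)

  st <- reference_state(model, tol = tol)
  S <- model$setup$sdd_mm
  a <- rotation_deg * pi / 180
  y_rot <- (model$d + offset_mm * sin(a)) / cos(a)
  F_rot <- 100 * S / (S - (st$H_ECM - y_rot))
  abs_err <- st$F_ref - F_rot
  data.frame(rotation_deg = rotation_deg,
             offset_mm = offset_mm,
             F_reference = st$F_ref,
             F_rotated = F_rot,
             absolute_error = abs_err,
             relative_error = 100 * abs_err / st$F_ref)
}

#' Rotation/offset error grid for the standard model
#'
#' Evaluates [rotation_error()] over a grid of rotations and offsets
#' (defaults: 0-30 degrees in 1 degree steps; offsets 0, 20 and 60 mm).
#'
#' @inheritParams rotation_error
#' @param rotations Rotation angles in degrees.
#' @param offsets Lateral offsets in mm.
#' @return A long-format `data.frame` of class `"rotation_error_table"`
#'   (one row per grid cell, columns as in [rotation_error()]), with the
#'   reference factor in attribute `"F_reference"`. Format for report
#'   precision with [format_error_table()]; plot with
#'   `plot(<table>)`.
#' @examples
#' tab <- error_table(standard_model())
#' head(format_error_table(tab))
#' @export
error_table <- function(model, rotations = 0:30, offsets = c(0, 20, 60),
                        tol = 1e-4) {
  grid <- expand.grid(rotation_deg = rotations, offset_mm = offsets,
                      KEEP.OUT.ATTRS = FALSE)
  out <- rotation_error(model, grid$rotation_deg, grid$offset_mm, tol = tol)
  structure(out,
            F_reference = out$F_reference[1],
            class = c("rotation_error_table", "data.frame"))
}

#' Round-half-up formatting of the error grid
#'
#' Reshapes the long error grid into a wide report: one row per rotation,
#' one pair of columns (absolute, relative) per offset. Absolute errors
#' are rounded half-up to 3 decimals (factor points), relative errors to
#' 1 decimal (percent).
#'
#' @param tab A table from [error_table()].
#' @return A wide `data.frame` with columns `rotation_deg`,
#'   `abs_err_i<offset>` and `rel_err_i<offset>`.
#' @export
format_error_table <- function(tab) {
  stopifnot(inherits(tab, "rotation_error_table"))
  offsets <- sort(unique(tab$offset_mm))
  rotations <- sort(unique(tab$rotation_deg))
  out <- data.frame(rotation_deg = rotations)
  for (o in offsets) {
    sub <- tab[tab$offset_mm == o, ]
    sub <- sub[order(sub$rotation_deg), ]
    out[[paste0("abs_err_i", o)]] <- round_half_up(sub$absolute_error, 3)
  }
  for (o in offsets) {
    sub <- tab[tab$offset_mm == o, ]
    sub <- sub[order(sub$rotation_deg), ]
    out[[paste0("rel_err_i", o)]] <- round_half_up(sub$relative_error, 1)
  }
  out
}

# half-up decimal rounding (report convention; base round() is half-even)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' First rotation at which the error reaches a threshold
#'
#' Scans the rotation grid per offset and reports the smallest rotation
#' whose (unrounded) absolute error reaches the threshold.
#'
#' @inheritParams error_table
#' @param threshold Absolute error threshold in factor points (`> 0`);
#'   1.5 is the usual bound for a clinically relevant calibration error.
#' @return Named numeric vector, one element per offset, holding the first
#'   rotation in degrees (or `NA` if the threshold is never reached on the
#'   grid).
#' @examples
#' threshold_scan(standard_model(), 1.5)  # 26, 18, 10 degrees
#' @export
threshold_scan <- function(model, threshold, offsets = c(0, 20, 60),
                           rotations = 0:30, tol = 1e-4) {
  check_scalar(threshold, "threshold", lower = 0, strict_lower = TRUE)
  tab <- error_table(model, rotations = rotations, offsets = offsets,
                     tol = tol)
  vapply(offsets, function(o) {
    sub <- tab[tab$offset_mm == o, ]
    sub <- sub[order(sub$rotation_deg), ]
    hit <- which(sub$absolute_error >= threshold)
    if (length(hit)) sub$rotation_deg[hit[1]] else NA_real_
  }, numeric(1), USE.NAMES = FALSE) |>
    stats::setNames(paste0("i", offsets))
}

#' Plot the rotation/offset error curves
#'
#' Two panels: absolute error (factor points) and relative error (percent)
#' of the uncorrected hip-plane factor against rotation, one curve per
#' lateral offset.
#'
#' @param x A `"rotation_error_table"`.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.rotation_error_table <- function(x, ...) {
  offsets <- sort(unique(x$offset_mm))
  rotations <- sort(unique(x$rotation_deg))
  absm <- sapply(offsets, function(o) {
    s <- x[x$offset_mm == o, ]; s$absolute_error[order(s$rotation_deg)]
  })
  relm <- sapply(offsets, function(o) {
    s <- x[x$offset_mm == o, ]; s$relative_error[order(s$rotation_deg)]
  })
  old <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  graphics::matplot(rotations, absm, type = "l", lty = 1, lwd = 2,
                    xlab = "rotation (degrees)",
                    ylab = "absolute error (factor points)",
                    main = "Uncorrected error", ...)
  graphics::legend("topleft", legend = paste0("i = ", offsets, " mm"),
                   col = seq_along(offsets), lty = 1, lwd = 2, bty = "n")
  graphics::matplot(rotations, relm, type = "l", lty = 1, lwd = 2,
                    xlab = "rotation (degrees)", ylab = "relative error (%)",
                    main = "Relative error", ...)
  invisible(x)
}
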