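#' Estimate patient rotation in the lateral radiograph
#'
#' A perfectly lateral radiograph projects both hip centres onto the same
#' vertical line. Patient rotation separates them horizontally; from the
#' calibrated horizontal hip-centre mismatch `c_cal` (lateral image) and
#' the calibrated inter-hip distance `m_cal` (a.p. image) the rotation
#' angle follows as `alpha = asin(c_cal / m_cal)`.
#'
#' The rotation direction (toward or away from the source) is not encoded
#' in the magnitudes: it is inferred from which hip projects anteriorly in
#' the lateral image combined with the direction the patient faces. With
#' the source at the patient's right (`facing = "left"`), rotation toward
#' the source turns the patient's front to the right, bringing the left
#' hip forward; hence the rotation is toward the source exactly when the
#' anterior hip matches the facing direction.
#'
#' @param c_cal Calibrated horizontal hip-centre distance in the lateral
#'   image, mm (`>= 0`).
#' @param m_cal Calibrated inter-hip distance from the a.p. image, mm
#'   (`> 0`).
#' @param anterior_hip Which hip projects anteriorly in the lateral image:
#'   `"right"`, `"left"`, or `"none"` for a perfect overlay (see
#'   [derive_lateral()]).
#' @param facing Direction the patient faces relative to the source in the
#'   lateral radiograph.
#' @return Object of class `"rotation_estimate"`: list with `alpha_deg`
#'   in `[0, 90)` and `direction` (`"toward_source"` or
#'   `"away_from_source"`). For a perfect overlay `alpha_deg = 0` and the
#'   direction defaults to `"toward_source"`; the choice is inert since the
#'   correction vanishes at zero rotation.
#' @examples
#' estimate_rotation(75, 150, anterior_hip = "left", facing = "left")
#' @export
estimate_rotation <- function(c_cal, m_cal,
                              anterior_hip = c("none", "right", "left"),
                              facing = c("left", "right")) {
  anterior_hip <- match.arg(anterior_hip)
  facing <- match.arg(facing)
  check_scalar(c_cal, "c_cal", lower = 0)
  check_scalar(m_cal, "m_cal", lower = 0, strict_lower = TRUE)
  if (c_cal > m_cal)
    stop("inconsistent measurements: calibrated hip-centre mismatch c_cal (",
         signif(c_cal, 6), " mm) exceeds the calibrated inter-hip distance ",
         "m_cal (", signif(m_cal, 6), " mm); check the hip landmarks")
  alpha <- asin(c_cal / m_cal) * 180 / pi
  if (alpha >= 90)
    stop("rotation angle of 90 degrees or more is outside the admissible ",
         "range; the lateral radiograph cannot be interpreted")
  direction <- if (anterior_hip == "none") {
    "toward_source"
  } else if (anterior_hip == facing) "toward_source" else "away_from_source"
  structure(list(alpha_deg = alpha, direction = direction),
            class = "rotation_estimate")
}

#' @export
print.rotation_estimate <- function(x, ...) {
  cat(sprintf("Patient rotation: %.3f degrees, %s\n", x$alpha_deg,
              gsub("_", " ", x$direction)))
  invisible(x)
}

#' Direction of the marker's lateral offset in the lateral radiograph
#'
#' A marker displaced toward the patient's right or left in the a.p.
#' radiograph ends up displaced toward the source or the detector in the
#' lateral radiograph, depending on which way the patient faces. For
#' example, offset toward the patient's right is toward the source when
#' the patient faces left (source at the patient's right side).
#'
#' @param offset_side Side of the patient the marker is offset toward in
#'   the a.p. image (`"right"` or `"left"`).
#' @param facing Direction the patient faces relative to the source in the
#'   lateral radiograph.
#' @return `"toward_source"` or `"away_from_source"`.
#' @examples
#' offset_direction_lateral("right", "left")   # toward_source
#' offset_direction_lateral("right", "right")  # away_from_source
#' @export
offset_direction_lateral <- function(offset_side = c("right", "left"),
                                     facing = c("left", "right")) {
  offset_side <- match.arg(offset_side)
  facing <- match.arg(facing)
  if (offset_side == facing) "away_from_source" else "toward_source"
}

#' Correct the marker-to-hip-plane distance for rotation and offset
#'
#' The horizontal marker-to-hip distance measured in the lateral image is
#' distorted by patient rotation `alpha` and by the marker's lateral
#' offset `i`. The offset contributes `x = sin(alpha) * i_cal`, signed
#' positive toward the source and negative away from it for both the
#' offset and the rotation direction (the two signs multiply); the
#' corrected distance is
#' `y_correction = (d_cal + x) / cos(alpha)`.
#'
#' @param d_cal Calibrated horizontal marker-to-hip-plane distance from the
#'   lateral image, mm (`>= 0`).
#' @param i_cal Calibrated lateral offset of the marker from the a.p.
#'   image, mm (`>= 0`).
#' @param alpha_deg Patient rotation angle in degrees, `[0, 90)`.
#' @param offset_direction,rotation_direction `"toward_source"` or
#'   `"away_from_source"` (see [offset_direction_lateral()] and
#'   [estimate_rotation()]).
#' @return List with `x` (signed offset contribution, mm), `y`
#'   (`d_cal + x`, mm) and `y_correction` (rotation-corrected distance,
#'   mm).
#' @examples
#' correct_rotation(110, 60, 30, "toward_source", "toward_source")
#' @export
correct_rotation <- function(d_cal, i_cal, alpha_deg,
                             offset_direction = c("toward_source",
                                                  "away_from_source"),
                             rotation_direction = c("toward_source",
                                                    "away_from_source")) {
  offset_direction <- match.arg(offset_direction)
  rotation_direction <- match.arg(rotation_direction)
  check_scalar(d_cal, "d_cal", lower = 0)
  check_scalar(i_cal, "i_cal", lower = 0)
  check_scalar(alpha_deg, "alpha_deg", lower = 0, upper = 90,
               strict_upper = TRUE)
  s_off <- if (offset_direction == "toward_source") 1 else -1
  s_rot <- if (rotation_direction == "toward_source") 1 else -1
  a <- alpha_deg * pi / 180
  x <- sin(a) * i_cal * s_off * s_rot
  y <- d_cal + x
  list(x = x, y = y, y_correction = y / cos(a))
}
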