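#' Landmark sets for the two radiographs
#'
#' Constructors for the raw per-image inputs of the calibration pipeline:
#' four landmark points plus the measured long axis of the projected marker
#' ellipse. Coordinates are detector-plane millimetres with the origin at
#' the image centre (the central beam); pixel-level landmark detection is
#' outside the scope of this package.
#'
#' Coordinate conventions (enforced nowhere but assumed throughout):
#' * antero-posterior (a.p.) image: x runs along the patient's left-right
#'   axis (patient right at negative x unless `right_x = "positive"`),
#'   y is vertical.
#' * lateral image: x runs along the patient's antero-posterior axis with
#'   +x pointing in the direction the patient faces (anterior), y vertical.
#'
#' `facing` records the direction the patient faces in the lateral
#' radiograph relative to the X-ray source: `"left"` means the source is at
#' the patient's right side, `"right"` means it is at the patient's left.
#'
#' @param image_center,marker_center,right_hip,left_hip Numeric `(x, y)`
#'   pairs in mm. In the a.p. image these are the points O (central beam),
#'   P (marker centre), Q and R (hip centres); in the lateral image A, B,
#'   C and D.
#' @param marker_long_axis_mm Measured long axis of the projected marker
#'   ellipse in this image, mm.
#' @param right_x Which sign of the a.p. x axis is the patient's right.
#' @param facing Direction the patient faces in the lateral image relative
#'   to the source (`"left"` or `"right"`).
#' @return An object of class `"ap_landmarks"` or `"lateral_landmarks"`.
#' @examples
#' ap <- ap_landmarks(image_center = c(0, 0), marker_center = c(10, 0),
#'                    right_hip = c(-75, 0), left_hip = c(75, 0),
#'                    marker_long_axis_mm = 35)
#' lat <- lateral_landmarks(image_center = c(0, 0), marker_center = c(140, 0),
#'                          right_hip = c(30, 10), left_hip = c(30, -10),
#'                          marker_long_axis_mm = 35, facing = "left")
#' @name landmarks
NULL

#' @rdname landmarks
#' @export
ap_landmarks <- function(image_center, marker_center, right_hip, left_hip,
                         marker_long_axis_mm,
                         right_x = c("negative", "positive")) {
  right_x <- match.arg(right_x)
  check_scalar(marker_long_axis_mm, "marker_long_axis_mm", lower = 0,
               strict_lower = TRUE)
  structure(list(image_center = check_point(image_center, "image_center (O)"),
                 marker_center = check_point(marker_center, "marker_center (P)"),
                 right_hip = check_point(right_hip, "right_hip (Q)"),
                 left_hip = check_point(left_hip, "left_hip (R)"),
                 marker_long_axis_mm = marker_long_axis_mm,
                 right_x = right_x),
            class = "ap_landmarks")
}

#' @rdname landmarks
#' @export
lateral_landmarks <- function(image_center, marker_center, right_hip,
                              left_hip, marker_long_axis_mm,
                              facing = c("left", "right")) {
  facing <- match.arg(facing)
  check_scalar(marker_long_axis_mm, "marker_long_axis_mm", lower = 0,
               strict_lower = TRUE)
  structure(list(image_center = check_point(image_center, "image_center (A)"),
                 marker_center = check_point(marker_center, "marker_center (B)"),
                 right_hip = check_point(right_hip, "right_hip (C)"),
                 left_hip = check_point(left_hip, "left_hip (D)"),
                 marker_long_axis_mm = marker_long_axis_mm,
                 facing = facing),
            class = "lateral_landmarks")
}

#' Scalar measurements from the lateral radiograph
#'
#' Reduces the lateral landmark set to the scalar distances the method
#' needs, via the geometric construction on the image: with A the image
#' centre, B the marker centre and C/D the right/left hip centres, the
#' auxiliary points are E = (x of C, y of D), G = midpoint of E and D (the
#' horizontal hip-centre construct) and H = (x of G, y of B). Then
#' `a = |A - B|` (direct distance image centre to marker), `c = |x_C - x_D|`
#' (horizontal mismatch of the hip centres, zero for a perfect lateral) and
#' `d = |B - H| = |x_B - x_G|` (horizontal distance hip-centre construct to
#' marker).
#'
#' The hip centre that projects further anterior (larger x under the +x =
#' anterior convention) is recorded: together with `facing` it determines
#' the direction of patient rotation.
#'
#' @param landmarks A [lateral_landmarks()] object.
#' @return Object of class `"lateral_measurements"`: list with `a`, `b`
#'   (marker long axis), `c`, `d` (all mm), `anterior_hip`
#'   (`"right"`, `"left"` or `"none"`) and `facing`.
#' @export
derive_lateral <- function(landmarks) {
  if (!inherits(landmarks, "lateral_landmarks"))
    stop("`landmarks` must be a lateral_landmarks object")
  A <- landmarks$image_center; B <- landmarks$marker_center
  C <- landmarks$right_hip;    D <- landmarks$left_hip
  x_G <- (C[1] + D[1]) / 2
  a <- sqrt(sum((A - B)^2))
  c_ <- abs(C[1] - D[1])
  d <- abs(B[1] - x_G)
  anterior_hip <- if (C[1] > D[1]) "right" else if (D[1] > C[1]) "left" else "none"
  structure(list(a = a, b = landmarks$marker_long_axis_mm, c = c_, d = d,
                 anterior_hip = anterior_hip, facing = landmarks$facing),
            class = "lateral_measurements")
}

#' Scalar measurements from the antero-posterior radiograph
#'
#' With O the image centre, P the marker centre and Q/R the right/left hip
#' centres: `h = |O - P|` (direct distance, the displacement entering the
#' height equation), `i = |x_P - x_O|` (its horizontal component, the
#' lateral offset of the marker) with the patient side it points to, and
#' `m = |x_Q - x_R|` (horizontal inter-hip distance, via the construct
#' T = (x of Q, y of R), V = midpoint of T and R).
#'
#' @param landmarks An [ap_landmarks()] object.
#' @return Object of class `"ap_measurements"`: list with `h`, `i`, `k`
#'   (marker long axis), `m` (all mm) and `offset_side` (`"right"`,
#'   `"left"`, or `"none"` when the marker sits exactly on the central
#'   beam).
#' @export
derive_ap <- function(landmarks) {
  if (!inherits(landmarks, "ap_landmarks"))
    stop("`landmarks` must be an ap_landmarks object")
  O <- landmarks$image_center; P <- landmarks$marker_center
  Q <- landmarks$right_hip;    R <- landmarks$left_hip
  h <- sqrt(sum((O - P)^2))
  i <- abs(P[1] - O[1])
  m <- abs(Q[1] - R[1])
  if (m == 0)
    stop("degenerate anatomy: hip centres Q and R coincide horizontally ",
         "in the a.p. image (m = 0)")
  right_sign <- if (landmarks$right_x == "negative") -1 else 1
  dx <- (P[1] - O[1]) * right_sign
  offset_side <- if (dx > 0) "right" else if (dx < 0) "left" else "none"
  structure(list(h = h, i = i, k = landmarks$marker_long_axis_mm, m = m,
                 offset_side = offset_side),
            class = "ap_measurements")
}

#' @export
print.lateral_measurements <- function(x, ...) {
  cat("Lateral measurements (mm): a =", x$a, " b =", x$b,
      " c =", x$c, " d =", x$d, "\n")
  cat("  anterior hip:", x$anterior_hip, " facing:", x$facing, "\n")
  invisible(x)
}

#' @export
print.ap_measurements <- function(x, ...) {
  cat("A.p. measurements (mm): h =", x$h, " i =", x$i,
      " k =", x$k, " m =", x$m, "\n")
  cat("  lateral offset toward patient side:", x$offset_side, "\n")
  invisible(x)
}
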