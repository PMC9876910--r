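#' Marker height above the detector from its projected ellipse
#'
#' A sphere of radius `r` placed between X-ray source and detector projects
#' as an ellipse. Given the measured long axis of that ellipse and the
#' measured distance of the ellipse centre from the image centre (the
#' central beam), the height of the sphere centre above the detector plane
#' follows in closed form:
#'
#' \deqn{H = S - \sqrt{r^2\left(1 + \frac{2S^2}{b^2}\right) +
#'   \frac{2rS}{b}\sqrt{\frac{r^2S^2}{b^2} + a^2}}}
#'
#' where `b` is the projected long axis and `a` the projected displacement
#' from the central beam. The same formula serves the lateral (`b`, `a`)
#' and the antero-posterior (`k`, `h`) radiograph.
#'
#' The displacement entering the formula is a projected (hence magnified)
#' length; [marker_height_iterative()] removes that magnification by
#' fixed-point iteration and is what the calibration pipeline uses.
#'
#' @param setup A [device_setup()] object.
#' @param long_axis Measured long axis of the projected marker ellipse, mm.
#'   Must exceed the marker diameter `2r` (the projection is magnified).
#' @param displacement Measured distance of the ellipse centre from the
#'   image centre, mm (non-negative).
#' @return Marker-centre height above the detector in mm, a value in
#'   `[0, S)`.
#' @examples
#' setup <- device_setup(1150, 12.5)
#' marker_height(setup, long_axis = 35, displacement = 10)
#' @seealso [marker_height_iterative()], [factor_from_height()]
#' @export
marker_height <- function(setup, long_axis, displacement) {
  setup <- as_device_setup(setup)
  S <- setup$sdd_mm
  r <- setup$marker_radius_mm
  check_scalar(long_axis, "long_axis", lower = 0, strict_lower = TRUE)
  check_scalar(displacement, "displacement", lower = 0)
  if (long_axis <= 2 * r)
    stop("projected long axis (", long_axis, " mm) must exceed the marker ",
         "diameter 2r = ", 2 * r, " mm: the projection of the marker is ",
         "always magnified")
  H <- height_formula(S, r, long_axis, displacement)
  if (H < -1e-6)
    stop("non-physical measurement: long_axis = ", long_axis,
         ", displacement = ", displacement,
         " place the marker below the detector (H = ", signif(H, 6), " mm)")
  max(H, 0)
}

# raw closed-form height; strictly increasing in axis, decreasing in |disp|
height_formula <- function(S, r, axis, disp) {
  S - sqrt(r^2 * (1 + 2 * S^2 / axis^2) +
             (2 * r * S / axis) * sqrt(r^2 * S^2 / axis^2 + disp^2))
}

#' Marker height with fixed-point recalibration of the displacement
#'
#' The displacement measured in the image is itself magnified by the
#' (initially unknown) marker-plane factor. Starting from the raw
#' measurement, the solver alternates between computing the height via
#' [marker_height()] and recalibrating the displacement,
#' `displacement_n = displacement_0 * (S - H_n) / S`, until the
#' marker-plane calibration factor changes by less than `tol` between
#' passes. At least one recalibration pass is always performed; with
#' `displacement = 0` the update is the identity and the solver stops after
#' that mandatory pass at the direct closed-form height.
#'
#' @inheritParams marker_height
#' @param tol Convergence tolerance on the calibration factor (percentage
#'   points). Default `1e-4`.
#' @param max_iter Maximum number of recalibration passes. Convergence is
#'   contractive and typically takes 2-6 passes.
#' @param view Optional label (`"antero-posterior"` or `"lateral"`) carried
#'   into the result for reporting.
#' @return An object of class `"height_solution"`: list with `height_H`
#'   (mm above detector), `factor_percent` (marker-plane calibration
#'   factor, 100 = life size), `n_iterations`, `converged`, `factor_trace`
#'   (factor after each pass, diagnostics) and `view`.
#' @examples
#' setup <- device_setup(1150, 12.5)
#' marker_height_iterative(setup, long_axis = 35, displacement = 10)
#' @export
marker_height_iterative <- function(setup, long_axis, displacement,
                                    tol = 1e-4, max_iter = 100L,
                                    view = NULL) {
  setup <- as_device_setup(setup)
  S <- setup$sdd_mm
  check_scalar(tol, "tol", lower = 0, strict_lower = TRUE)
  check_scalar(max_iter, "max_iter", lower = 1)

  H <- marker_height(setup, long_axis, displacement)
  F_prev <- factor_from_height(S, H)
  trace <- F_prev
  converged <- FALSE
  n <- 0L
  while (n < max_iter) {
    disp_n <- displacement * (S - H) / S  # undo marker-plane magnification
    H <- marker_height(setup, long_axis, disp_n)
    F_n <- factor_from_height(S, H)
    n <- n + 1L
    trace <- c(trace, F_n)
    if (abs(F_n - F_prev) < tol) {
      converged <- TRUE
      break
    }
    F_prev <- F_n
  }
  if (!converged) {
    cond <- errorCondition(
      paste0("marker height iteration did not converge within ", max_iter,
             " passes (last factor ", signif(trace[length(trace)], 8), ")"),
      class = c("hipcal_no_convergence", "error", "condition"),
      last_height = H, factor_trace = trace)
    stop(cond)
  }
  structure(list(height_H = H,
                 factor_percent = factor_from_height(S, H),
                 n_iterations = n,
                 converged = converged,
                 factor_trace = trace,
                 view = view),
            class = "height_solution")
}

#' @export
print.height_solution <- function(x, ...) {
  cat("Marker height solution", if (!is.null(x$view)) paste0("(", x$view, " view)"), "\n")
  cat(sprintf("  height above detector: %.3f mm\n", x$height_H))
  cat(sprintf("  calibration factor:    %.4f\n", x$factor_percent))
  cat("  recalibration passes:  ", x$n_iterations, "\n")
  invisible(x)
}

#' Intercept-theorem conversion between object height and factor
#'
#' For a flat object (or plane) at height `H` above the detector, the
#' intercept theorem gives the magnification as a percentage:
#' `F = 100 * S / (S - H)`; 100 means life size. `height_from_factor()` is
#' the algebraic inverse, `H = S * (1 - 100 / F)`.
#'
#' @param sdd_mm Source-detector distance `S` in mm (a plain number or a
#'   [device_setup()] object).
#' @param height_mm Object height above the detector plane, mm, in `[0, S)`.
#' @return `factor_from_height()`: the calibration factor in percent
#'   (`>= 100`). `height_from_factor()`: the height in mm.
#' @examples
#' factor_from_height(1150, 575)            # 200: midway doubles size
#' height_from_factor(1150, 200)            # 575
#' @export
factor_from_height <- function(sdd_mm, height_mm) {
  S <- if (inherits(sdd_mm, "device_setup")) sdd_mm$sdd_mm else sdd_mm
  check_scalar(S, "sdd_mm", lower = 0, strict_lower = TRUE)
  check_scalar(height_mm, "height_mm", lower = 0, upper = S,
               strict_upper = TRUE)
  100 * S / (S - height_mm)
}

#' @rdname factor_from_height
#' @param factor_percent Calibration factor in percent, `>= 100`.
#' @export
height_from_factor <- function(sdd_mm, factor_percent) {
  S <- if (inherits(sdd_mm, "device_setup")) sdd_mm$sdd_mm else sdd_mm
  check_scalar(S, "sdd_mm", lower = 0, strict_lower = TRUE)
  check_scalar(factor_percent, "factor_percent", lower = 100)
  S * (1 - 100 / factor_percent)
}
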