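#' X-ray device geometry
#'
#' Bundles the two pre-defined constants shared by every computation in the
#' package: the source-detector distance `S` of the radiographic setup and
#' the radius `r` of the spherical external calibration marker (ECM) fixed
#' to the patient.
#'
#' @param sdd_mm Source-detector distance `S` in mm. Must be positive.
#'   Defaults to 1150 mm, a typical standing pelvis setup.
#' @param marker_radius_mm Radius `r` of the calibration marker ball in mm.
#'   Must satisfy `0 < r < S/2`. Defaults to 12.5 mm (a standard 25 mm
#'   marker ball).
#'
#' @return An object of class `"device_setup"`: a list with elements
#'   `sdd_mm` and `marker_radius_mm`.
#' @examples
#' device_setup(sdd_mm = 1150, marker_radius_mm = 12.5)
#' @export
device_setup <- function(sdd_mm = 1150, marker_radius_mm = 12.5) {
  stopifnot(is.numeric(sdd_mm), length(sdd_mm) == 1L, is.finite(sdd_mm),
            is.numeric(marker_radius_mm), length(marker_radius_mm) == 1L,
            is.finite(marker_radius_mm))
  if (sdd_mm <= 0)
    stop("source-detector distance `sdd_mm` must be positive, got ", sdd_mm)
  if (marker_radius_mm <= 0 || marker_radius_mm >= sdd_mm / 2)
    stop("marker radius must satisfy 0 < r < S/2, got r = ", marker_radius_mm,
         " with S = ", sdd_mm)
  structure(list(sdd_mm = sdd_mm, marker_radius_mm = marker_radius_mm),
            class = "device_setup")
}

#' @export
print.device_setup <- function(x, ...) {
  cat("X-ray device setup\n")
  cat("  source-detector distance S:", x$sdd_mm, "mm\n")
  cat("  marker radius r:           ", x$marker_radius_mm, "mm\n")
  invisible(x)
}

as_device_setup <- function(x) {
  if (inherits(x, "device_setup")) return(x)
  stop("`setup` must be a device_setup object; see device_setup()")
}

# shared scalar validation helper
check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("`", name, "` must be a single finite number")
  if (if (strict_lower) x <= lower else x < lower)
    stop("`", name, "` must be ", if (strict_lower) "> " else ">= ", lower,
         ", got ", x)
  if (if (strict_upper) x >= upper else x > upper)
    stop("`", name, "` must be ", if (strict_upper) "< " else "<= ", upper,
         ", got ", x)
  invisible(x)
}

check_point <- function(p, name) {
  if (!is.numeric(p) || length(p) != 2L || any(!is.finite(p)))
    stop("landmark `", name, "` must be a finite numeric (x, y) pair")
  as.numeric(p)
}
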