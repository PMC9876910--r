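#' Read and write measurement files
#'
#' A calibration case is exchanged as JSON with the layout
#'
#' ```
#' {
#'   "device":  {"sdd_mm": 1150, "marker_radius_mm": 12.5},
#'   "ap":      {"landmarks": {"O": [x, y], "P": [...], "Q": [...], "R": [...]},
#'               "marker_long_axis_mm": 35, "right_x": "negative"},
#'   "lateral": {"landmarks": {"A": [x, y], "B": [...], "C": [...], "D": [...]},
#'               "marker_long_axis_mm": 35, "facing": "left"}
#' }
#' ```
#'
#' (`O`/`A` image centre, `P`/`B` marker centre, `Q`/`C` right hip,
#' `R`/`D` left hip; coordinates in detector-plane mm). The CSV variant
#' holds one case per row with columns `sdd_mm`, `marker_radius_mm`,
#' `ap_O_x`, `ap_O_y`, ..., `ap_k`, `ap_right_x`, `lat_A_x`, ...,
#' `lat_b`, `facing`.
#'
#' @param path File path.
#' @return `read_measurements()`: a list with elements `setup`
#'   ([device_setup()]), `ap` ([ap_landmarks()]) and `lateral`
#'   ([lateral_landmarks()]), directly consumable by
#'   [hip_calibration()]. `read_measurements_csv()`: a list of such
#'   case lists.
#' @examples
#' case <- project_scene(scene3d(), device_setup())
#' f <- tempfile(fileext = ".json")
#' write_measurements(list(setup = case$setup, ap = case$ap,
#'                         lateral = case$lateral), f)
#' rt <- read_measurements(f)
#' hip_calibration(rt$ap, rt$lateral, rt$setup)
#' @name measurement_io
NULL

#' @rdname measurement_io
#' @export
read_measurements <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  measurement_list_to_case(x)
}

measurement_list_to_case <- function(x) {
  for (f in c("device", "ap", "lateral"))
    if (is.null(x[[f]])) stop("measurement record lacks the `", f, "` field")
  setup <- device_setup(x$device$sdd_mm, x$device$marker_radius_mm)
  apl <- x$ap$landmarks
  latl <- x$lateral$landmarks
  ap <- ap_landmarks(unlist(apl$O), unlist(apl$P), unlist(apl$Q),
                     unlist(apl$R),
                     marker_long_axis_mm = x$ap$marker_long_axis_mm,
                     right_x = if (is.null(x$ap$right_x)) "negative"
                               else x$ap$right_x)
  lateral <- lateral_landmarks(unlist(latl$A), unlist(latl$B),
                               unlist(latl$C), unlist(latl$D),
                               marker_long_axis_mm =
                                 x$lateral$marker_long_axis_mm,
                               facing = x$lateral$facing)
  list(setup = setup, ap = ap, lateral = lateral)
}

#' @rdname measurement_io
#' @param case A list with elements `setup`, `ap`, `lateral` (as returned
#'   by [read_measurements()] or assembled from the constructors), or a
#'   `"synthetic_case"`.
#' @export
write_measurements <- function(case, path) {
  jsonlite::write_json(case_to_measurement_list(case), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

case_to_measurement_list <- function(case) {
  stopifnot(!is.null(case$setup), !is.null(case$ap), !is.null(case$lateral))
  ap <- case$ap; lat <- case$lateral
  list(device = list(sdd_mm = case$setup$sdd_mm,
                     marker_radius_mm = case$setup$marker_radius_mm),
       ap = list(landmarks = list(O = ap$image_center, P = ap$marker_center,
                                  Q = ap$right_hip, R = ap$left_hip),
                 marker_long_axis_mm = ap$marker_long_axis_mm,
                 right_x = ap$right_x),
       lateral = list(landmarks = list(A = lat$image_center,
                                       B = lat$marker_center,
                                       C = lat$right_hip, D = lat$left_hip),
                      marker_long_axis_mm = lat$marker_long_axis_mm,
                      facing = lat$facing))
}

case_csv_row <- function(case) {
  ap <- case$ap; lat <- case$lateral
  data.frame(sdd_mm = case$setup$sdd_mm,
             marker_radius_mm = case$setup$marker_radius_mm,
             ap_O_x = ap$image_center[1], ap_O_y = ap$image_center[2],
             ap_P_x = ap$marker_center[1], ap_P_y = ap$marker_center[2],
             ap_Q_x = ap$right_hip[1], ap_Q_y = ap$right_hip[2],
             ap_R_x = ap$left_hip[1], ap_R_y = ap$left_hip[2],
             ap_k = ap$marker_long_axis_mm, ap_right_x = ap$right_x,
             lat_A_x = lat$image_center[1], lat_A_y = lat$image_center[2],
             lat_B_x = lat$marker_center[1], lat_B_y = lat$marker_center[2],
             lat_C_x = lat$right_hip[1], lat_C_y = lat$right_hip[2],
             lat_D_x = lat$left_hip[1], lat_D_y = lat$left_hip[2],
             lat_b = lat$marker_long_axis_mm, facing = lat$facing)
}

#' @rdname measurement_io
#' @param cases A list of cases (see `case`).
#' @export
write_measurements_csv <- function(cases, path) {
  if (!is.null(cases$setup)) cases <- list(cases)
  rows <- do.call(rbind, lapply(cases, case_csv_row))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname measurement_io
#' @export
read_measurements_csv <- function(path) {
  rows <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(rows)), function(j) {
    row <- rows[j, ]
    list(setup = device_setup(row$sdd_mm, row$marker_radius_mm),
         ap = ap_landmarks(c(row$ap_O_x, row$ap_O_y),
                           c(row$ap_P_x, row$ap_P_y),
                           c(row$ap_Q_x, row$ap_Q_y),
                           c(row$ap_R_x, row$ap_R_y),
                           marker_long_axis_mm = row$ap_k,
                           right_x = row$ap_right_x),
         lateral = lateral_landmarks(c(row$lat_A_x, row$lat_A_y),
                                     c(row$lat_B_x, row$lat_B_y),
                                     c(row$lat_C_x, row$lat_C_y),
                                     c(row$lat_D_x, row$lat_D_y),
                                     marker_long_axis_mm = row$lat_b,
                                     facing = row$facing))
  })
}

#' Write a calibration report as JSON
#'
#' Serialises a [hip_calibration()] fit with all intermediate quantities
#' (raw and calibrated measurements, marker heights, rotation and offset
#' correction, iteration counts, final factor).
#'
#' @param fit A `"hip_calibration"` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(fit, path) {
  stopifnot(inherits(fit, "hip_calibration"))
  report <- c(list(device = list(sdd_mm = fit$setup$sdd_mm,
                                 marker_radius_mm = fit$setup$marker_radius_mm)),
              as.list(as.data.frame(fit)),
              list(notes = fit$notes))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
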