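# shared builders for the test suite

std_setup <- function() device_setup(sdd_mm = 1150, marker_radius_mm = 12.5)

# frozen reference grid for the standard-model rotation/offset error
# (absolute errors at 3 dp, relative at 1 dp)
reference_grid <- function() {
  read.csv(test_path("rotation-error-reference.csv"))
}

# scene whose measured (calibrated) lateral marker-to-hip distance equals the
# standard model's d, with the marker at the standard-model height: the
# forward counterpart of the rotation-error recipe
standard_error_scene <- function(alpha_deg, offset_mm, tol = 1e-10) {
  st <- reference_factor(standard_model(), tol = tol)
  H_ECM <- attr(st, "H_ECM")
  a <- alpha_deg * pi / 180
  d_true <- (110 + offset_mm * sin(a)) / cos(a)
  scene3d(d_true = d_true, i_true = offset_mm, i_side = "right",
          facing = "left", rotation_direction = "toward_source",
          alpha_deg = alpha_deg, hip_height_ap = H_ECM - d_true)
}
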