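test_that("closed-form marker height matches direct evaluation", {
  setup <- std_setup()
  expect_equal(marker_height(setup, long_axis = 35, displacement = 10),
               328.415, tolerance = 0.01 / 328.415)
  expect_equal(marker_height(setup, long_axis = 35, displacement = 200),
               305.7, tolerance = 0.1 / 305.7)
  # on the central beam the closed form is the exact tangent-cone inverse
  expect_equal(marker_height(setup, 35, 0),
               1150 - 12.5 * sqrt(1 + 4 * 1150^2 / 35^2))
})

test_that("marker height is monotone in its measurements", {
  setup <- std_setup()
  axes <- seq(28, 60, by = 4)
  h_axis <- vapply(axes, function(ax) marker_height(setup, ax, 10), 1)
  expect_true(all(diff(h_axis) > 0))  # larger shadow -> nearer the source
  disps <- seq(0, 250, by = 50)
  h_disp <- vapply(disps, function(d) marker_height(setup, 35, d), 1)
  expect_true(all(diff(h_disp) < 0))  # off-axis shadow -> farther down
})

test_that("non-physical measurements are rejected with context", {
  setup <- std_setup()
  expect_error(marker_height(setup, long_axis = 24, displacement = 0),
               "marker")
  expect_error(marker_height(setup, long_axis = 25, displacement = 0),
               "magnified")
  expect_error(marker_height(setup, 35, -1), "displacement")
  expect_error(marker_height(setup, 25.0001, 3000), "below the detector")
})

test_that("iterative solver reaches the self-consistent height", {
  setup <- std_setup()
  sol <- marker_height_iterative(setup, 35, 10)
  expect_s3_class(sol, "height_solution")
  expect_equal(sol$height_H, 328.445, tolerance = 0.01 / 328.445)
  expect_true(sol$converged)
  expect_gte(sol$n_iterations, 1)

  # large displacement: several recalibration passes needed
  sol2 <- marker_height_iterative(setup, 35, 200)
  expect_equal(sol2$height_H, 316.145, tolerance = 1 / 316)
  expect_gte(sol2$n_iterations, 2)
  # brute-force oracle: scan for the self-consistent height
  H_grid <- seq(312, 320, by = 1e-4)
  resid <- abs(vapply(H_grid, function(H)
    marker_height(setup, 35, 200 * (1150 - H) / 1150) - H, 1))
  expect_equal(sol2$height_H, H_grid[which.min(resid)], tolerance = 1e-5)

  # factor sequence contracts
  steps <- abs(diff(sol2$factor_trace))
  expect_true(all(diff(steps) < 0))
})

test_that("zero displacement converges after the mandatory single pass", {
  setup <- std_setup()
  sol <- marker_height_iterative(setup, 35, 0)
  expect_identical(sol$n_iterations, 1L)
  expect_equal(sol$height_H, marker_height(setup, 35, 0))
})

test_that("non-convergence raises an error carrying the last iterate", {
  setup <- std_setup()
  err <- tryCatch(marker_height_iterative(setup, 35, 200, tol = 1e-12,
                                          max_iter = 2),
                  error = identity)
  expect_s3_class(err, "hipcal_no_convergence")
  expect_true(is.numeric(err$last_height))
  expect_gte(length(err$factor_trace), 2)
})

test_that("factor/height conversions satisfy the intercept theorem", {
  expect_equal(factor_from_height(1150, 0), 100)
  expect_equal(factor_from_height(1150, 575), 200)
  expect_equal(height_from_factor(1150, 100), 0)
  expect_equal(height_from_factor(1150, 200), 575)
  expect_equal(factor_from_height(1150, 218.45), 123.45,
               tolerance = 0.01 / 123.45)
  expect_error(factor_from_height(1150, 1150), "height_mm")
  expect_error(height_from_factor(1150, 99), "factor_percent")
})

test_that("factor and height are inverse to 1e-9 relative", {
  S <- 1150
  for (H in c(0, 12.5, 218.45, 328.445, 575, 900, 1149)) {
    expect_equal(height_from_factor(S, factor_from_height(S, H)), H,
                 tolerance = 1e-9)
  }
  for (F in c(100, 100.5, 123.45, 200, 1000)) {
    expect_equal(factor_from_height(S, height_from_factor(S, F)), F,
                 tolerance = 1e-9)
  }
})

test_that("iterative inversion recovers true sphere heights from exact projections", {
  setup <- std_setup()
  for (z in seq(100, 500, by = 50)) {
    for (X in seq(0, 200, by = 50)) {
      p <- project_sphere(setup, height_mm = z, radial_mm = X)
      sol <- marker_height_iterative(setup, p$long_axis, p$displacement)
      expect_lt(abs(sol$height_H - z), 0.5)
    }
  }
})
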