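test_that("standard model settings yield the reference factor 123.45", {
  F_ref <- reference_factor(standard_model())
  expect_equal(round(as.numeric(F_ref), 2), 123.45)
  expect_equal(attr(F_ref, "H_ECM"), 328.445, tolerance = 0.01 / 328.445)
})

test_that("reference factor responds to the hip-plane distance as geometry dictates", {
  m0 <- standard_model(d = 0)
  sol <- marker_height_iterative(device_setup(), 35, 10)
  expect_equal(as.numeric(reference_factor(m0)), sol$factor_percent,
               tolerance = 1e-8)
  ds <- c(0, 50, 110, 200)
  Fs <- vapply(ds, function(d)
    as.numeric(reference_factor(standard_model(d = d))), 1)
  expect_true(all(diff(Fs) < 0))  # hip plane nearer the detector
})

test_that("uncorrected rotation/offset error matches spot values", {
  m <- standard_model()
  e00 <- rotation_error(m, 0, 0)
  expect_equal(e00$absolute_error, 0, tolerance = 1e-12)
  expect_equal(round_half_up(rotation_error(m, 30, 0)$absolute_error, 3),
               2.215)
  expect_equal(round_half_up(rotation_error(m, 21, 0)$absolute_error, 3),
               1.028)
  e30_60 <- rotation_error(m, 30, 60)
  expect_equal(round_half_up(e30_60$absolute_error, 3), 6.486)
  expect_equal(round_half_up(e30_60$relative_error, 1), 5.3)
})

test_that("the full 31 x 3 error grid reproduces the frozen reference cell-for-cell", {
  ref <- reference_grid()
  got <- format_error_table(error_table(standard_model()))
  expect_equal(got$rotation_deg, ref$rotation_deg)
  for (col in c("abs_err_i0", "abs_err_i20", "abs_err_i60"))
    expect_equal(got[[col]], ref[[col]], tolerance = 1e-12)
  for (col in c("rel_err_i0", "rel_err_i20", "rel_err_i60"))
    expect_equal(got[[col]], ref[[col]], tolerance = 1e-12)
})

test_that("error grows monotonically in rotation and offset", {
  tab <- error_table(standard_model())
  for (o in c(0, 20, 60)) {
    col <- tab[tab$offset_mm == o, ]
    col <- col[order(col$rotation_deg), ]
    expect_true(all(diff(col$absolute_error) > 0))
  }
  for (al in unique(tab$rotation_deg)) {
    if (al == 0) next
    row <- tab[tab$rotation_deg == al, ]
    row <- row[order(row$offset_mm), ]
    expect_true(all(diff(row$absolute_error) > 0))
  }
  expect_true(all(tab$absolute_error[tab$rotation_deg > 0] > 0))
  expect_true(all(tab$absolute_error[tab$rotation_deg == 0] == 0))
})

test_that("relative and absolute errors are consistent before rounding", {
  tab <- error_table(standard_model())
  expect_equal(tab$relative_error * tab$F_reference / 100,
               tab$absolute_error, tolerance = 1e-12)
})

test_that("threshold scans locate the first offending rotation per offset", {
  m <- standard_model()
  expect_equal(unname(threshold_scan(m, 1.5)), c(26, 18, 10))
  expect_equal(unname(threshold_scan(m, 1.0)), c(21, 14, 7))
  expect_true(is.na(threshold_scan(m, 10, offsets = 0)[["i0"]]))
})

test_that("applying the correction with the true pose inverts the simulated error", {
  m <- standard_model()
  st <- reference_factor(m)
  H_ECM <- attr(st, "H_ECM")
  S <- 1150
  for (al in c(5, 18, 30)) {
    for (i in c(0, 20, 60)) {
      err <- rotation_error(m, al, i)
      # the rotated scenario measures d = 110; correcting it recovers the
      # true distance and hence the true (rotated-geometry) factor
      corr <- correct_rotation(110, i, al, "toward_source", "toward_source")
      F_corrected <- factor_from_height(S, H_ECM - corr$y_correction)
      expect_equal(F_corrected, err$F_rotated, tolerance = 1e-12)
      expect_equal(as.numeric(st) - F_corrected, err$absolute_error,
                   tolerance = 1e-12)
    }
  }
})

test_that("report rounding is half-up at the printed precision", {
  expect_equal(round_half_up(5.25, 1), 5.3)   # base round() would give 5.2
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(-1.25, 1), -1.3)
})
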