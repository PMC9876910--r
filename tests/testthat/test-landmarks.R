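test_that("lateral construction reduces landmarks to a, c, d", {
  lm <- lateral_landmarks(image_center = c(0, 0), marker_center = c(140, 0),
                          right_hip = c(30, 10), left_hip = c(30, -10),
                          marker_long_axis_mm = 35, facing = "left")
  m <- derive_lateral(lm)
  expect_equal(m$a, 140)
  expect_equal(m$c, 0)      # perfect overlay despite vertical separation
  expect_equal(m$d, 110)
  expect_identical(m$anterior_hip, "none")

  lm2 <- lateral_landmarks(c(0, 0), c(140, 0), c(40, 10), c(20, -10),
                           marker_long_axis_mm = 35, facing = "left")
  m2 <- derive_lateral(lm2)
  expect_equal(m2$c, 20)
  expect_equal(m2$d, 110)   # G at x = 30, midpoint of E = (40,-10) and D
  expect_identical(m2$anterior_hip, "right")
})

test_that("lateral d is invariant under vertical translation of the marker", {
  base <- function(yB) derive_lateral(
    lateral_landmarks(c(0, 0), c(140, yB), c(37, 12), c(21, -4),
                      marker_long_axis_mm = 35, facing = "right"))
  d_vals <- vapply(c(-50, 0, 13, 80), function(y) base(y)$d, 1)
  expect_true(all(d_vals == d_vals[1]))
})

test_that("a.p. construction reduces landmarks to h, i, m with the offset side", {
  lm <- ap_landmarks(c(0, 0), c(10, 0), right_hip = c(-75, 0),
                     left_hip = c(75, 0), marker_long_axis_mm = 35)
  m <- derive_ap(lm)
  expect_equal(m$m, 150)
  expect_equal(m$i, 10)
  expect_equal(m$h, 10)
  # default convention: patient right at negative x, so +10 is to the left
  expect_identical(m$offset_side, "left")
  m_flip <- derive_ap(ap_landmarks(c(0, 0), c(10, 0), c(-75, 0), c(75, 0),
                                   marker_long_axis_mm = 35,
                                   right_x = "positive"))
  expect_identical(m_flip$offset_side, "right")

  # purely vertical displacement has no lateral offset
  m2 <- derive_ap(ap_landmarks(c(0, 0), c(0, 8), c(-75, 0), c(75, 0), 35))
  expect_equal(m2$i, 0)
  expect_equal(m2$h, 8)
  expect_identical(m2$offset_side, "none")

  # 6-8-10 triangle
  m3 <- derive_ap(ap_landmarks(c(0, 0), c(6, 8), c(-75, 5), c(75, -5), 35))
  expect_equal(m3$h, 10)
  expect_equal(m3$i, 6)
  expect_equal(m3$m, 150)
})

test_that("malformed landmarks are rejected", {
  expect_error(ap_landmarks(c(0, 0), c(NaN, 0), c(-75, 0), c(75, 0), 35),
               "finite")
  expect_error(lateral_landmarks(c(0, 0), c(140), c(30, 10), c(30, -10),
                                 35, "left"),
               "\\(x, y\\)")
  expect_error(derive_ap(ap_landmarks(c(0, 0), c(10, 0), c(0, 5), c(0, -5),
                                      35)),
               "degenerate")
})
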