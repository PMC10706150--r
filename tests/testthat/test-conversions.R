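test_that("linear calibration maps cf1 through intercept and slope", {
  expect_equal(apply_linear_calibration(0), 0.53)
  expect_equal(apply_linear_calibration(10), 6.03)
  arm1 <- sensor_calibration("Arm1", 0.53, 0.580)
  expect_equal(apply_linear_calibration(20, arm1), 12.13)
  # strictly increasing in cf1 for positive slope
  cf1 <- sort(runif(50, 0, 400))
  expect_true(all(diff(apply_linear_calibration(cf1, arm1)) > 0))
  # large inputs pass through without complaint
  expect_equal(apply_linear_calibration(1e6), 0.53 + 0.55e6)
  expect_error(apply_linear_calibration(c(3, -1)),
               class = "pacolloc_invalid_input")
  expect_error(sensor_calibration("x", 1, 0),
               class = "pacolloc_invalid_calibration")
})

test_that("packaged calibration table matches the deployed units", {
  cal <- read_calibrations()
  expect_equal(nrow(cal), 8)
  expect_setequal(cal$unit_id,
                  c("DPE", "ARC2", "ARC1", "ARC02", "ARC17",
                    "Arm1", "Arm2", "Arm3"))
  arm1 <- lookup_calibration("Arm1", cal)
  expect_equal(c(arm1$intercept, arm1$slope), c(0.53, 0.580))
  # uncalibrated units fall back to the default woodsmoke conversion
  expect_warning(unknown <- lookup_calibration("nope", cal),
                 class = "pacolloc_default_calibration")
  expect_equal(c(unknown$intercept, unknown$slope), c(0.53, 0.55))
  expect_equal(unknown$source, "default_woodsmoke")
})

test_that("ALT-3.4 converts binned counts to mass", {
  expect_equal(alt34(0, 0, 0, 0), 0)
  expect_equal(alt34(1000, 0, 0, 0), 3.4 * 0.00030418 * 1000)
  expect_equal(alt34(1000, 0, 0, 0), 1.0342, tolerance = 1e-4)
  expect_equal(alt34(1110, 110, 10, 0), 2.3673, tolerance = 1e-4)
  expect_error(alt34(10, 20, 0, 0), class = "pacolloc_invalid_counts")
})

test_that("ALT-3.4 is linear and non-negative; P1 stays within [0, 1]", {
  withr::with_seed(11, {
    a <- random_counts(300)
    b <- random_counts(300)
  })
  sum_ab <- a + b
  expect_equal(alt34(sum_ab$n_gt_0p3, sum_ab$n_gt_0p5, sum_ab$n_gt_1,
                     sum_ab$n_gt_2p5),
               alt34(a$n_gt_0p3, a$n_gt_0p5, a$n_gt_1, a$n_gt_2p5) +
                 alt34(b$n_gt_0p3, b$n_gt_0p5, b$n_gt_1, b$n_gt_2p5),
               tolerance = 1e-12)
  mass <- alt34(a$n_gt_0p3, a$n_gt_0p5, a$n_gt_1, a$n_gt_2p5)
  expect_true(all(mass >= 0))
  p1 <- p1_fraction(a$n_gt_0p3, a$n_gt_0p5, a$n_gt_1, a$n_gt_2p5)
  expect_true(all(p1 >= 0 & p1 <= 1, na.rm = TRUE))
})

test_that("P1 splits mass around the 1-micron boundary", {
  expect_equal(p1_fraction(1100, 100, 0, 0), 1)       # no coarse channel
  expect_equal(p1_fraction(10, 10, 10, 0), 0)         # all mass coarse
  expect_equal(p1_fraction(1110, 110, 10, 0), 0.48930 / 0.6962706,
               tolerance = 1e-4)
  expect_warning(out <- p1_fraction(0, 0, 0, 0),
                 class = "pacolloc_undefined_fraction")
  expect_true(is.na(out))
})

test_that("nephelometer woodsmoke relationship is affine in scattering", {
  expect_equal(neph_to_pm25(0), 0.53)
  expect_equal(neph_to_pm25(1), 22.716)
  expect_equal(neph_to_pm25(0.5), 11.623)
  expect_equal(neph_to_pm25(-0.01), 0.53 - 0.22186) # instrument noise allowed
})

test_that("US EPA conversion has the documented RH-dependent intercept", {
  expect_equal(round(usepa_conversion(0, 100), 2), -2.87)
  expect_equal(round(usepa_conversion(0, 33), 2), 2.91)
  expect_equal(round(usepa_conversion(0, 66.7), 2), 0)
  # strictly decreasing in RH, with its root between 66 and 67 percent
  rh <- seq(0, 100, by = 0.5)
  expect_true(all(diff(usepa_conversion(0, rh)) < 0))
  root <- uniroot(function(r) usepa_conversion(0, r), c(0, 100))$root
  expect_gt(root, 66)
  expect_lt(root, 67)
  expect_error(usepa_conversion(5, 101), class = "pacolloc_invalid_input")
  expect_error(usepa_conversion(5, -2), class = "pacolloc_invalid_input")
})
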