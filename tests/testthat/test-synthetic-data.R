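test_that("truth process is flat without peak and noise, seasonal otherwise", {
  cfg <- simulation_config(seed = 5, n_days = 3, evening_peak_pm = 0,
                           truth_noise_sd = 0)
  truth <- simulate_truth(cfg)
  expect_true(all(truth$pm_true == cfg$baseline_pm))
  expect_equal(nrow(truth), 3 * 1440)

  # winter daily means exceed summer daily means when seasonality is on
  cfg_yr <- simulation_config(seed = 5, n_days = 365)
  truth_yr <- simulate_truth(cfg_yr)
  daily <- truth_yr |>
    dplyr::mutate(month = lubridate::month(time)) |>
    dplyr::group_by(month) |>
    dplyr::summarise(pm = mean(pm_true), p1 = mean(p1_true))
  expect_gt(mean(daily$pm[daily$month %in% 6:8]),
            mean(daily$pm[daily$month %in% c(12, 1, 2)]))
  expect_gt(mean(daily$p1[daily$month %in% 6:8]),
            mean(daily$p1[daily$month %in% c(12, 1, 2)]))
})

test_that("the same seed reproduces every stream bit for bit", {
  cfg <- simulation_config(seed = 17, n_days = 4, units = "Arm1")
  s1 <- simulate_site(cfg)
  s2 <- simulate_site(cfg)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$pa$Arm1, s2$pa$Arm1)
  expect_identical(s1$reference, s2$reference)
})

test_that("noise-free sensors invert their calibration exactly at 2-min scale", {
  cfg <- simulation_config(seed = 6, n_days = 2, sensor_noise_cv = 0,
                           spike_rate = 0, units = "ARC2")
  truth <- simulate_truth(cfg)
  rec <- simulate_pa_unit(truth, cfg, "ARC2")
  cal <- attr(rec, "calibration")
  truth_2min <- colMeans(matrix(truth$pm_true, nrow = 2))
  expect_equal(apply_linear_calibration(rec$cf1_a, cal), truth_2min,
               tolerance = 1e-12)
  expect_identical(rec$cf1_a, rec$cf1_b)
})

test_that("synthesised counts reproduce the target mass and P1 fraction", {
  cfg <- simulation_config(seed = 8, n_days = 2, spike_rate = 0,
                           units = "Arm1")
  truth <- simulate_truth(cfg)
  rec <- simulate_pa_unit(truth, cfg, "Arm1")
  cal <- attr(rec, "calibration")
  mass_a <- apply_linear_calibration(rec$cf1_a, cal)
  expect_equal(alt34(rec$n_gt_0p3_a, rec$n_gt_0p5_a, rec$n_gt_1_a,
                     rec$n_gt_2p5_a),
               mass_a, tolerance = 1e-9)
  p1_target <- colMeans(matrix(truth$p1_true, nrow = 2))
  expect_equal(p1_fraction(rec$n_gt_0p3_a, rec$n_gt_0p5_a, rec$n_gt_1_a,
                           rec$n_gt_2p5_a),
               p1_target, tolerance = 1e-9)
})

test_that("an unknown unit id falls back to the default conversion with a warning", {
  cfg <- simulation_config(seed = 9, n_days = 1, units = "mystery")
  truth <- simulate_truth(cfg)
  expect_warning(rec <- simulate_pa_unit(truth, cfg, "mystery"),
                 class = "pacolloc_default_calibration")
  expect_equal(attr(rec, "calibration")$source, "default_woodsmoke")
})

test_that("an injected one-channel spike is flagged by the fusion rule", {
  cfg <- simulation_config(seed = 10, n_days = 10, spike_rate = 40,
                           spike_magnitude = 50, units = "Arm1")
  truth <- simulate_truth(cfg)
  rec <- simulate_pa_unit(truth, cfg, "Arm1")
  spikes <- attr(rec, "spikes")
  expect_gt(nrow(spikes), 0)
  cal <- attr(rec, "calibration")
  rec$pm_a <- apply_linear_calibration(rec$cf1_a, cal)
  rec$pm_b <- apply_linear_calibration(rec$cf1_b, cal)
  fused <- rec |>
    records_to_hourly(cols = c(pm_a, pm_b)) |>
    fuse_channels()
  expect_true(all(spikes$hour_start %in% fused$hour_start[fused$discordant]))
})

test_that("the FDMS duty cycle averages only the measurement windows", {
  # constant truth, zero noise: duty-cycled value equals the constant
  cfg <- simulation_config(seed = 12, n_days = 1, evening_peak_pm = 0,
                           truth_noise_sd = 0, teom_noise_sd = 0)
  truth <- simulate_truth(cfg)
  ref <- simulate_teom_fdms(truth, cfg)
  expect_equal(ref$pm25, rep(cfg$baseline_pm, 24), tolerance = 1e-12)

  # a step aligned with the reference half of each cycle biases the duty mean
  step_truth <- truth
  step_truth$pm_true <- ifelse(lubridate::minute(truth$time) %% 12 < 6, 10, 30)
  duty <- simulate_teom_fdms(step_truth, cfg)
  full <- simulate_teom_fdms(step_truth,
                             simulation_config(seed = 12, n_days = 1,
                                               teom_noise_sd = 0,
                                               teom_duty_cycle = FALSE))
  expect_equal(duty$pm25, rep(10, 24))
  expect_equal(full$pm25, rep(20, 24))

  # zero truth with noise sd 3 yields some negative hourly readings
  cfg_n <- simulation_config(seed = 13, n_days = 42, baseline_pm = 0,
                             evening_peak_pm = 0, truth_noise_sd = 0,
                             teom_noise_sd = 3)
  ref_n <- simulate_teom_fdms(simulate_truth(cfg_n), cfg_n)
  expect_gt(nrow(ref_n), 1000)
  expect_gt(sum(ref_n$pm25 < 0), 0)
})

test_that("a simulated site bundles coherent instrument streams", {
  cfg <- simulation_config(seed = 14, n_days = 3, units = c("Arm1", "DPE"))
  site <- simulate_site(cfg)
  expect_named(site$pa, c("Arm1", "DPE"))
  expect_true(all(c("timestamp", "pm25", "pm10", "neph") %in%
                    names(site$reference)))
  expect_equal(nrow(site$reference), 72)
  # nephelometer inverts the woodsmoke relationship up to noise
  hourly_truth <- colMeans(matrix(site$truth$pm_true, nrow = 60))
  expect_lt(max(abs(neph_to_pm25(site$reference$neph) - hourly_truth)), 2)
  # PM10 never falls below PM2.5 on average
  expect_gt(mean(site$reference$pm10 - site$reference$pm25), 0)
})
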