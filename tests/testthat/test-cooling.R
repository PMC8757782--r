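test_that("reduced cooling laws satisfy their structural constraints", {
  cal <- default_cooling()
  expect_identical(irrigation_h(cal, 0), 0)
  Q <- c(2, 17, 30, 60)
  expect_true(all(diff(irrigation_h(cal, Q)) > 0))
  expect_identical(blood_keff_multiplier(cal, 0), 1)
  v <- c(0, 0.1, 0.5)
  expect_true(all(diff(blood_keff_multiplier(cal, v)) > 0))
  expect_identical(blood_sink_rate(cal, 0), 0)
  expect_identical(endocardial_h(cal, 0), 0)
  expect_identical(cloud_multiplier(cal, 0), 1)
  expect_true(all(diff(cloud_multiplier(cal, Q)) > 0))
})

test_that("calibration objects validate their parameters", {
  expect_error(cooling_calibration(h_irr = c(-1, 0.8), keff = c(25, 0.8),
                                   h_endo = c(0, 1), blood_sink = c(0, 1)),
               "h_irr")
  expect_error(cooling_calibration(h_irr = c(1200, 0.8), keff = c(25, 0.8),
                                   h_endo = c(0, 1), blood_sink = c(0, 1),
                                   cooled_fraction = 1.4),
               "cooled_fraction")
  cal <- cooling_calibration(h_irr = c(1200, 0.8), keff = c(25, 0.8),
                             h_endo = c(4000, 0.8), blood_sink = c(250, 1))
  expect_s3_class(cal, "abl_cooling")
})

test_that("single-reference single-parameter calibration recovers the truth", {
  # generate a synthetic reference by running the model at a known cloud
  # strength, then recover it from a perturbed start
  num <- numerics_config(preset = "sweep")
  cfg <- study_config(tip = "spherical", power_W = 90, duration_s = 4,
                      cf_g = 5, irrigation_ml_min = 60,
                      blood_velocity_m_s = 0.1, chamber = "atrium",
                      numerics = num)
  truth <- default_cooling()
  res_truth <- run_application(cfg, truth)
  ref <- list(list(config = cfg, depth_mm = res_truth$lesion$depth_D_mm,
                   width_mm = res_truth$lesion$width_W_mm))
  start <- truth
  start$sigma_cloud[1] <- truth$sigma_cloud[1] * 1.6
  cal <- suppressWarnings(
    calibrate_cooling(ref, start = start, free = "sigma_cloud_a",
                      reltol = 0.02))
  r <- attr(cal, "residuals")
  expect_lt(max(abs(r)), 0.02)
  expect_equal(cal$sigma_cloud[1], truth$sigma_cloud[1], tolerance = 0.15)
})

test_that("calibration is deterministic", {
  # two identical cheap calibrations give identical parameters
  num <- numerics_config(preset = "sweep")
  cfg <- study_config(tip = "spherical", power_W = 90, duration_s = 4,
                      cf_g = 5, irrigation_ml_min = 60,
                      blood_velocity_m_s = 0.1, chamber = "atrium",
                      numerics = num)
  ref <- list(list(config = cfg, depth_mm = 3.0, width_mm = 5.8))
  c1 <- suppressWarnings(calibrate_cooling(ref, free = "sigma_cloud_a",
                                           reltol = 0.1))
  c2 <- suppressWarnings(calibrate_cooling(ref, free = "sigma_cloud_a",
                                           reltol = 0.1))
  expect_identical(c1$sigma_cloud, c2$sigma_cloud)
})

test_that("irrigation cooling is monotone in a full application", {
  # raising the flushing rate never raises the peak blood temperature
  cal <- default_cooling()
  num <- numerics_config(preset = "sweep")
  peaks <- vapply(c(17, 30, 60), function(Q) {
    cfg <- study_config(tip = "cylindrical", power_W = 90, duration_s = 4,
                        cf_g = 5, irrigation_ml_min = Q,
                        blood_velocity_m_s = 0.1, chamber = "ventricle",
                        numerics = num)
    max(run_application(cfg, cal)$traces$max_shell_T)
  }, numeric(1))
  expect_true(all(diff(peaks) <= 0))
})

test_that("blood flow cooling shallows completed standard lesions", {
  cal <- default_cooling()
  num <- numerics_config(preset = "sweep")
  runs <- lapply(c(0, 0.1, 0.5), function(v) {
    cfg <- study_config(tip = "spherical", power_W = 30, duration_s = 30,
                        cf_g = 10, irrigation_ml_min = 17,
                        blood_velocity_m_s = v, chamber = "atrium",
                        numerics = num)
    run_application(cfg, cal)
  })
  # stagnant blood chars: the application is cut short with a smaller lesion
  expect_identical(runs[[1]]$outcome, "charring")
  expect_lt(runs[[1]]$lesion$depth_D_mm, runs[[2]]$lesion$depth_D_mm)
  # among completed runs, more flow never deepens the lesion
  expect_identical(runs[[2]]$outcome, "safe")
  expect_identical(runs[[3]]$outcome, "safe")
  expect_lte(runs[[3]]$lesion$depth_D_mm, runs[[2]]$lesion$depth_D_mm)
})
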