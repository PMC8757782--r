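sweep_cfg <- function(...) {
  study_config(..., numerics = numerics_config(preset = "sweep"))
}

test_that("a zero-power protocol is safe with an empty lesion", {
  cfg <- sweep_cfg(tip = "spherical", power_W = 0, duration_s = 4,
                   cf_g = 5, irrigation_ml_min = 60,
                   blood_velocity_m_s = 0.1, chamber = "atrium")
  res <- run_application(cfg, default_cooling())
  expect_identical(res$outcome, "safe")
  expect_identical(res$lesion$volume_mm3, 0)
  expect_identical(res$delivered_energy_J, 0)
})

test_that("an application satisfies its structural invariants", {
  cfg <- sweep_cfg(tip = "cylindrical", power_W = 90, duration_s = 4,
                   cf_g = 5, irrigation_ml_min = 60,
                   blood_velocity_m_s = 0.1, chamber = "ventricle")
  res <- run_application(cfg, default_cooling())
  expect_true(res$outcome %in% c("safe", "pop", "charring"))
  expect_lte(res$delivered_energy_J,
             protocol_energy(cfg$protocol) + 1e-9)
  if (!is.na(res$event_time_s))
    expect_lte(res$event_time_s, cfg$protocol$duration_s)
  # running maximum dominates the final field
  expect_true(all(res$Tmax_final >= res$T_final - 1e-12))
  # thermal latency: the cumulative lesion is at least the power-off one
  expect_gte(res$lesion$volume_mm3, res$lesion_at_power_off$volume_mm3)
  # traces are per-step and monotone in time
  expect_true(all(diff(res$traces$t_s) > 0))
  # manifest echoes the configuration for provenance
  expect_identical(res$manifest$config$protocol$power_W, 90)
  expect_identical(res$manifest$calibration$shell_mm, 0.3)
})

test_that("per-step delivered power matches the setpoint to round-off", {
  # reconstruct the power from the reported applied voltage and current
  cfg <- sweep_cfg(tip = "spherical", power_W = 70, duration_s = 2,
                   cf_g = 5, irrigation_ml_min = 60,
                   blood_velocity_m_s = 0.1, chamber = "atrium")
  res <- run_application(cfg, default_cooling())
  tr <- res$traces[res$traces$phase == "heating", ]
  expect_true(all(abs(tr$applied_V * tr$current_A - 70) / 70 < 1e-8))
})

test_that("identical configurations give bit-identical traces", {
  cfg <- sweep_cfg(tip = "cylindrical", power_W = 80, duration_s = 3,
                   cf_g = 10, irrigation_ml_min = 30,
                   blood_velocity_m_s = 0.1, chamber = "ventricle")
  r1 <- run_application(cfg, default_cooling())
  r2 <- run_application(cfg, default_cooling())
  expect_identical(r1$traces, r2$traces)
  expect_identical(r1$lesion, r2$lesion)
})

test_that("halving the heating step leaves the lesion depth unchanged", {
  cal <- default_cooling()
  depth <- vapply(c(0.1, 0.05), function(dt) {
    num <- numerics_config(dt_heating_s = dt, dt_cooldown_s = 1,
                           mesh_h_min_m = 3e-4, mesh_h_max_m = 4e-3)
    cfg <- study_config(tip = "spherical", power_W = 90, duration_s = 4,
                        cf_g = 5, irrigation_ml_min = 60,
                        blood_velocity_m_s = 0.1, chamber = "atrium",
                        numerics = num)
    run_application(cfg, cal)$lesion$depth_D_mm
  }, numeric(1))
  expect_lt(abs(depth[2] - depth[1]) / depth[1], 0.01)
})

test_that("the global energy audit closes on a safe application", {
  cfg <- sweep_cfg(tip = "spherical", power_W = 90, duration_s = 4,
                   cf_g = 5, irrigation_ml_min = 60,
                   blood_velocity_m_s = 0.1, chamber = "atrium")
  res <- run_application(cfg, default_cooling(), audit = TRUE)
  expect_identical(res$outcome, "safe")
  expect_equal(res$delivered_energy_J, 360, tolerance = 1e-3)
  a <- res$audit
  # delivered energy = enthalpy change + film/sink/boundary losses
  closure <- a$E_in -
    (a$dH + a$robin_out + a$sink_out + a$dirichlet_out + a$return_out)
  expect_lt(abs(closure) / a$E_in, 0.02)
})

test_that("a popped application is cut short, cooled down and measured", {
  # high CF spherical tip in the atrium at modest irrigation pops
  cfg <- sweep_cfg(tip = "spherical", power_W = 90, duration_s = 4,
                   cf_g = 20, irrigation_ml_min = 60,
                   blood_velocity_m_s = 0.1, chamber = "atrium")
  res <- run_application(cfg, default_cooling())
  expect_identical(res$outcome, "pop")
  expect_lt(res$event_time_s, 4)
  expect_lt(res$delivered_energy_J, 360)
  expect_gt(res$lesion$volume_mm3, 0)  # partial lesion still reported
  expect_gte(res$event$peak_T_C, 97)
  expect_identical(res$event$kind, "pop")
  # power is zero after the event
  after <- res$traces$power_W[res$traces$t_s > res$event_time_s]
  expect_true(all(after == 0))
})

test_that("charring appears at the very beginning at low irrigation", {
  cfg <- sweep_cfg(tip = "spherical", power_W = 90, duration_s = 4,
                   cf_g = 10, irrigation_ml_min = 17,
                   blood_velocity_m_s = 0, chamber = "atrium")
  res <- run_application(cfg, default_cooling())
  expect_identical(res$outcome, "charring")
  expect_lt(res$event_time_s, 1)
  # charring event sits in the blood near the electrode / shaft junction
  expect_gte(res$event$peak_T_C, 80)
})
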