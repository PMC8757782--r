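# Shared expensive objects, computed once per test run.
.rfab_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.rfab_cache[[key]])) .rfab_cache[[key]] <- force(expr)
  .rfab_cache[[key]]
}

# Stage-1 cooling calibration on the two standard 30 W/30 s references.
acc_calibration <- function() cached("calibration", {
  suppressWarnings(calibrate_cooling(standard_references(),
                                     free = "h_substrate", reltol = 0.08))
})

# Standard atrial application run with the stage-1 calibration.
acc_standard_atrium <- function() cached("std_atrium", {
  run_application(standard_references()[[1]]$config, acc_calibration())
})

# The six step-B HPSD runs (no refit): spherical/atrium,
# cylindrical/ventricle, CF 5 g, 60 ml/min, low blood flow.
acc_hpsd_runs <- function() cached("hpsd", {
  cal <- acc_calibration()
  out <- list()
  for (ch in c("atrium", "ventricle")) {
    tip <- if (ch == "atrium") "spherical" else "cylindrical"
    for (p in hpsd_protocols()) {
      cfg <- study_config(tip = tip, power_W = p$power_W,
                          duration_s = p$duration_s, cf_g = 5,
                          irrigation_ml_min = 60, blood_velocity_m_s = 0.1,
                          chamber = ch,
                          numerics = numerics_config(preset = "coarse"))
      out[[paste(ch, p$name)]] <- run_application(cfg, cal)
    }
  }
  out
})

# Full factorial sweep at the sweep-grade numerics preset, with the
# shipped stage-1 calibration.
acc_sweep <- function() cached("sweep", {
  run_sweep(enumerate_sweep(sweep_grid()), default_cooling())
})

# Repeated-application table for 90 W/4 s in the ventricle.
acc_repeat <- function() cached("repeat", {
  repeat_study(protocols = list(ablation_protocol(90, 4)),
               intervals_s = c(2, 4, 6, 8, 10), chamber = "ventricle",
               calibration = acc_calibration(),
               numerics = numerics_config(preset = "coarse"))
})
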