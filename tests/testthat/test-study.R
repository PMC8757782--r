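test_that("sweep enumeration yields the full factorial in documented order", {
  g <- sweep_grid()
  expect_identical(sweep_size(g), 432L)
  cfgs <- enumerate_sweep(g)
  expect_length(cfgs, 432)
  fac <- attr(cfgs, "factors")
  # first factor (tip) varies fastest
  expect_identical(fac$tip[1:4], c("spherical", "cylindrical",
                                   "spherical", "cylindrical"))
  # keys are unique and count identity holds per stratum
  keys <- vapply(cfgs, rfablate:::sweep_key, character(1))
  expect_identical(anyDuplicated(keys), 0L)
  expect_identical(sum(fac$chamber == "atrium"), 216L)
  # singleton grid
  g1 <- sweep_grid(tips = "spherical", contact_forces_g = 5,
                   protocols = list(ablation_protocol(90, 4)),
                   irrigation_ml_min = 60, blood_velocities_m_s = 0.1,
                   chambers = "atrium")
  expect_length(enumerate_sweep(g1), 1)
  # the per-stratum denominator used in the safety tables
  g48 <- sweep_grid(irrigation_ml_min = 17, blood_velocities_m_s = 0)
  expect_identical(sweep_size(g48), 48L)
  expect_error(sweep_grid(tips = character(0)), "nonempty")
})

test_that("an empty configuration list gives an empty result", {
  sw <- run_sweep(list(), default_cooling())
  expect_s3_class(sw, "abl_sweep_result")
  expect_true(is.null(sw$rows) || nrow(sw$rows) == 0)
})

test_that("a journaled sweep resumes to the identical result", {
  g <- sweep_grid(tips = "spherical", contact_forces_g = c(5, 10),
                  protocols = list(ablation_protocol(90, 4)),
                  irrigation_ml_min = 60, blood_velocities_m_s = 0.1,
                  chambers = "atrium")
  cfgs <- enumerate_sweep(g)
  j <- tempfile(fileext = ".tsv")
  sw1 <- run_sweep(cfgs, default_cooling(), journal = j)
  expect_true(file.exists(j))
  # resume: the journal is replayed, results identical to the fresh run
  sw2 <- run_sweep(cfgs, default_cooling(), journal = j)
  expect_equal(sw2$rows$depth_D_mm, sw1$rows$depth_D_mm)
  expect_identical(sw2$rows$outcome, sw1$rows$outcome)
})

test_that("failed runs become error rows, never dropped", {
  g <- sweep_grid(tips = "spherical", contact_forces_g = 5,
                  protocols = list(ablation_protocol(90, 4)),
                  irrigation_ml_min = 60, blood_velocities_m_s = 0.1,
                  chambers = "atrium")
  cfgs <- enumerate_sweep(g)
  # sabotage the config so the run errors deep in the solver
  cfgs[[1]]$numerics$max_picard_iters <- 0L
  sw <- run_sweep(cfgs, default_cooling())
  expect_identical(nrow(sw$rows), 1L)
  expect_identical(sw$rows$outcome, "error")
  expect_true(nzchar(sw$rows$error))
})

test_that("safety summaries tally outcomes with printed denominators", {
  rows <- data.frame(
    tip = rep(c("spherical", "cylindrical"), each = 4),
    cf_g = 5, protocol = "90 W/4 s", irrigation_ml_min = 17,
    blood_velocity_m_s = 0, chamber = rep(c("atrium", "ventricle"), 4),
    outcome = c("safe", "pop", "charring", "safe", "pop", "pop",
                "charring", "safe"),
    stringsAsFactors = FALSE)
  sw <- structure(list(rows = rows), class = "abl_sweep_result")
  overall <- safety_summary(sw)
  expect_identical(overall$n, 8L)
  expect_equal(overall$pct_safe, 100 * 3 / 8)
  by_ch <- safety_summary(sw, "chamber")
  expect_identical(nrow(by_ch), 2L)
  expect_identical(sum(by_ch$n), 8L)
  # double-entry check: stratified counts re-sum to the overall table
  expect_identical(sum(by_ch$n_pop), overall$n_pop)
  expect_identical(sum(by_ch$n_charring), overall$n_charring)
  # per-stratum rates sum to one
  expect_equal(by_ch$pct_safe + by_ch$pct_pop + by_ch$pct_charring,
               c(100, 100))
  expect_error(safety_summary(sw, "speed"), "unknown strata")
})

test_that("protocol comparison normalizes to the reference", {
  m <- data.frame(protocol = c("30 W/30 s", "90 W/4 s"),
                  depth_D_mm = c(5.31, 2.97), width_W_mm = c(7.59, 6.20),
                  depth_at_width_DW_mm = c(1.5, 1.0),
                  volume_mm3 = c(160, 60))
  cmp <- compare_protocols(m, "30 W/30 s")
  ref_row <- cmp$percent[cmp$percent$protocol == "30 W/30 s", ]
  expect_equal(unlist(ref_row[-1]), rep(100, 4), ignore_attr = TRUE)
  # depth ratio of the printed values: about 56%, i.e. 40-60 % shallower
  expect_equal(cmp$percent$depth_D_mm[2], 100 * 2.97 / 5.31)
  expect_lt(cmp$percent$volume_mm3[2], 100)
  expect_error(compare_protocols(m, "80 W/6 s"), "not present")
  m0 <- m; m0$volume_mm3[1] <- 0
  expect_error(compare_protocols(m0, "30 W/30 s"), "zero")
})
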