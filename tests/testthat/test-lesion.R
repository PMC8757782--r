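test_that("an all-cold field yields an empty lesion", {
  mesh <- fixture_rect_mesh(8, 6, 0.25)
  lm <- extract_lesion(rep(37, nrow(mesh$nodes)), mesh)
  expect_identical(lm$depth_D_mm, 0)
  expect_identical(lm$width_W_mm, 0)
  expect_identical(lm$volume_mm3, 0)
})

test_that("hemisphere fixture metrics match the closed form", {
  mesh <- fixture_rect_mesh(8, 6, 0.1)
  f <- synthetic_field("hemisphere", r0_mm = 3)
  lm <- extract_lesion(synthetic_maxT(f, mesh), mesh)
  expect_equal(lm$depth_D_mm, 3, tolerance = 0.05 / 3)
  expect_equal(lm$width_W_mm, 6, tolerance = 0.05 / 6)
  expect_equal(lm$depth_at_width_DW_mm, 0, tolerance = 0.05)
  expect_equal(lm$volume_mm3, 2 / 3 * pi * 27, tolerance = 0.005)
})

test_that("half-ellipsoid fixture metrics match the closed form", {
  mesh <- fixture_rect_mesh(10, 6, 0.1)
  f <- synthetic_field("half_ellipsoid", a_mm = 4, b_mm = 2.5)
  lm <- extract_lesion(synthetic_maxT(f, mesh), mesh)
  expect_equal(lm$depth_D_mm, 2.5, tolerance = 0.02)
  expect_equal(lm$width_W_mm, 8, tolerance = 0.01)
  expect_equal(lm$depth_at_width_DW_mm, 0, tolerance = 0.05)
  expect_equal(lm$volume_mm3, 2 / 3 * pi * 16 * 2.5, tolerance = 0.005)
})

test_that("voxel oracle converges and matches the closed forms", {
  f <- synthetic_field("hemisphere", r0_mm = 3)
  bf <- brute_force_metrics(f, voxel_mm = 0.02)
  expect_equal(bf$volume_mm3, 2 / 3 * pi * 27, tolerance = 0.005)
  bf2 <- brute_force_metrics(f, voxel_mm = 0.01)
  expect_lt(abs(bf2$volume_mm3 - bf$volume_mm3) / bf$volume_mm3, 0.002)
  cold <- synthetic_field("gaussian", amp = 5)  # peaks at 42 C, below iso
  expect_identical(brute_force_metrics(cold)$volume_mm3, 0)
})

test_that("FE metrics agree with the voxel oracle on randomized fields", {
  mesh <- fixture_rect_mesh(10, 8, 0.08)
  set.seed(7)
  for (i in 1:20) {
    f <- synthetic_field("gaussian",
                         amp = runif(1, 25, 70),
                         sr_mm = runif(1, 1.2, 3.2),
                         sz_mm = runif(1, 1.0, 2.6),
                         z0_mm = runif(1, -1.5, 0.5))
    lm <- extract_lesion(synthetic_maxT(f, mesh), mesh)
    bf <- brute_force_metrics(f, r_max_mm = 10, z_min_mm = -8,
                              voxel_mm = 0.02)
    if (bf$volume_mm3 == 0) {
      expect_identical(lm$volume_mm3, 0)
      next
    }
    expect_equal(lm$volume_mm3, bf$volume_mm3, tolerance = 0.01)
    expect_lt(abs(lm$depth_D_mm - bf$depth_D_mm), 0.05)
    expect_lt(abs(lm$width_W_mm - bf$width_W_mm), 0.05)
  }
})

test_that("raising the isotherm never increases any metric", {
  mesh <- fixture_rect_mesh(10, 8, 0.12)
  f <- synthetic_field("gaussian", amp = 55, sr_mm = 2.5, sz_mm = 1.8)
  Tm <- synthetic_maxT(f, mesh)
  l50 <- extract_lesion(Tm, mesh, iso = 50)
  l60 <- extract_lesion(Tm, mesh, iso = 60)
  for (m in c("depth_D_mm", "width_W_mm", "depth_at_width_DW_mm",
              "volume_mm3")) {
    expect_lte(l60[[m]], l50[[m]])
  }
})

test_that("hemisphere metrics are mesh-independent under refinement", {
  f <- synthetic_field("hemisphere", r0_mm = 3)
  l1 <- extract_lesion(synthetic_maxT(f, fixture_rect_mesh(8, 6, 0.1)),
                       fixture_rect_mesh(8, 6, 0.1))
  l2 <- extract_lesion(synthetic_maxT(f, fixture_rect_mesh(8, 6, 0.05)),
                       fixture_rect_mesh(8, 6, 0.05))
  expect_lt(abs(l2$volume_mm3 - l1$volume_mm3) / l1$volume_mm3, 0.005)
  expect_lt(abs(l2$depth_D_mm - l1$depth_D_mm), 0.05)
})

test_that("a disconnected lesion is still measured and flagged", {
  mesh <- fixture_rect_mesh(10, 6, 0.1)
  r <- 1e3 * mesh$nodes[, 1]; z <- 1e3 * mesh$nodes[, 2]
  two <- 37 + 40 * exp(-((r - 1)^2 + (z + 1)^2) / 0.5) +
    40 * exp(-((r - 6)^2 + (z + 1)^2) / 0.5)
  lm <- extract_lesion(two, mesh)
  expect_gt(lm$volume_mm3, 0)
  expect_gte(lm$n_components, 2)
  # bounding-cylinder bound still holds
  expect_lte(lm$volume_mm3,
             pi / 4 * lm$width_W_mm^2 * max(lm$depth_D_mm, 2) + 1e-9)
})

test_that("complication monitors apply thresholds and the tie-break", {
  mesh <- fixture_rect_mesh(4, 4, 0.5)
  n <- nrow(mesh$nodes)
  th <- thresholds()
  shell <- 1:4; tissue <- 5:n
  mk <- function(tmax_tissue, tmax_shell) {
    T <- rep(37, n); T[tissue[1]] <- tmax_tissue; T[shell[1]] <- tmax_shell
    list(T = T, t = 1.5, mesh = mesh)
  }
  ev <- check_complications(mk(98, 60), th, shell, tissue)
  expect_equal(ev$kind, "pop")
  expect_equal(ev$peak_T_C, 98)
  ev2 <- check_complications(mk(90, 81), th, shell, tissue)
  expect_equal(ev2$kind, "charring")
  expect_null(check_complications(mk(96.9, 79.9), th, shell, tissue))
  # both crossed: larger overshoot wins; ties go to pop
  expect_equal(check_complications(mk(98, 83), th, shell, tissue)$kind,
               "charring")
  expect_equal(check_complications(mk(99, 81), th, shell, tissue)$kind, "pop")
  expect_equal(check_complications(mk(98, 81), th, shell, tissue)$kind, "pop")
})

test_that("outcome classification follows the completion rule", {
  expect_identical(classify_outcome(list(), completed = TRUE), "safe")
  ev <- structure(list(kind = "pop", time_s = 3.1), class = "abl_event")
  expect_identical(classify_outcome(list(ev), completed = FALSE), "pop")
  ev2 <- structure(list(kind = "charring", time_s = 0.4), class = "abl_event")
  expect_identical(classify_outcome(list(ev2), completed = FALSE), "charring")
  expect_error(classify_outcome(list(ev, ev2), completed = FALSE),
               "at most one")
  expect_error(classify_outcome(list(), completed = FALSE), "completed")
})

test_that("the lesion contour exports as a polyline table", {
  mesh <- fixture_rect_mesh(8, 6, 0.2)
  f <- synthetic_field("hemisphere", r0_mm = 3)
  path <- tempfile(fileext = ".tsv")
  df <- export_lesion_contour(synthetic_maxT(f, mesh), mesh, path)
  expect_true(file.exists(path))
  expect_true(all(c("segment", "r_mm", "z_mm") %in% names(df)))
  # contour points sit on the hemisphere of radius 3
  rho <- sqrt(df$r_mm^2 + df$z_mm^2)
  expect_lt(max(abs(rho - 3)), 0.15)
})
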