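test_that("insertion depth interpolates the table exactly and monotonically", {
  cm <- default_contact_model()
  expect_identical(insertion_depth(cm, 0, "spherical"), 0)
  expect_identical(insertion_depth(cm, 10, "cylindrical"), 0.7)
  expect_identical(insertion_depth(cm, 10, "spherical"), 0.7 + 7 / 12)
  # piecewise linear: midpoint of knots
  expect_equal(insertion_depth(cm, 7.5, "cylindrical"), (0.4 + 0.7) / 2)
  cfs <- seq(0, 20, by = 0.5)
  for (tip in c("spherical", "cylindrical")) {
    d <- insertion_depth(cm, cfs, tip)
    expect_true(all(diff(d) > 0))
  }
  expect_error(insertion_depth(cm, 25, "spherical"), "extrapolation")
  expect_error(insertion_depth(cm, -1, "spherical"), ">= 0")
})

test_that("contact areas match the closed forms", {
  R <- 7 / 6
  cyl <- electrode_spec("cylindrical")
  sph <- electrode_spec("spherical")
  # flat base touches fully at zero depth; tangent sphere touches a point
  expect_equal(contact_area(cyl, 0)$tissue_contact_mm2, pi * R^2)
  expect_identical(contact_area(sph, 0)$tissue_contact_mm2, 0)
  # submerged hemisphere: cap area 2 pi R h with h = R
  expect_equal(contact_area(sph, R)$tissue_contact_mm2, 2 * pi * R^2)
  expect_error(contact_area(sph, 4), "tip_length")
})

test_that("contact areas agree with numerical surface integration", {
  R <- 7 / 6
  sph <- electrode_spec("spherical")
  cyl <- electrode_spec("cylindrical")
  # lateral area of revolution: 2 pi int r(s) ds along the submerged profile
  for (d in c(0.4, 0.9, 1.6)) {
    if (d <= R) {
      # cap: parametrize by polar angle from the bottom pole
      th_max <- acos((R - d) / R)
      th <- seq(0, th_max, length.out = 20001)
      r <- R * sin(th)
      ds <- R * diff(th)
      a_num <- sum(2 * pi * (r[-1] + r[-length(r)]) / 2 * ds)
    } else {
      th <- seq(0, pi / 2, length.out = 20001)
      ds <- R * diff(th)
      r <- R * sin(th)
      a_num <- sum(2 * pi * (r[-1] + r[-length(r)]) / 2 * ds) +
        2 * pi * R * (d - R)
    }
    expect_equal(contact_area(sph, d)$tissue_contact_mm2, a_num,
                 tolerance = 1e-3)
    expect_equal(contact_area(cyl, d)$tissue_contact_mm2,
                 pi * R^2 + 2 * pi * R * d, tolerance = 1e-12)
  }
})

test_that("tissue-contact areas cross over at 10 g", {
  cm <- default_contact_model()
  sph <- electrode_spec("spherical")
  cyl <- electrode_spec("cylindrical")
  area <- function(tip_obj, tip_name, cf) {
    contact_area(tip_obj, insertion_depth(cm, cf, tip_name))$tissue_contact_mm2
  }
  for (cf in c(2, 5, 8, 9.5)) {
    expect_lt(area(sph, "spherical", cf), area(cyl, "cylindrical", cf))
  }
  expect_equal(area(sph, "spherical", 10), area(cyl, "cylindrical", 10),
               tolerance = 1e-12)
  for (cf in c(10.5, 12, 15, 20)) {
    expect_gt(area(sph, "spherical", cf), area(cyl, "cylindrical", cf))
  }
})

test_that("geometry partitions the domain and respects the datum", {
  geom <- build_geometry(electrode_spec("spherical"), chamber_spec("atrium"),
                         depth_mm = 0.5)
  # every sampled point belongs to exactly one region
  set.seed(42)
  r <- runif(4000, 0, 0.039); z <- runif(4000, -0.0059, 0.019)
  reg <- geom$classify(r, z)
  expect_true(all(reg %in% 1:4))
  # tissue occupies z <= 0 outside the electrode: axial extent [-6, 0] mm
  expect_true(all(reg[z > 0 & r > 2e-3] == 2))       # blood far from shaft
  expect_true(all(reg[z < -1e-3 & r > 2e-3] == 1))   # tissue below datum
  expect_equal(geom$undeformed_surface_z, 0)
  expect_error(build_geometry(electrode_spec("spherical"),
                              chamber_spec("atrium"), depth_mm = 6),
               "wall thickness")
  # ventricle: 12 mm wall, cylindrical tip, shaft sits in the blood region
  gv <- build_geometry(electrode_spec("cylindrical"),
                       chamber_spec("ventricle"), depth_mm = 1)
  expect_equal(gv$wall_m, 0.012)
  expect_equal(gv$classify(0.5e-3, 5e-3), 4L)  # shaft column above the tip
  expect_equal(gv$classify(0.5e-3, -1.5e-3), 1L)
})

test_that("mesh generation grades, tags and refines as configured", {
  geom <- build_geometry(electrode_spec("cylindrical"), chamber_spec("atrium"),
                         depth_mm = 0.7)
  num <- numerics_config(preset = "sweep")
  mesh <- generate_mesh(geom, num)
  expect_true(all(mesh$nodes[, 1] >= 0))
  expect_true(all(mesh$area > 0))
  tags <- unique(mesh$facets$tag)
  for (needed in c(1, 2, 3, 4, 5, 6, 7)) expect_true(needed %in% tags)
  # every electrode-adjacent element is at the fine size
  f <- mesh$facets
  el <- f$tag %in% c(1, 2)
  expect_lte(max(f$length[el]), num$mesh_h_min_m * 1.6)
  # halving both bounds at least triples the element count
  num2 <- numerics_config(dt_heating_s = num$dt_heating_s,
                          dt_cooldown_s = num$dt_cooldown_s,
                          mesh_h_min_m = num$mesh_h_min_m / 2,
                          mesh_h_max_m = num$mesh_h_max_m / 2)
  mesh2 <- generate_mesh(geom, num2)
  expect_gte(nrow(mesh2$tri), 3 * nrow(mesh$tri))
  # degenerate grading: h_min = h_max gives a quasi-uniform mesh
  numu <- numerics_config(mesh_h_min_m = 1e-3, mesh_h_max_m = 1e-3)
  meshu <- generate_mesh(geom, numu)
  expect_lt(max(meshu$area) / min(meshu$area), 8)
})

test_that("mesh export writes a parsable interchange file", {
  geom <- build_geometry(electrode_spec("spherical"), chamber_spec("atrium"), 0.5)
  mesh <- generate_mesh(geom, numerics_config(preset = "sweep"))
  f <- tempfile(fileext = ".msh")
  write_mesh_msh(mesh, f, field = rep(37, nrow(mesh$nodes)))
  lines <- readLines(f)
  expect_true("$MeshFormat" %in% lines)
  expect_equal(as.integer(lines[which(lines == "$Nodes") + 1]),
               nrow(mesh$nodes))
  expect_true("$NodeData" %in% lines)
})
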