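# Analytic oracles and synthetic fields: every oracle here is an
# independent implementation (closed form or dense enumeration), sharing
# no code path with the solver or metric extraction it checks.

#' Uniform rectangular tissue-region mesh
#'
#' Axisymmetric rectangle `r in [0, r_max]`, `z in [-depth, 0]`, tagged
#' entirely as tissue — a plain canvas for synthetic-field and conduction
#' fixtures.
#'
#' @param r_max_mm radial extent, mm.
#' @param depth_mm axial extent below the datum, mm.
#' @param h_mm target element size, mm.
#' @param z_top_mm upper axial bound, mm (default 0).
#' @return An `abl_mesh`.
#' @export
fixture_rect_mesh <- function(r_max_mm = 10, depth_mm = 8, h_mm = 0.25,
                              z_top_mm = 0) {
  rs <- seq(0, r_max_mm, by = h_mm) * 1e-3
  zs <- seq(-depth_mm, z_top_mm, by = h_mm) * 1e-3
  nr <- length(rs); nz <- length(zs)
  nodes <- cbind(rep(rs, nz), rep(zs, each = nr))
  id <- function(ir, iz) (iz - 1L) * nr + ir
  ir <- rep(seq_len(nr - 1L), nz - 1L)
  iz <- rep(seq_len(nz - 1L), each = nr - 1L)
  a <- id(ir, iz); b <- id(ir + 1L, iz); c_ <- id(ir, iz + 1L)
  d <- id(ir + 1L, iz + 1L)
  tri <- rbind(cbind(a, b, d), cbind(a, d, c_))
  finalize_mesh(nodes, tri, rep(REG_TISSUE, nrow(tri)),
                h_min = h_mm * 1e-3, h_max = h_mm * 1e-3)
}

#' Steady 1D slab conduction fixture
#'
#' A slab held at fixed temperatures on its two faces reaches the linear
#' steady profile `T(z) = T_left + (T_right - T_left) * z / thickness`.
#' Returns the analytic solution, a mesh and the boundary sets needed to
#' reproduce it with [thermal_system()] / [step_temperature()].
#'
#' @param thickness_mm slab thickness, mm.
#' @param T_left temperature at `z = -thickness` (bottom), degrees C.
#' @param T_right temperature at `z = 0` (top), degrees C.
#' @param h_mm mesh size, mm.
#' @param r_max_mm radial extent of the modeled slab, mm.
#' @return List with `mesh`, `analytic(z_m)`, `bottom_nodes`, `top_nodes`,
#'   `dirichlet_nodes`, `dirichlet_values`.
#' @export
slab_steady_fixture <- function(thickness_mm = 6, T_left = 80, T_right = 37,
                                h_mm = 0.4, r_max_mm = 3) {
  stopifnot(thickness_mm > 0)
  mesh <- fixture_rect_mesh(r_max_mm, thickness_mm, h_mm)
  th <- thickness_mm * 1e-3
  analytic <- function(z_m) T_left + (T_right - T_left) * (z_m + th) / th
  zb <- min(mesh$nodes[, 2]); zt <- max(mesh$nodes[, 2])
  bottom <- which(abs(mesh$nodes[, 2] - zb) < 1e-12)
  top <- which(abs(mesh$nodes[, 2] - zt) < 1e-12)
  list(mesh = mesh, analytic = analytic, bottom_nodes = bottom,
       top_nodes = top,
       dirichlet_nodes = c(bottom, top),
       dirichlet_values = c(rep(T_left, length(bottom)),
                            rep(T_right, length(top))))
}

#' Concentric-spheres resistance fixture
#'
#' A conducting spherical shell between radii `a` and `b` has conductance
#' `G = 4 pi sigma a b / (b - a)` (closed form). Returns the analytic
#' conductance and a polar-structured axisymmetric mesh of the shell with
#' the inner/outer Dirichlet node sets for [solve_potential()]: with 1 V
#' applied the computed raw power equals G.
#'
#' @param a_mm,b_mm inner and outer radii, mm (`0 < a < b`).
#' @param sigma conductivity, S/m.
#' @param n_rho,n_theta mesh resolution in radius and polar angle.
#' @return List with `mesh`, `conductance` (S), `inner_nodes`,
#'   `outer_nodes`.
#' @export
spherical_resistance_fixture <- function(a_mm = 2, b_mm = 8, sigma = 0.5,
                                         n_rho = 60, n_theta = 90) {
  stopifnot(a_mm > 0, b_mm > a_mm)
  a <- a_mm * 1e-3; b <- b_mm * 1e-3
  G <- 4 * pi * sigma * a * b / (b - a)
  # grade rho as 1/rho (equipotentials uniform in 1/rho)
  u <- seq(1 / a, 1 / b, length.out = n_rho + 1L)
  rho <- 1 / u
  th <- seq(0, pi, length.out = n_theta + 1L)
  nr <- length(rho); nt <- length(th)
  R <- outer(rho, sin(th))  # nr x nt
  Z <- outer(rho, cos(th))
  nodes <- cbind(as.vector(R), as.vector(Z))
  id <- function(i, j) (j - 1L) * nr + i
  i <- rep(seq_len(nr - 1L), nt - 1L)
  j <- rep(seq_len(nt - 1L), each = nr - 1L)
  aid <- id(i, j); bid <- id(i + 1L, j); cid <- id(i, j + 1L)
  did <- id(i + 1L, j + 1L)
  tri <- rbind(cbind(aid, bid, did), cbind(aid, did, cid))
  # drop zero-area triangles on the axis (sin(theta) = 0 edges)
  keep <- abs((nodes[tri[, 2], 1] - nodes[tri[, 1], 1]) *
                (nodes[tri[, 3], 2] - nodes[tri[, 1], 2]) -
              (nodes[tri[, 3], 1] - nodes[tri[, 1], 1]) *
                (nodes[tri[, 2], 2] - nodes[tri[, 1], 2])) > 1e-18
  tri <- tri[keep, , drop = FALSE]
  mesh <- finalize_mesh(nodes, tri, rep(REG_TISSUE, nrow(tri)),
                        compute_facets = FALSE)
  rad <- sqrt(mesh$nodes[, 1]^2 + mesh$nodes[, 2]^2)
  inner <- which(abs(rad - a) < 1e-9)
  outer_ <- which(abs(rad - b) < 1e-9)
  list(mesh = mesh, conductance = G, inner_nodes = inner,
       outer_nodes = outer_)
}

#' Synthetic closed-form maximum-temperature fields
#'
#' Pointwise descriptors whose 50 degree isotherm geometry is known in
#' closed form, used as oracles for lesion-metric extraction:
#' \describe{
#'   \item{hemisphere}{`T = max(floor, peak - (peak - iso) * rho / r0)`
#'     with `rho` the distance from the surface origin: the isotherm is
#'     the hemisphere of radius `r0`, volume `(2/3) pi r0^3`.}
#'   \item{half_ellipsoid}{same with `rho` replaced by the elliptical
#'     radius `sqrt((r/a)^2 + (z/b)^2)`: half-ellipsoid of semi-axes
#'     `(a, a, b)`, volume `(2/3) pi a^2 b`.}
#'   \item{gaussian}{`T = floor + amp * exp(-r^2/(2 sr^2) - (z - z0)^2 /
#'     (2 sz^2))`: a smooth bump whose isotherm is a (half-clipped)
#'     ellipse.}
#' }
#'
#' @param kind `"hemisphere"`, `"half_ellipsoid"` or `"gaussian"`.
#' @param r0_mm hemisphere radius, mm.
#' @param a_mm,b_mm ellipsoid semi-axes (radial, axial), mm.
#' @param amp,sr_mm,sz_mm,z0_mm gaussian parameters.
#' @param peak,floor field extremes, degrees C.
#' @param iso isotherm the descriptor is designed around, degrees C.
#' @return An object of class `abl_synthetic_field` with a vectorized
#'   `fn(r_mm, z_mm)` and, where closed-form, `analytic` metrics.
#' @export
synthetic_field <- function(kind = c("hemisphere", "half_ellipsoid",
                                     "gaussian"),
                            r0_mm = 3, a_mm = 4, b_mm = 2.5,
                            amp = 40, sr_mm = 2, sz_mm = 1.5, z0_mm = 0,
                            peak = 100, floor = 37, iso = 50) {
  kind <- match.arg(kind)
  slope <- peak - iso
  fn <- switch(kind,
    hemisphere = function(r_mm, z_mm) {
      rho <- sqrt(r_mm^2 + z_mm^2)
      pmax(floor, peak - slope * rho / r0_mm)
    },
    half_ellipsoid = function(r_mm, z_mm) {
      s <- sqrt((r_mm / a_mm)^2 + (z_mm / b_mm)^2)
      pmax(floor, peak - slope * s)
    },
    gaussian = function(r_mm, z_mm) {
      floor + amp * exp(-r_mm^2 / (2 * sr_mm^2) -
                          (z_mm - z0_mm)^2 / (2 * sz_mm^2))
    })
  analytic <- switch(kind,
    hemisphere = list(depth_D_mm = r0_mm, width_W_mm = 2 * r0_mm,
                      depth_at_width_DW_mm = 0,
                      volume_mm3 = 2 / 3 * pi * r0_mm^3),
    half_ellipsoid = list(depth_D_mm = b_mm, width_W_mm = 2 * a_mm,
                          depth_at_width_DW_mm = 0,
                          volume_mm3 = 2 / 3 * pi * a_mm^2 * b_mm),
    gaussian = NULL)
  structure(list(kind = kind, fn = fn, analytic = analytic, iso = iso),
            class = "abl_synthetic_field")
}

#' Evaluate a synthetic field on a mesh
#'
#' @param field an [synthetic_field()].
#' @param mesh an `abl_mesh`.
#' @return Nodal values, degrees C.
#' @export
synthetic_maxT <- function(field, mesh) {
  stopifnot(inherits(field, "abl_synthetic_field"), inherits(mesh, "abl_mesh"))
  field$fn(1e3 * mesh$nodes[, 1], 1e3 * mesh$nodes[, 2])
}

#' Brute-force lesion metrics by dense voxel enumeration
#'
#' Independent oracle for [extract_lesion()]: evaluates the descriptor on
#' a dense (r, z) grid of voxel centers restricted to the tissue half
#' `z <= 0`, sums the axisymmetric volume `2 pi r dr dz` over voxels at
#' or above the isotherm and reads the extrema off the mask (with
#' half-voxel boundary correction). Shares no code with the
#' finite-element metric path.
#'
#' @param field an [synthetic_field()].
#' @param iso isotherm, degrees C.
#' @param r_max_mm,z_min_mm grid extents, mm.
#' @param voxel_mm voxel edge, mm (convergence documented at <= 0.02).
#' @return List with `depth_D_mm`, `width_W_mm`, `depth_at_width_DW_mm`,
#'   `volume_mm3`.
#' @export
brute_force_metrics <- function(field, iso = 50, r_max_mm = 10,
                                z_min_mm = -10, voxel_mm = 0.02) {
  stopifnot(inherits(field, "abl_synthetic_field"), voxel_mm > 0)
  rc <- seq(voxel_mm / 2, r_max_mm - voxel_mm / 2, by = voxel_mm)
  zc <- seq(z_min_mm + voxel_mm / 2, -voxel_mm / 2, by = voxel_mm)
  vol <- 0
  minz <- Inf; maxr <- -Inf; z_at_maxr <- NA_real_
  # stream over z rows to bound memory
  for (z in zc) {
    vals <- field$fn(rc, rep(z, length(rc)))
    inside <- vals >= iso
    if (!any(inside)) next
    vol <- vol + sum(2 * pi * rc[inside]) * voxel_mm^2
    minz <- min(minz, z)
    mr <- max(rc[inside])
    if (mr > maxr + 1e-12) {
      maxr <- mr
      z_at_maxr <- z
    } else if (abs(mr - maxr) <= 1e-12) {
      z_at_maxr <- z  # tie on the grid: keep the shallowest row
    }
  }
  if (!is.finite(maxr))
    return(list(depth_D_mm = 0, width_W_mm = 0, depth_at_width_DW_mm = 0,
                volume_mm3 = 0))
  list(depth_D_mm = -(minz) + voxel_mm / 2,
       width_W_mm = 2 * (maxr + voxel_mm / 2),
       depth_at_width_DW_mm = max(0, -z_at_maxr - voxel_mm / 2),
       volume_mm3 = vol)
}
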