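#' Build the deformed axisymmetric geometry
#'
#' Lays out the (r, z) half-plane domain for one application: tissue slab
#' of the chamber's wall thickness below the undeformed endocardial datum
#' z = 0, blood compartment above, electrode tip inserted to the given
#' depth, insulating catheter shaft above the metal tip. The tissue
#' surface conforms to the electrode over the indented footprint and
#' returns to z = 0 immediately outside it (zero-width fillet).
#'
#' The datum plane z = 0 is fixed at the undeformed endocardial surface
#' regardless of contact force; depths are reported as positive distances
#' below it.
#'
#' @param electrode an [electrode_spec()].
#' @param chamber a [chamber_spec()].
#' @param depth_mm electrode insertion depth, mm (must be below the wall
#'   thickness).
#' @param domain_radius_mm radial far-field extent, mm.
#' @param blood_height_mm axial extent of the blood compartment, mm.
#' @return An object of class `abl_geometry` with a vectorized region
#'   classifier, key coordinates and closed-form contact areas.
#' @export
build_geometry <- function(electrode, chamber, depth_mm,
                           domain_radius_mm = 40, blood_height_mm = 20) {
  stopifnot(inherits(electrode, "abl_electrode"), inherits(chamber, "abl_chamber"))
  if (depth_mm < 0) stop("insertion depth must be >= 0", call. = FALSE)
  if (depth_mm >= chamber$wall_thickness_mm)
    stop("insertion depth must be below the wall thickness", call. = FALSE)
  R <- electrode$diameter_mm / 2 * 1e-3
  if (R >= domain_radius_mm * 1e-3)
    stop("electrode wider than the domain", call. = FALSE)
  L <- electrode$tip_length_mm * 1e-3
  d <- depth_mm * 1e-3
  z_tip <- -d                 # lowest electrode point
  z_top <- L - d              # metal / shaft junction
  wall <- chamber$wall_thickness_mm * 1e-3
  shape <- electrode$tip_shape
  zc <- if (shape == "spherical") R - d else NA_real_

  classify <- function(r, z) {
    out <- integer(length(r))
    if (shape == "spherical") {
      in_metal <- (r <= R & z >= zc & z <= z_top) |
        (z < zc & (r^2 + (z - zc)^2) <= R^2)
    } else {
      in_metal <- r <= R & z >= z_tip & z <= z_top
    }
    in_shaft <- r <= R & z > z_top
    out[in_metal] <- REG_ELECTRODE
    out[!in_metal & in_shaft] <- REG_SHAFT
    out[!in_metal & !in_shaft & z <= 0] <- REG_TISSUE
    out[out == 0L] <- REG_BLOOD
    out
  }
  areas <- contact_area(electrode, depth_mm)
  structure(list(electrode = electrode, chamber = chamber,
                 insertion_depth_mm = depth_mm,
                 undeformed_surface_z = 0,
                 contact_area_mm2 = areas$tissue_contact_mm2,
                 blood_exposed_area_mm2 = areas$blood_exposed_mm2,
                 R_m = R, z_tip_m = z_tip, z_top_m = z_top,
                 zc_m = zc, wall_m = wall,
                 domain_radius_m = domain_radius_mm * 1e-3,
                 blood_height_m = blood_height_mm * 1e-3,
                 classify = classify),
            class = "abl_geometry")
}

#' @export
print.abl_geometry <- function(x, ...) {
  cat(sprintf("<abl_geometry> %s tip, depth %.2f mm, %s wall %.0f mm\n",
              x$electrode$tip_shape, x$insertion_depth_mm,
              x$chamber$chamber, 1e3 * x$wall_m))
  cat(sprintf("  contact %.2f mm^2 tissue / %.2f mm^2 blood-exposed\n",
              x$contact_area_mm2, x$blood_exposed_area_mm2))
  invisible(x)
}

# Graded 1D coordinate array: uniform spacing h_min inside
# [fine_lo, fine_hi], geometric growth (factor `growth`) capped at h_max
# outside, covering [lo, hi] with exact endpoints.
graded_coords <- function(lo, hi, fine_lo, fine_hi, h_min, h_max,
                          growth = 1.35) {
  fine_lo <- max(lo, fine_lo); fine_hi <- min(hi, fine_hi)
  nf <- max(1L, ceiling((fine_hi - fine_lo) / h_min))
  xs <- seq(fine_lo, fine_hi, length.out = nf + 1L)
  grow <- function(from, to) {
    # geometric steps from |from| towards `to` (to > from direction +1)
    if (abs(to - from) < 1e-12) return(numeric(0))
    s <- sign(to - from)
    h <- h_min
    pts <- numeric(0)
    x <- from
    repeat {
      h <- min(h * growth, h_max)
      x <- x + s * h
      if ((to - x) * s <= h * 0.4) break
      pts <- c(pts, x)
    }
    c(pts, to)
  }
  up <- grow(fine_hi, hi)
  down <- grow(fine_lo, lo)
  sort(unique(c(rev(down), xs, up)))
}

# Shift the grid point nearest to each target coordinate onto it.
snap_coords <- function(xs, targets) {
  for (t in targets) {
    if (t < min(xs) - 1e-12 || t > max(xs) + 1e-12) next
    i <- which.min(abs(xs - t))
    xs[i] <- t
  }
  sort(unique(xs))
}

#' Generate the graded axisymmetric mesh
#'
#' Builds a structured, graded triangulation of the geometry: uniform
#' spacing `mesh_h_min_m` in a window around the electrode and the
#' prospective lesion, geometric coarsening to `mesh_h_max_m` towards the
#' far field. Grid lines are snapped to the electrode radius, the datum
#' plane, the tip apex and the metal/shaft junction so the cylindrical
#' interfaces are mesh-conforming (the spherical cap is resolved at
#' `h_min`). Elements are tagged by region through the geometry
#' classifier at centroids; the mesh is deterministic for a given
#' geometry and numerics.
#'
#' @param geom an [build_geometry()] result.
#' @param num a [numerics_config()].
#' @return An `abl_mesh`.
#' @export
generate_mesh <- function(geom, num) {
  stopifnot(inherits(geom, "abl_geometry"), inherits(num, "abl_numerics"))
  h <- num$mesh_h_min_m
  H <- num$mesh_h_max_m
  R <- geom$R_m
  # fine window: radially past the expected lesion width, axially from
  # most of the wall to just above the metal/shaft junction
  r_fine <- R + 4.5e-3
  z_fine_lo <- -min(geom$wall_m, geom$insertion_depth_mm * 1e-3 + 6.2e-3)
  z_fine_hi <- geom$z_top_m + 1.0e-3
  rs <- graded_coords(0, geom$domain_radius_m, 0, r_fine, h, H)
  zs <- graded_coords(-geom$wall_m, geom$blood_height_m, z_fine_lo,
                      z_fine_hi, h, H)
  rs <- snap_coords(rs, R)
  zs <- snap_coords(zs, c(0, geom$z_tip_m, geom$z_top_m,
                          if (!is.na(geom$zc_m)) geom$zc_m))
  nr <- length(rs); nz <- length(zs)
  nodes <- cbind(rep(rs, nz), rep(zs, each = nr))
  id <- function(ir, iz) (iz - 1L) * nr + ir
  ir <- rep(seq_len(nr - 1L), nz - 1L)
  iz <- rep(seq_len(nz - 1L), each = nr - 1L)
  a <- id(ir, iz); b <- id(ir + 1L, iz); c_ <- id(ir, iz + 1L)
  d <- id(ir + 1L, iz + 1L)
  tri <- rbind(cbind(a, b, d), cbind(a, d, c_))
  cent_r <- (nodes[tri[, 1], 1] + nodes[tri[, 2], 1] + nodes[tri[, 3], 1]) / 3
  cent_z <- (nodes[tri[, 1], 2] + nodes[tri[, 2], 2] + nodes[tri[, 3], 2]) / 3
  region <- geom$classify(cent_r, cent_z)
  finalize_mesh(nodes, tri, region, h_min = h, h_max = H, geom = geom)
}
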