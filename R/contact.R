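#' Contact-force to insertion-depth mapping
#'
#' The full elastic contact problem is replaced by a parametric,
#' monotone piecewise-linear table mapping contact force (grams) to
#' electrode insertion depth (mm), one table per tip shape. Interpolation
#' is exact at the knots; extrapolation beyond the table range is refused.
#'
#' @param spherical named numeric vector: names are contact forces in
#'   grams, values insertion depths in mm. Must include 0 -> 0 and be
#'   strictly increasing.
#' @param cylindrical same, for the cylindrical tip.
#' @return An object of class `abl_contact_model`.
#' @seealso [default_contact_model()] for the calibrated default table.
#' @export
contact_model <- function(spherical, cylindrical) {
  check_tab <- function(tab, lbl) {
    cf <- as.numeric(names(tab))
    if (anyNA(cf)) stop("contact_model: names must be numeric CF values",
                        call. = FALSE)
    o <- order(cf)
    cf <- cf[o]; d <- as.numeric(tab)[o]
    if (cf[1] != 0 || d[1] != 0)
      stop("contact_model (", lbl, "): table must start at 0 g -> 0 mm",
           call. = FALSE)
    if (any(diff(cf) <= 0) || any(diff(d) <= 0))
      stop("contact_model (", lbl, "): depth must be strictly increasing in CF",
           call. = FALSE)
    list(cf = cf, depth = d)
  }
  structure(list(spherical = check_tab(spherical, "spherical"),
                 cylindrical = check_tab(cylindrical, "cylindrical")),
            class = "abl_contact_model")
}

#' Default contact model
#'
#' Default CF-to-depth tables for the 7 Fr tips. The cylindrical table is
#' 0.4/0.7/1.0/1.3 mm at 5/10/15/20 g; the spherical table is deeper at
#' equal force (a rounded tip concentrates the load) and is set so that
#' the tissue-contact areas of the two tips cross over exactly at 10 g:
#' the spherical cap area 2*pi*R*depth is smaller than the cylindrical
#' base-plus-band area below 10 g and larger above it.
#'
#' @return An `abl_contact_model`.
#' @export
default_contact_model <- function() {
  # spherical 10 g knot = cylindrical depth + R/2 (area crossover), R = 7/6 mm
  contact_model(
    spherical = c("0" = 0, "5" = 0.90, "10" = 0.7 + 7 / 12, "15" = 1.70,
                  "20" = 2.10),
    cylindrical = c("0" = 0, "5" = 0.40, "10" = 0.70, "15" = 1.00,
                    "20" = 1.30))
}

#' Insertion depth for a given contact force
#'
#' @param cm an [contact_model()].
#' @param cf_g contact force, grams.
#' @param tip `"spherical"` or `"cylindrical"`.
#' @return Insertion depth in mm.
#' @export
insertion_depth <- function(cm, cf_g, tip = c("spherical", "cylindrical")) {
  stopifnot(inherits(cm, "abl_contact_model"))
  tip <- match.arg(tip)
  tab <- cm[[tip]]
  if (any(cf_g < 0)) stop("contact force must be >= 0 g", call. = FALSE)
  if (any(cf_g > max(tab$cf)))
    stop(sprintf("contact force %g g above table range (max %g g); no extrapolation",
                 max(cf_g), max(tab$cf)), call. = FALSE)
  approx(tab$cf, tab$depth, xout = cf_g, method = "linear", ties = "ordered")$y
}

#' Electrode-tissue and electrode-blood contact areas
#'
#' Closed-form wetted areas of the inserted tip. For a spherical tip at
#' insertion depth d the tissue-contact area is the submerged spherical
#' cap (continued as a barrel band past the hemisphere), 2*pi*R*d; at
#' d = 0 the sphere touches at a point. For a cylindrical tip the flat
#' base always touches, so the contact is pi*R^2 + 2*pi*R*d. The
#' blood-exposed area is the remaining lateral tip surface 2*pi*R*(L-d).
#'
#' @param tip an [electrode_spec()].
#' @param depth_mm insertion depth, mm; must lie in `[0, tip_length]`.
#' @return List with `tissue_contact_mm2` and `blood_exposed_mm2`.
#' @export
contact_area <- function(tip, depth_mm) {
  stopifnot(inherits(tip, "abl_electrode"))
  if (any(depth_mm < 0) || any(depth_mm > tip$tip_length_mm))
    stop("depth must lie within [0, tip_length]", call. = FALSE)
  R <- tip$diameter_mm / 2
  L <- tip$tip_length_mm
  if (tip$tip_shape == "spherical") {
    tissue <- 2 * pi * R * depth_mm
  } else {
    tissue <- pi * R^2 + 2 * pi * R * depth_mm
  }
  list(tissue_contact_mm2 = tissue,
       blood_exposed_mm2 = 2 * pi * R * (L - depth_mm))
}
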