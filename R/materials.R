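#' Material properties with linear temperature dependence
#'
#' Describes one material (myocardium, blood, electrode metal, catheter
#' body) by its density and by reference values of specific heat, thermal
#' conductivity and electrical conductivity together with linear
#' temperature coefficients. Specific heat varies by an absolute slope
#' (J/(kg K) per degree C, negative for tissue), while thermal and
#' electrical conductivity vary by fractional slopes (1/degree C):
#' \deqn{c(T) = c_{ref} + s_c (T - T_{ref})}
#' \deqn{k(T) = k_{ref} (1 + s_k (T - T_{ref}))}
#' \deqn{\sigma(T) = \sigma_{ref} (1 + s_\sigma (T - T_{ref}))}
#'
#' Validation rejects slopes that drive any evaluated property
#' non-positive anywhere on the simulated range 20-110 degrees C.
#'
#' @param rho density, kg/m^3.
#' @param c_ref specific heat at `T_ref`, J/(kg K).
#' @param k_ref thermal conductivity at `T_ref`, W/(m K).
#' @param sigma_ref electrical conductivity at `T_ref`, S/m.
#' @param T_ref reference temperature, degrees C.
#' @param c_slope absolute specific-heat slope, J/(kg K)/degree C.
#' @param k_frac_slope fractional thermal-conductivity slope, 1/degree C.
#' @param sigma_frac_slope fractional electrical-conductivity slope,
#'   1/degree C.
#' @param name optional material label.
#' @return An object of class `abl_material`.
#' @examples
#' myo <- material_properties(1081, 3686, 0.56, 0.54,
#'                            c_slope = -0.42, k_frac_slope = -5e-4,
#'                            sigma_frac_slope = 1.5e-3)
#' property_at(myo, 57)
#' @export
material_properties <- function(rho, c_ref, k_ref, sigma_ref, T_ref = 37,
                                c_slope = 0, k_frac_slope = 0,
                                sigma_frac_slope = 0, name = NULL) {
  m <- structure(list(rho = rho, c_ref = c_ref, k_ref = k_ref,
                      sigma_ref = sigma_ref, T_ref = T_ref,
                      c_slope = c_slope, k_frac_slope = k_frac_slope,
                      sigma_frac_slope = sigma_frac_slope,
                      name = name %||% "material"),
                 class = "abl_material")
  validate_material(m)
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_material <- function(m) {
  lbl <- m$name
  for (f in c("rho", "c_ref", "k_ref", "sigma_ref")) {
    if (!is.numeric(m[[f]]) || length(m[[f]]) != 1 || !is.finite(m[[f]]) ||
        m[[f]] <= 0) {
      stop(sprintf("material '%s': field '%s' must be a positive number",
                   lbl, f), call. = FALSE)
    }
  }
  # positivity of evaluated properties over the simulated range
  Ts <- c(20, 110)
  p <- property_at(m, Ts)
  if (any(p$c <= 0) || any(p$k <= 0) || any(p$sigma <= 0)) {
    stop(sprintf(paste0("material '%s': temperature slopes drive a ",
                        "property non-positive within 20-110 degrees C"),
                 lbl), call. = FALSE)
  }
  invisible(m)
}

#' Evaluate temperature-dependent material properties
#'
#' Evaluates the linear property laws of a material at temperature(s) `T`.
#'
#' @param mat an [material_properties()] object.
#' @param T temperature(s), degrees C.
#' @return A list with numeric components `sigma` (S/m), `k` (W/(m K)) and
#'   `c` (J/(kg K)), each the length of `T`.
#' @export
property_at <- function(mat, T) {
  stopifnot(inherits(mat, "abl_material"), all(is.finite(T)))
  dT <- T - mat$T_ref
  list(sigma = mat$sigma_ref * (1 + mat$sigma_frac_slope * dT),
       k = mat$k_ref * (1 + mat$k_frac_slope * dT),
       c = mat$c_ref + mat$c_slope * dT)
}

#' @export
print.abl_material <- function(x, ...) {
  cat(sprintf("<abl_material> %s\n", x$name))
  cat(sprintf("  rho %.0f kg/m^3 | c %.0f J/(kg K) | k %.3g W/(m K) | sigma %.3g S/m (at %.0f C)\n",
              x$rho, x$c_ref, x$k_ref, x$sigma_ref, x$T_ref))
  cat(sprintf("  slopes: c %+.3g J/(kg K)/C, k %+.3g %%/C, sigma %+.3g %%/C\n",
              x$c_slope, 100 * x$k_frac_slope, 100 * x$sigma_frac_slope))
  invisible(x)
}

#' Electrode tip specification
#'
#' Open-irrigated ablation electrode: a 7 Fr (2.33 mm diameter) metal tip,
#' either spherical (hemispherical end) or cylindrical (flat end), of given
#' metal length. Irrigation pores are carried as metadata only; their
#' cooling effect enters through the reduced irrigation model, they are
#' never meshed.
#'
#' @param tip_shape `"spherical"` or `"cylindrical"`.
#' @param diameter_mm tip diameter, mm; default 7 Fr = 7/3 mm.
#' @param tip_length_mm metal tip length along the axis, mm.
#' @param n_pores number of irrigation pores (metadata).
#' @param pore_diameter_mm pore diameter, mm (metadata).
#' @return An object of class `abl_electrode`.
#' @export
electrode_spec <- function(tip_shape = c("spherical", "cylindrical"),
                           diameter_mm = 7 / 3, tip_length_mm = 3.5,
                           n_pores = 6, pore_diameter_mm = 0.5) {
  tip_shape <- match.arg(tip_shape)
  if (diameter_mm <= 0) stop("electrode.diameter_mm must be > 0", call. = FALSE)
  if (tip_shape == "spherical" && tip_length_mm < diameter_mm / 2) {
    stop("electrode.tip_length_mm must be >= diameter/2 for a spherical tip",
         call. = FALSE)
  }
  if (tip_length_mm <= 0) stop("electrode.tip_length_mm must be > 0", call. = FALSE)
  structure(list(tip_shape = tip_shape, diameter_mm = diameter_mm,
                 tip_length_mm = tip_length_mm, n_pores = n_pores,
                 pore_diameter_mm = pore_diameter_mm),
            class = "abl_electrode")
}

#' Ablation protocol (power / duration)
#'
#' @param power_W RF power setpoint, W.
#' @param duration_s application duration, s.
#' @param name protocol label; default `"<power> W/<duration> s"`.
#' @return An object of class `abl_protocol`.
#' @examples
#' protocol_energy(ablation_protocol(90, 4))  # 360 J
#' @export
ablation_protocol <- function(power_W, duration_s, name = NULL) {
  if (!is.numeric(power_W) || power_W < 0)
    stop("protocol.power must be >= 0 W", call. = FALSE)
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("protocol.duration must be > 0 s", call. = FALSE)
  structure(list(name = name %||% sprintf("%g W/%g s", power_W, duration_s),
                 power_W = power_W, duration_s = duration_s),
            class = "abl_protocol")
}

#' Total energy delivered by a protocol
#'
#' Power times duration, in joules (e.g. 900 J for 30 W over 30 s).
#'
#' @param protocol an [ablation_protocol()].
#' @return Energy in J.
#' @export
protocol_energy <- function(protocol) {
  stopifnot(inherits(protocol, "abl_protocol"))
  protocol$power_W * protocol$duration_s
}

#' Cooling conditions (blood flow and saline irrigation)
#'
#' @param blood_velocity_m_s far-field blood velocity, m/s (0, 0.1 or 0.5
#'   in the characterization study).
#' @param irrigation_ml_min saline irrigation rate through the tip pores,
#'   ml/min (17, 30 or 60 for the commercial settings; 2 between repeated
#'   applications).
#' @param saline_T_C coolant (saline) temperature, degrees C.
#' @param blood_T_C far-field baseline blood temperature, degrees C.
#' @return An object of class `abl_cooling_conditions`.
#' @export
cooling_conditions <- function(blood_velocity_m_s, irrigation_ml_min,
                               saline_T_C = 25, blood_T_C = 37) {
  if (blood_velocity_m_s < 0)
    stop("cooling.blood_velocity must be >= 0 m/s", call. = FALSE)
  if (irrigation_ml_min < 0)
    stop("cooling.irrigation_rate must be >= 0 ml/min", call. = FALSE)
  structure(list(blood_velocity_m_s = blood_velocity_m_s,
                 irrigation_ml_min = irrigation_ml_min,
                 saline_T_C = saline_T_C, blood_T_C = blood_T_C),
            class = "abl_cooling_conditions")
}

#' Cardiac chamber specification
#'
#' Atrium and ventricle share biophysical properties and differ only by
#' wall thickness (6 mm atrium, 12 mm ventricle by default).
#'
#' @param chamber `"atrium"` or `"ventricle"`.
#' @param wall_thickness_mm wall thickness, mm; defaults by chamber.
#' @return An object of class `abl_chamber`.
#' @export
chamber_spec <- function(chamber = c("atrium", "ventricle"),
                         wall_thickness_mm = NULL) {
  chamber <- match.arg(chamber)
  wall_thickness_mm <- wall_thickness_mm %||%
    switch(chamber, atrium = 6, ventricle = 12)
  if (wall_thickness_mm <= 0)
    stop("chamber.wall_thickness_mm must be > 0", call. = FALSE)
  structure(list(chamber = chamber, wall_thickness_mm = wall_thickness_mm),
            class = "abl_chamber")
}

#' RF generator settings
#'
#' Power-controlled delivery only: the generator rescales voltage/current
#' each step so dissipated power equals the setpoint, with no temperature
#' limit. The fixed reference impedance (120 Ohm) is used only for the
#' generator-style voltage/current reporting.
#'
#' @param mode delivery mode; only `"power_controlled"` is supported.
#' @param reference_impedance_ohm reporting impedance, Ohm.
#' @return An object of class `abl_generator`.
#' @export
generator_settings <- function(mode = "power_controlled",
                               reference_impedance_ohm = 120) {
  mode <- match.arg(mode, "power_controlled")
  if (reference_impedance_ohm <= 0)
    stop("generator.reference_impedance must be > 0 Ohm", call. = FALSE)
  structure(list(mode = mode,
                 reference_impedance_ohm = reference_impedance_ohm),
            class = "abl_generator")
}

#' Lesion and complication temperature thresholds
#'
#' Lesion boundary at the 50 degree C isotherm of the maximum attained
#' tissue temperature; steam pop when tissue reaches 97 degrees C;
#' charring when blood near the electrode reaches 80 degrees C.
#'
#' @param lesion_isotherm_C lesion isotherm, degrees C.
#' @param pop_tissue_T_C steam-pop tissue threshold, degrees C.
#' @param charring_blood_T_C charring blood threshold, degrees C.
#' @return An object of class `abl_thresholds`.
#' @export
thresholds <- function(lesion_isotherm_C = 50, pop_tissue_T_C = 97,
                       charring_blood_T_C = 80) {
  if (!(lesion_isotherm_C < charring_blood_T_C &&
        charring_blood_T_C < pop_tissue_T_C)) {
    stop("thresholds must satisfy lesion_isotherm < charring_blood_T < pop_tissue_T",
         call. = FALSE)
  }
  structure(list(lesion_isotherm_C = lesion_isotherm_C,
                 pop_tissue_T_C = pop_tissue_T_C,
                 charring_blood_T_C = charring_blood_T_C),
            class = "abl_thresholds")
}

#' Numerical settings
#'
#' Time steps, mesh grading bounds, Picard iteration control and domain
#' extents for the axisymmetric desk-scale solver. Three presets bundle
#' choices used throughout: `"desk"` (default single-run fidelity),
#' `"coarse"` (calibration and comparison runs) and `"sweep"` (large
#' factorial sweeps).
#'
#' @param preset one of `"desk"`, `"coarse"`, `"sweep"`, or `NULL` to take
#'   the explicit arguments as given.
#' @param dt_heating_s time step during RF delivery, s.
#' @param dt_cooldown_s time step after power-off, s.
#' @param cooldown_duration_s post-application cool-down horizon, s
#'   (thermal latency is about 45-60 s).
#' @param mesh_h_min_m smallest element size, near the electrode, m.
#' @param mesh_h_max_m largest element size, at the far field, m.
#' @param picard_tol relative tolerance of the inner Picard update.
#' @param max_picard_iters maximum Picard iterations per step.
#' @param domain_radius_mm radial far-field extent, mm.
#' @param blood_height_mm axial extent of the blood compartment, mm.
#' @param rng_seed seed recorded in manifests (the solver itself is
#'   deterministic).
#' @return An object of class `abl_numerics`.
#' @export
numerics_config <- function(preset = NULL,
                            dt_heating_s = 0.02, dt_cooldown_s = 0.25,
                            cooldown_duration_s = 60,
                            mesh_h_min_m = 1.2e-4, mesh_h_max_m = 2.5e-3,
                            picard_tol = 1e-4, max_picard_iters = 8,
                            domain_radius_mm = 40, blood_height_mm = 20,
                            rng_seed = 1L) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("desk", "coarse", "sweep"))
    p <- switch(preset,
      desk = list(dt_heating_s = 0.02, dt_cooldown_s = 0.25,
                  mesh_h_min_m = 1.2e-4, mesh_h_max_m = 2.5e-3),
      coarse = list(dt_heating_s = 0.05, dt_cooldown_s = 0.5,
                    mesh_h_min_m = 2e-4, mesh_h_max_m = 3e-3),
      sweep = list(dt_heating_s = 0.1, dt_cooldown_s = 1,
                   mesh_h_min_m = 3e-4, mesh_h_max_m = 4e-3))
    dt_heating_s <- p$dt_heating_s; dt_cooldown_s <- p$dt_cooldown_s
    mesh_h_min_m <- p$mesh_h_min_m; mesh_h_max_m <- p$mesh_h_max_m
  }
  vals <- list(dt_heating_s = dt_heating_s, dt_cooldown_s = dt_cooldown_s,
               cooldown_duration_s = cooldown_duration_s,
               mesh_h_min_m = mesh_h_min_m, mesh_h_max_m = mesh_h_max_m,
               picard_tol = picard_tol,
               max_picard_iters = as.integer(max_picard_iters),
               domain_radius_mm = domain_radius_mm,
               blood_height_mm = blood_height_mm,
               rng_seed = as.integer(rng_seed))
  for (f in setdiff(names(vals), "rng_seed")) {
    if (!is.numeric(vals[[f]]) || vals[[f]] <= 0)
      stop(sprintf("numerics.%s must be > 0", f), call. = FALSE)
  }
  if (dt_heating_s > dt_cooldown_s)
    stop("numerics.dt_heating_s must be <= dt_cooldown_s", call. = FALSE)
  if (mesh_h_min_m > mesh_h_max_m)
    stop("numerics.mesh_h_min_m must be <= mesh_h_max_m", call. = FALSE)
  structure(vals, class = "abl_numerics")
}
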