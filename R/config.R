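#' Bundled default materials
#'
#' Reads the material parameter file shipped with the package
#' (`inst/extdata/materials.yaml`): IT'IS-style literature stand-ins for
#' myocardium, blood, platinum-iridium and polyurethane at RF frequencies.
#'
#' @param path optional alternative parameter file.
#' @return Named list of [material_properties()] objects: `tissue`,
#'   `blood`, `electrode_metal`, `catheter_body`.
#' @export
default_materials <- function(path = NULL) {
  path <- path %||% system.file("extdata", "materials.yaml",
                                package = "rfablate", mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$schema_version) || raw$schema_version != 1)
    stop("materials file: unsupported or missing schema_version", call. = FALSE)
  need <- c("tissue", "blood", "electrode_metal", "catheter_body")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop("materials file: missing entries: ", paste(missing, collapse = ", "),
         call. = FALSE)
  lapply(setNames(need, need), function(nm) do.call(material_properties, raw[[nm]]))
}

#' Assemble a complete simulation configuration
#'
#' Bundles materials, electrode, protocol, cooling, chamber, contact force,
#' generator, thresholds and numerics into one validated description of a
#' virtual RF application.
#'
#' @param electrode an [electrode_spec()].
#' @param protocol an [ablation_protocol()].
#' @param cooling a [cooling_conditions()].
#' @param chamber a [chamber_spec()].
#' @param contact_force_g catheter contact force, grams.
#' @param materials named list as from [default_materials()].
#' @param generator a [generator_settings()].
#' @param thresholds_ a [thresholds()].
#' @param numerics a [numerics_config()].
#' @param contact_model a [contact_model()] mapping contact force to
#'   insertion depth.
#' @return An object of class `abl_config`.
#' @export
simulation_config <- function(electrode = electrode_spec("spherical"),
                              protocol = ablation_protocol(30, 30),
                              cooling = cooling_conditions(0.1, 17),
                              chamber = chamber_spec("atrium"),
                              contact_force_g = 10,
                              materials = default_materials(),
                              generator = generator_settings(),
                              thresholds_ = thresholds(),
                              numerics = numerics_config(),
                              contact_model = default_contact_model()) {
  stopifnot(inherits(electrode, "abl_electrode"),
            inherits(protocol, "abl_protocol"),
            inherits(cooling, "abl_cooling_conditions"),
            inherits(chamber, "abl_chamber"),
            inherits(generator, "abl_generator"),
            inherits(thresholds_, "abl_thresholds"),
            inherits(numerics, "abl_numerics"),
            inherits(contact_model, "abl_contact_model"))
  if (!is.numeric(contact_force_g) || contact_force_g < 0)
    stop("contact_force_g must be >= 0", call. = FALSE)
  need <- c("tissue", "blood", "electrode_metal", "catheter_body")
  if (!all(need %in% names(materials)))
    stop("materials must contain: ", paste(need, collapse = ", "), call. = FALSE)
  for (nm in need) validate_material(materials[[nm]])
  cfg <- structure(list(electrode = electrode, protocol = protocol,
                        cooling = cooling, chamber = chamber,
                        contact_force_g = contact_force_g,
                        materials = materials, generator = generator,
                        thresholds = thresholds_, numerics = numerics,
                        contact_model = contact_model),
                   class = "abl_config")
  d <- insertion_depth(contact_model, contact_force_g, electrode$tip_shape)
  if (d >= chamber$wall_thickness_mm)
    stop("insertion depth must stay below the wall thickness", call. = FALSE)
  cfg
}

#' @export
print.abl_config <- function(x, ...) {
  cat("<abl_config>\n")
  cat(sprintf("  %s | %s tip | CF %g g | %s (%g mm wall)\n",
              x$protocol$name, x$electrode$tip_shape, x$contact_force_g,
              x$chamber$chamber, x$chamber$wall_thickness_mm))
  cat(sprintf("  irrigation %g ml/min | blood flow %g m/s | saline %g C\n",
              x$cooling$irrigation_ml_min, x$cooling$blood_velocity_m_s,
              x$cooling$saline_T_C))
  invisible(x)
}

config_fields <- c("schema_version", "electrode", "protocol", "cooling",
                   "chamber", "contact_force_g", "materials", "generator",
                   "thresholds", "numerics", "contact_model")

#' Load a simulation configuration from a YAML file
#'
#' The configuration dialect is versioned YAML (`schema_version: 1`).
#' Any field may be omitted and takes its documented default; material
#' values default to the bundled parameter file. Unknown keys are errors.
#'
#' @param path path to a YAML configuration file.
#' @return A validated [simulation_config()] object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$schema_version) || raw$schema_version != 1)
    stop("config: unsupported or missing schema_version (expected 1)",
         call. = FALSE)
  unknown <- setdiff(names(raw), config_fields)
  if (length(unknown))
    stop("config: unknown keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  args <- list()
  if (!is.null(raw$electrode)) args$electrode <- do.call(electrode_spec, raw$electrode)
  if (!is.null(raw$protocol)) args$protocol <- do.call(ablation_protocol, raw$protocol)
  if (!is.null(raw$cooling)) args$cooling <- do.call(cooling_conditions, raw$cooling)
  if (!is.null(raw$chamber)) args$chamber <- do.call(chamber_spec, raw$chamber)
  if (!is.null(raw$contact_force_g)) args$contact_force_g <- raw$contact_force_g
  if (!is.null(raw$generator)) args$generator <- do.call(generator_settings, raw$generator)
  if (!is.null(raw$thresholds)) args$thresholds_ <- do.call(thresholds, raw$thresholds)
  if (!is.null(raw$numerics)) args$numerics <- do.call(numerics_config, raw$numerics)
  if (!is.null(raw$contact_model))
    args$contact_model <- do.call(contact_model,
                                  lapply(raw$contact_model, unlist))
  if (!is.null(raw$materials)) {
    mats <- default_materials()
    for (nm in names(raw$materials)) {
      if (!nm %in% names(mats))
        stop("config: unknown material entry '", nm, "'", call. = FALSE)
      mats[[nm]] <- do.call(material_properties,
                            modifyList(unclass(mats[[nm]]), raw$materials[[nm]]))
    }
    args$materials <- mats
  }
  do.call(simulation_config, args)
}

#' Serialize a simulation configuration to YAML
#'
#' Writes the full configuration (all defaults expanded) so that
#' [load_config()] on the result reproduces the object field for field.
#'
#' @param config an `abl_config`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "abl_config"))
  strip <- function(x) lapply(unclass(x), function(v) if (is.list(v)) strip(v) else v)
  cm_tab <- function(tab) as.list(setNames(tab$depth, as.character(tab$cf)))
  out <- list(schema_version = 1,
              electrode = strip(config$electrode),
              protocol = strip(config$protocol),
              cooling = strip(config$cooling),
              chamber = strip(config$chamber),
              contact_force_g = config$contact_force_g,
              materials = lapply(config$materials, strip),
              generator = strip(config$generator),
              thresholds = strip(config$thresholds),
              numerics = strip(config$numerics),
              contact_model = list(
                spherical = cm_tab(config$contact_model$spherical),
                cylindrical = cm_tab(config$contact_model$cylindrical)))
  yaml::write_yaml(out, path, precision = 12)
  invisible(path)
}

#' Convenience constructor for study configurations
#'
#' Builds a [simulation_config()] from scalar study factors (the Table-1
#' style factorial axes), sharing materials/numerics across calls.
#'
#' @param tip `"spherical"` or `"cylindrical"`.
#' @param power_W,duration_s protocol setpoint.
#' @param cf_g contact force, grams.
#' @param irrigation_ml_min irrigation rate, ml/min.
#' @param blood_velocity_m_s blood velocity, m/s.
#' @param chamber `"atrium"` or `"ventricle"`.
#' @param numerics a [numerics_config()].
#' @param materials materials list; defaults to the bundled set.
#' @return An `abl_config`.
#' @export
study_config <- function(tip = "spherical", power_W = 30, duration_s = 30,
                         cf_g = 10, irrigation_ml_min = 17,
                         blood_velocity_m_s = 0.1, chamber = "atrium",
                         numerics = numerics_config(),
                         materials = default_materials()) {
  simulation_config(
    electrode = electrode_spec(tip),
    protocol = ablation_protocol(power_W, duration_s),
    cooling = cooling_conditions(blood_velocity_m_s, irrigation_ml_min),
    chamber = chamber_spec(chamber),
    contact_force_g = cf_g,
    materials = materials,
    numerics = numerics)
}
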