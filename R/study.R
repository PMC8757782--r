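#' Factorial sweep grid
#'
#' The characterization grid: catheter tips x contact forces x
#' power/duration protocols x irrigation rates x blood velocities x
#' chambers. The default is the full study grid,
#' 2 x 4 x 3 x 3 x 3 x 2 = 432 configurations.
#'
#' @param tips character vector of tip shapes.
#' @param contact_forces_g contact forces, grams.
#' @param protocols list of [ablation_protocol()]s.
#' @param irrigation_ml_min irrigation rates, ml/min.
#' @param blood_velocities_m_s blood velocities, m/s.
#' @param chambers character vector of chambers.
#' @return An object of class `abl_sweep_grid`.
#' @export
sweep_grid <- function(tips = c("spherical", "cylindrical"),
                       contact_forces_g = c(5, 10, 15, 20),
                       protocols = hpsd_protocols(),
                       irrigation_ml_min = c(17, 30, 60),
                       blood_velocities_m_s = c(0, 0.1, 0.5),
                       chambers = c("atrium", "ventricle")) {
  if (!length(tips) || !length(contact_forces_g) || !length(protocols) ||
      !length(irrigation_ml_min) || !length(blood_velocities_m_s) ||
      !length(chambers))
    stop("all sweep factors must be nonempty", call. = FALSE)
  if (inherits(protocols, "abl_protocol")) protocols <- list(protocols)
  structure(list(tips = tips, contact_forces_g = contact_forces_g,
                 protocols = protocols,
                 irrigation_ml_min = irrigation_ml_min,
                 blood_velocities_m_s = blood_velocities_m_s,
                 chambers = chambers),
            class = "abl_sweep_grid")
}

#' The three HPSD protocols
#'
#' 70 W/8 s, 80 W/6 s and 90 W/4 s, power-controlled without temperature
#' limit.
#'
#' @return List of [ablation_protocol()]s.
#' @export
hpsd_protocols <- function() {
  list(ablation_protocol(70, 8), ablation_protocol(80, 6),
       ablation_protocol(90, 4))
}

#' Number of grid points
#' @param grid an [sweep_grid()].
#' @return Integer count (product of factor cardinalities).
#' @export
sweep_size <- function(grid) {
  stopifnot(inherits(grid, "abl_sweep_grid"))
  length(grid$tips) * length(grid$contact_forces_g) *
    length(grid$protocols) * length(grid$irrigation_ml_min) *
    length(grid$blood_velocities_m_s) * length(grid$chambers)
}

#' Enumerate a sweep grid into configurations
#'
#' Full Cartesian product in deterministic order: the factor listed first
#' in the grid varies fastest (tips, then contact force, protocol,
#' irrigation, blood velocity, chamber). Each configuration is validated
#' on construction.
#'
#' @param grid an [sweep_grid()].
#' @param numerics a [numerics_config()]; the `"sweep"` preset by default.
#' @param materials shared materials list.
#' @return List of `abl_config` objects with a `factors` attribute (a
#'   data frame of the factor tuples in matching order).
#' @export
enumerate_sweep <- function(grid, numerics = numerics_config(preset = "sweep"),
                            materials = default_materials()) {
  stopifnot(inherits(grid, "abl_sweep_grid"))
  fac <- expand.grid(tip = grid$tips, cf_g = grid$contact_forces_g,
                     protocol = seq_along(grid$protocols),
                     irrigation_ml_min = grid$irrigation_ml_min,
                     blood_velocity_m_s = grid$blood_velocities_m_s,
                     chamber = grid$chambers,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  configs <- lapply(seq_len(nrow(fac)), function(i) {
    p <- grid$protocols[[fac$protocol[i]]]
    study_config(tip = fac$tip[i], power_W = p$power_W,
                 duration_s = p$duration_s, cf_g = fac$cf_g[i],
                 irrigation_ml_min = fac$irrigation_ml_min[i],
                 blood_velocity_m_s = fac$blood_velocity_m_s[i],
                 chamber = fac$chamber[i], numerics = numerics,
                 materials = materials)
  })
  fac$protocol <- vapply(grid$protocols, function(p) p$name,
                         character(1))[fac$protocol]
  attr(configs, "factors") <- fac
  configs
}

sweep_key <- function(cfg) {
  sprintf("%s|%g|%s|%g|%g|%s", cfg$electrode$tip_shape, cfg$contact_force_g,
          cfg$protocol$name, cfg$cooling$irrigation_ml_min,
          cfg$cooling$blood_velocity_m_s, cfg$chamber$chamber)
}

#' Run a configuration sweep
#'
#' Executes every configuration, reusing solver contexts across
#' configurations that share a geometry (tip, contact force, chamber) and
#' journaling each completed row to disk so an interrupted sweep can be
#' resumed without recomputation. Failures become error rows, never
#' silently dropped.
#'
#' @param configs list of `abl_config`s, e.g. from [enumerate_sweep()].
#' @param calibration an [cooling_calibration()].
#' @param journal optional path of a tab-separated journal file; existing
#'   rows are reused on resume.
#' @param progress print one line per completed run.
#' @return An object of class `abl_sweep_result`: a data frame `rows`
#'   (one per configuration: factor tuple, outcome, event time, lesion
#'   metrics, delivered energy, error message if any).
#' @export
run_sweep <- function(configs, calibration = default_cooling(),
                      journal = NULL, progress = FALSE) {
  if (!length(configs)) {
    return(structure(list(rows = data.frame()), class = "abl_sweep_result"))
  }
  fac <- attr(configs, "factors")
  if (is.null(fac)) {
    fac <- do.call(rbind, lapply(configs, function(cfg) {
      data.frame(tip = cfg$electrode$tip_shape, cf_g = cfg$contact_force_g,
                 protocol = cfg$protocol$name,
                 irrigation_ml_min = cfg$cooling$irrigation_ml_min,
                 blood_velocity_m_s = cfg$cooling$blood_velocity_m_s,
                 chamber = cfg$chamber$chamber,
                 stringsAsFactors = FALSE)
    }))
  }
  cols <- c("key", "outcome", "event_time_s", "depth_D_mm", "width_W_mm",
            "depth_at_width_DW_mm", "volume_mm3", "delivered_energy_J",
            "error")
  done <- NULL
  if (!is.null(journal) && file.exists(journal)) {
    done <- utils::read.table(journal, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  }
  ctx_cache <- new.env(parent = emptyenv())
  rows <- vector("list", length(configs))
  for (i in seq_along(configs)) {
    cfg <- configs[[i]]
    key <- sweep_key(cfg)
    if (!is.null(done) && key %in% done$key) {
      rows[[i]] <- done[match(key, done$key), cols]
      next
    }
    gkey <- sprintf("%s|%g|%s|%s", cfg$electrode$tip_shape,
                    cfg$contact_force_g, cfg$chamber$chamber,
                    paste(cfg$numerics$mesh_h_min_m,
                          cfg$numerics$mesh_h_max_m))
    ctx <- ctx_cache[[gkey]]
    if (is.null(ctx)) {
      ctx <- build_run_context(cfg, calibration)
      ctx_cache[[gkey]] <- ctx
    } else {
      ctx$config <- cfg
    }
    row <- tryCatch({
      res <- run_application(cfg, calibration, context = ctx)
      data.frame(key = key, outcome = res$outcome,
                 event_time_s = res$event_time_s,
                 depth_D_mm = res$lesion$depth_D_mm,
                 width_W_mm = res$lesion$width_W_mm,
                 depth_at_width_DW_mm = res$lesion$depth_at_width_DW_mm,
                 volume_mm3 = res$lesion$volume_mm3,
                 delivered_energy_J = res$delivered_energy_J,
                 error = NA_character_, stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(key = key, outcome = "error", event_time_s = NA_real_,
                 depth_D_mm = NA_real_, width_W_mm = NA_real_,
                 depth_at_width_DW_mm = NA_real_, volume_mm3 = NA_real_,
                 delivered_energy_J = NA_real_,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
    rows[[i]] <- row
    if (!is.null(journal)) {
      jexists <- file.exists(journal)
      utils::write.table(row, journal, sep = "\t", row.names = FALSE,
                         col.names = !jexists, append = jexists,
                         quote = FALSE)
    }
    if (progress)
      message(sprintf("[%d/%d] %s -> %s", i, length(configs), key,
                      row$outcome))
  }
  rows <- do.call(rbind, rows)
  structure(list(rows = cbind(fac, rows[, setdiff(cols, "key")],
                              row.names = NULL)),
            class = "abl_sweep_result")
}

#' @export
print.abl_sweep_result <- function(x, ...) {
  cat(sprintf("<abl_sweep_result> %d runs\n", nrow(x$rows)))
  print(table(x$rows$outcome))
  invisible(x)
}

#' Safety rates by stratum
#'
#' Counts and percentages of safe / pop / charring outcomes, stratified
#' by any subset of the grid factors (or overall for `strata = NULL`),
#' with denominators.
#'
#' @param sweep an [run_sweep()] result.
#' @param strata character vector of factor column names, or `NULL`.
#' @return Data frame with one row per stratum: counts `n_safe`,
#'   `n_pop`, `n_charring`, denominator `n`, and the corresponding
#'   percentages.
#' @export
safety_summary <- function(sweep, strata = NULL) {
  stopifnot(inherits(sweep, "abl_sweep_result"))
  rows <- sweep$rows
  factors <- c("tip", "cf_g", "protocol", "irrigation_ml_min",
               "blood_velocity_m_s", "chamber")
  if (!is.null(strata)) {
    bad <- setdiff(strata, factors)
    if (length(bad))
      stop("unknown strata: ", paste(bad, collapse = ", "), call. = FALSE)
    key <- interaction(rows[strata], drop = TRUE, lex.order = TRUE)
  } else {
    key <- factor(rep("overall", nrow(rows)))
  }
  out <- lapply(levels(key), function(lv) {
    sub <- rows[key == lv, ]
    n <- nrow(sub)
    cnt <- c(safe = sum(sub$outcome == "safe"),
             pop = sum(sub$outcome == "pop"),
             charring = sum(sub$outcome == "charring"))
    base <- if (!is.null(strata)) sub[1, strata, drop = FALSE] else
      data.frame(stratum = "overall")
    cbind(base,
          data.frame(n = n, n_safe = cnt["safe"], n_pop = cnt["pop"],
                     n_charring = cnt["charring"],
                     pct_safe = 100 * cnt["safe"] / n,
                     pct_pop = 100 * cnt["pop"] / n,
                     pct_charring = 100 * cnt["charring"] / n,
                     pct_complication = 100 * (n - cnt["safe"]) / n,
                     row.names = NULL))
  })
  do.call(rbind, out)
}

#' Protocol comparison against a reference (radar-chart data)
#'
#' Expresses each protocol's lesion metrics as percentages of a named
#' reference protocol (the reference maps to 100% in every metric), plus
#' the absolute table.
#'
#' @param metrics data frame with columns `protocol`, `depth_D_mm`,
#'   `width_W_mm`, `depth_at_width_DW_mm`, `volume_mm3` (one row per
#'   protocol).
#' @param reference name of the reference protocol (must be present).
#' @return An object of class `abl_comparison`: `absolute` and `percent`
#'   data frames.
#' @export
compare_protocols <- function(metrics, reference) {
  need <- c("protocol", "depth_D_mm", "width_W_mm", "depth_at_width_DW_mm",
            "volume_mm3")
  stopifnot(all(need %in% names(metrics)))
  i <- match(reference, metrics$protocol)
  if (is.na(i)) stop("reference protocol not present: ", reference,
                     call. = FALSE)
  ref <- metrics[i, need[-1]]
  if (any(unlist(ref) == 0))
    stop("reference protocol has a zero metric; percentages undefined",
         call. = FALSE)
  pct <- metrics
  for (cn in need[-1]) pct[[cn]] <- 100 * metrics[[cn]] / ref[[cn]]
  structure(list(reference = reference, absolute = metrics, percent = pct),
            class = "abl_comparison")
}

#' @export
print.abl_comparison <- function(x, ...) {
  cat(sprintf("<abl_comparison> reference: %s (= 100%%)\n", x$reference))
  print(x$percent, digits = 3)
  invisible(x)
}

#' Repeated-application study
#'
#' For each protocol and inter-application interval, runs the
#' two-application sequence under the step-B settings (CF 5 g, 60 ml/min,
#' low blood flow; spherical tip in the atrium, cylindrical in the
#' ventricle by default) and tabulates the percentage changes in depth,
#' width and volume of the combined lesion over the single application,
#' with the second-application outcome.
#'
#' @param protocols list of [ablation_protocol()]s.
#' @param intervals_s inter-application intervals, s.
#' @param chamber `"atrium"` or `"ventricle"`.
#' @param tip tip shape; default per chamber (spherical atrium,
#'   cylindrical ventricle).
#' @param cf_g,irrigation_ml_min,blood_velocity_m_s step-B settings.
#' @param calibration an [cooling_calibration()].
#' @param numerics a [numerics_config()].
#' @return Data frame: one row per protocol x interval with
#'   `ddepth_pct`, `dwidth_pct`, `dvolume_pct`, `second_outcome`.
#' @export
repeat_study <- function(protocols = hpsd_protocols(),
                         intervals_s = c(2, 4, 6, 8, 10),
                         chamber = "ventricle", tip = NULL, cf_g = 5,
                         irrigation_ml_min = 60, blood_velocity_m_s = 0.1,
                         calibration = default_cooling(),
                         numerics = numerics_config(preset = "coarse")) {
  tip <- tip %||% switch(chamber, atrium = "spherical",
                         ventricle = "cylindrical")
  if (inherits(protocols, "abl_protocol")) protocols <- list(protocols)
  out <- list()
  for (p in protocols) {
    cfg <- study_config(tip = tip, power_W = p$power_W,
                        duration_s = p$duration_s, cf_g = cf_g,
                        irrigation_ml_min = irrigation_ml_min,
                        blood_velocity_m_s = blood_velocity_m_s,
                        chamber = chamber, numerics = numerics)
    ctx <- build_run_context(cfg, calibration)
    first <- run_application(cfg, calibration, context = ctx)
    if (first$outcome != "safe")
      stop("base application for ", p$name, " in the ", chamber,
           " is not safe under step-B settings", call. = FALSE)
    for (iv in intervals_s) {
      seq_res <- run_sequence(cfg, iv, calibration, context = ctx,
                              first = first)
      l1 <- first$lesion; l2 <- seq_res$combined$lesion
      out[[length(out) + 1L]] <- data.frame(
        protocol = p$name, chamber = chamber, interval_s = iv,
        ddepth_pct = 100 * (l2$depth_D_mm - l1$depth_D_mm) / l1$depth_D_mm,
        dwidth_pct = 100 * (l2$width_W_mm - l1$width_W_mm) / l1$width_W_mm,
        dvolume_pct = seq_res$volume_increase_pct,
        second_outcome = seq_res$second_outcome,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Standard-of-care reference configurations
#'
#' The stage-1 calibration references: 30 W/30 s, CF 10 g, 17 ml/min,
#' low blood flow (0.1 m/s), spherical tip in the atrium and cylindrical
#' tip in the ventricle, paired with their target lesion dimensions
#' (atrium depth 5.31 mm / width 7.59 mm; ventricle 4.53 mm / 6.49 mm).
#'
#' @param numerics a [numerics_config()].
#' @return List of references consumable by [calibrate_cooling()].
#' @export
standard_references <- function(numerics = numerics_config(preset = "coarse")) {
  list(
    list(config = study_config(tip = "spherical", power_W = 30,
                               duration_s = 30, cf_g = 10,
                               irrigation_ml_min = 17,
                               blood_velocity_m_s = 0.1,
                               chamber = "atrium", numerics = numerics),
         depth_mm = 5.31, width_mm = 7.59),
    list(config = study_config(tip = "cylindrical", power_W = 30,
                               duration_s = 30, cf_g = 10,
                               irrigation_ml_min = 17,
                               blood_velocity_m_s = 0.1,
                               chamber = "ventricle", numerics = numerics),
         depth_mm = 4.53, width_mm = 6.49))
}
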