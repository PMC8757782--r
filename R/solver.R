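# Coupled quasi-static potential / bioheat solver.
#
# Electric problem (per step, quasi-static at RF frequency):
#   div(sigma(T) grad V) = 0 on tissue + blood,
#   V = applied on the electrode surface, V = 0 at the tissue bottom
#   (ground), natural (insulating) elsewhere. The field is rescaled each
#   step so the dissipated power int sigma |grad V|^2 dOmega equals the
#   protocol setpoint (power control, no temperature limit).
#
# Thermal problem (backward Euler, lagged Picard coefficients):
#   rho c(T) dT/dt = div(k(T) grad T) + q_joule - q_sink
# on all four regions, with the reduced cooling models of
# cooling_calibration() as Robin films and a blood volumetric sink.

#' Solve the quasi-static potential problem
#'
#' Solves `div(sigma grad V) = 0` on the conducting subdomain of an
#' axisymmetric mesh with `V = applied` on the electrode surface and
#' `V = 0` on the ground boundary, and returns the raw dissipated power
#' `int sigma |grad V|^2 (2 pi r) dA`.
#'
#' @param mesh an `abl_mesh`.
#' @param sigma electrical conductivity: per element (length = number of
#'   elements) or per node (averaged onto elements), S/m.
#' @param applied electrode potential, V.
#' @param electrode_nodes,ground_nodes node index vectors for the two
#'   Dirichlet sets; defaults derive them from the mesh facet tags
#'   (electrode-tissue and electrode-blood interfaces; bottom boundary).
#' @param elems element subset forming the conducting domain; defaults to
#'   tissue + blood regions.
#' @return List with `V` (nodal potential) and `raw_power` (W).
#' @export
solve_potential <- function(mesh, sigma, applied = 1,
                            electrode_nodes = NULL, ground_nodes = NULL,
                            elems = NULL) {
  stopifnot(inherits(mesh, "abl_mesh"))
  m <- nrow(mesh$tri)
  if (length(sigma) == nrow(mesh$nodes)) {
    sigma <- (sigma[mesh$tri[, 1]] + sigma[mesh$tri[, 2]] +
              sigma[mesh$tri[, 3]]) / 3
  }
  if (length(sigma) == 1) sigma <- rep(sigma, m)
  stopifnot(length(sigma) == m, all(sigma > 0))
  if (is.null(elems))
    elems <- which(mesh$region %in% c(REG_TISSUE, REG_BLOOD))
  if (is.null(electrode_nodes)) {
    f <- mesh$facets
    sel <- f$tag %in% c(TAG_ELECTRODE_TISSUE, TAG_ELECTRODE_BLOOD)
    electrode_nodes <- unique(c(f$n1[sel], f$n2[sel]))
  }
  if (is.null(ground_nodes)) {
    f <- mesh$facets
    sel <- f$tag == TAG_BOTTOM
    ground_nodes <- unique(c(f$n1[sel], f$n2[sel]))
  }
  if (!length(electrode_nodes) || !length(ground_nodes))
    stop("potential solve: empty electrode or ground boundary set; ",
         "check mesh boundary tags", call. = FALSE)
  if (applied == 0) {
    return(list(V = numeric(nrow(mesh$nodes)), raw_power = 0))
  }
  prob <- fem_problem(mesh, elems,
                      fixed = c(electrode_nodes, ground_nodes),
                      fixed_val = c(rep(applied, length(electrode_nodes)),
                                    rep(0, length(ground_nodes))))
  kv <- fem_stiff_values(prob, sigma[elems])
  x <- fem_solve(prob, kv, NULL, numeric(prob$nfree))
  V <- fem_expand(prob, x)
  g2 <- fem_grad2(mesh, elems, V)
  raw <- sum(sigma[elems] * g2 * 2 * pi * mesh$rbar[elems] * mesh$area[elems])
  list(V = V, raw_power = raw)
}

#' Power-control field rescaling factor
#'
#' With Joule power quadratic in the applied potential, rescaling the
#' field by `sqrt(target / raw_power)` delivers exactly the target power.
#'
#' @param raw_power power dissipated by the unscaled field, W (> 0).
#' @param target power setpoint, W.
#' @return The scale factor.
#' @export
power_control_scale <- function(raw_power, target) {
  if (!is.numeric(raw_power) || raw_power <= 0)
    stop("raw_power must be > 0", call. = FALSE)
  sqrt(target / raw_power)
}

#' Generator-style voltage / current report
#'
#' RMS voltage and current the generator would display for a power
#' setpoint at its fixed reference impedance (reporting convenience only;
#' independent of the field solve).
#'
#' @param target_W power setpoint, W.
#' @param gen a [generator_settings()].
#' @return Named numeric `c(V_rms, I_rms)`.
#' @export
reported_voltage_current <- function(target_W, gen = generator_settings()) {
  stopifnot(inherits(gen, "abl_generator"), target_W >= 0)
  Z <- gen$reference_impedance_ohm
  c(V_rms = sqrt(target_W * Z), I_rms = sqrt(target_W / Z))
}

# --- run context --------------------------------------------------------

# Everything reusable across time steps (and across runs sharing the same
# geometry/materials/numerics): mesh, per-element material coefficients,
# Dirichlet-partitioned problems, Robin geometric weights, monitor node
# sets.
build_run_context <- function(config, calibration = default_cooling(),
                              mesh = NULL) {
  stopifnot(inherits(config, "abl_config"), inherits(calibration, "abl_cooling"))
  depth <- insertion_depth(config$contact_model, config$contact_force_g,
                           config$electrode$tip_shape)
  geom <- build_geometry(config$electrode, config$chamber, depth,
                         config$numerics$domain_radius_mm,
                         config$numerics$blood_height_mm)
  if (is.null(mesh)) mesh <- generate_mesh(geom, config$numerics)
  m <- nrow(mesh$tri); n <- nrow(mesh$nodes)
  reg <- mesh$region
  mats <- config$materials
  pick <- function(field) {
    v <- c(mats$tissue[[field]], mats$blood[[field]],
           mats$electrode_metal[[field]], mats$catheter_body[[field]])
    v[reg]
  }
  matv <- list(rho = pick("rho"), c_ref = pick("c_ref"),
               c_slope = pick("c_slope"), k_ref = pick("k_ref"),
               k_slope = pick("k_frac_slope"), sigma_ref = pick("sigma_ref"),
               sigma_slope = pick("sigma_frac_slope"), T_ref = pick("T_ref"))
  is_blood_e <- reg == REG_BLOOD
  elec_elems <- which(reg %in% c(REG_TISSUE, REG_BLOOD))

  f <- mesh$facets
  nodes_of <- function(sel) unique(c(f$n1[sel], f$n2[sel]))
  electrode_nodes <- nodes_of(f$tag %in% c(TAG_ELECTRODE_TISSUE,
                                           TAG_ELECTRODE_BLOOD))
  # dispersive return at the far radial boundary of the blood pool (the
  # remote bath return of the in-vitro reference setup); grounding the
  # slab bottom funnels current axially through the thin wall and
  # overheats the sub-tip axis, grounding the tissue rim makes the
  # tissue current share grow with wall thickness — both artifacts
  blood_outer <- f$tag == TAG_OUTER & f$zmid > 0
  ground_nodes <- setdiff(nodes_of(blood_outer), electrode_nodes)
  # thermal far field: outer rim and blood top at baseline; the tissue
  # bottom is a finite substrate film (h_substrate), not a hard clamp
  far_nodes <- nodes_of(f$tag %in% c(TAG_OUTER, TAG_TOP))

  baseT <- config$cooling$blood_T_C
  prob_elec <- fem_problem(mesh, elec_elems,
                           fixed = c(electrode_nodes, ground_nodes),
                           fixed_val = c(rep(1, length(electrode_nodes)),
                                         rep(0, length(ground_nodes))))
  prob_therm <- fem_problem(mesh, seq_len(m), fixed = far_nodes,
                            fixed_val = rep(baseT, length(far_nodes)))
  # triplets with a fixed row: used for the Dirichlet boundary-flux audit
  iifix <- prob_therm$isfix[as.integer(mesh$II)]
  prob_therm$sel_rf <- which(iifix)
  prob_therm$j_rf <- as.integer(mesh$JJ)[iifix]

  # Robin geometric node weights: facet length * 2 pi r_mid / 2 per node
  robin_weights <- function(sel) {
    w <- numeric(n)
    if (!any(sel)) return(w)
    wf <- 2 * pi * f$rmid[sel] * f$length[sel] / 2
    for (col in c("n1", "n2")) {
      acc <- tapply(wf, f[[col]][sel], sum)
      w[as.integer(names(acc))] <- w[as.integer(names(acc))] + as.vector(acc)
    }
    w
  }
  # saline-cloud elements: blood within the cloud radius of the metal
  cloud_e <- rep(FALSE, m)
  if (calibration$sigma_cloud[1] > 0) {
    esurf <- f$tag %in% c(TAG_ELECTRODE_BLOOD, TAG_ELECTRODE_TISSUE)
    if (any(esurf)) {
      cen_r <- (mesh$nodes[mesh$tri[, 1], 1] + mesh$nodes[mesh$tri[, 2], 1] +
                  mesh$nodes[mesh$tri[, 3], 1]) / 3
      cen_z <- (mesh$nodes[mesh$tri[, 1], 2] + mesh$nodes[mesh$tri[, 2], 2] +
                  mesh$nodes[mesh$tri[, 3], 2]) / 3
      bl <- which(is_blood_e)
      d2 <- outer(cen_r[bl], f$rmid[esurf], "-")^2 +
        outer(cen_z[bl], f$zmid[esurf], "-")^2
      cloud_e[bl[sqrt(apply(d2, 1, min)) <=
                   calibration$sigma_cloud[3] * 1e-3]] <- TRUE
    }
  }

  eb <- f$tag == TAG_ELECTRODE_BLOOD
  if (any(eb)) {
    zlo <- min(f$zmid[eb]); zhi <- max(f$zmid[eb])
    cooled <- eb & f$zmid <= zlo + calibration$cooled_fraction * (zhi - zlo)
  } else cooled <- eb
  W_plate <- robin_weights(f$tag == TAG_BOTTOM)  # electrical plate contact
  W_irr <- robin_weights(cooled)
  # uncooled junction band + adjacent shaft surface: indirect entrainment
  jun <- (eb & !cooled) |
    (f$tag == TAG_SHAFT_BLOOD & f$zmid <= geom$z_top_m + 1e-3)
  W_jun <- robin_weights(jun)
  W_endo <- robin_weights(f$tag == TAG_ENDOCARDIUM)
  W_sub <- robin_weights(f$tag == TAG_BOTTOM)

  # monitor node sets
  tri <- mesh$tri
  tissue_nodes <- sort(unique(as.integer(tri[reg == REG_TISSUE, ])))
  blood_nodes <- sort(unique(as.integer(tri[is_blood_e, ])))
  shell_sel <- f$tag == TAG_ELECTRODE_BLOOD |
    (f$tag == TAG_SHAFT_BLOOD & f$zmid <= geom$z_top_m + 1e-3)
  shell_pts <- cbind(f$rmid[shell_sel], f$zmid[shell_sel])
  shell_nodes <- nodes_of(shell_sel)
  if (nrow(shell_pts)) {
    d2 <- outer(mesh$nodes[blood_nodes, 1], shell_pts[, 1], "-")^2 +
      outer(mesh$nodes[blood_nodes, 2], shell_pts[, 2], "-")^2
    near <- blood_nodes[sqrt(apply(d2, 1, min)) <= calibration$shell_mm * 1e-3]
    shell_nodes <- sort(unique(c(shell_nodes, near)))
  }

  list(config = config, calibration = calibration, geom = geom, mesh = mesh,
       matv = matv, is_blood_e = is_blood_e, cloud_e = cloud_e,
       elec_elems = elec_elems,
       prob_elec = prob_elec, prob_therm = prob_therm,
       W_irr = W_irr, W_jun = W_jun, W_endo = W_endo, W_sub = W_sub,
       W_plate = W_plate,
       tissue_nodes = tissue_nodes, shell_nodes = shell_nodes,
       baseT = baseT)
}

# per-element temperature (mean of vertices)
elem_T <- function(mesh, T) {
  (T[mesh$tri[, 1]] + T[mesh$tri[, 2]] + T[mesh$tri[, 3]]) / 3
}

# --- schedule engine ----------------------------------------------------

# A schedule segment: duration (s), power (W), irrigation (ml/min),
# phase label, time step (s).
schedule_segment <- function(duration_s, power_W, irrigation_ml_min,
                             phase, dt_s) {
  list(duration_s = duration_s, power_W = power_W,
       irrigation_ml_min = irrigation_ml_min, phase = phase, dt_s = dt_s)
}

# Core time loop. Returns the full final state plus traces and audit.
run_schedule <- function(ctx, segments, audit = FALSE) {
  mesh <- ctx$mesh
  cfg <- ctx$config
  cal <- ctx$calibration
  num <- cfg$numerics
  th <- cfg$thresholds
  n <- nrow(mesh$nodes)
  matv <- ctx$matv
  v <- cfg$cooling$blood_velocity_m_s
  keff_mult <- blood_keff_multiplier(cal, v)
  h_endo <- endocardial_h(cal, v)
  sink_w <- blood_sink_rate(cal, v)
  baseT <- ctx$baseT
  prob <- ctx$prob_therm
  free <- prob$free
  Smat <- mesh$Smat

  T <- rep(baseT, n)
  Tmax <- T
  t <- 0
  event <- NULL
  delivered <- 0
  power_off_Tmax <- NULL
  iso <- th$lesion_isotherm_C

  nsteps_max <- sum(vapply(segments, function(s)
    ceiling(s$duration_s / s$dt_s), numeric(1))) +
    ceiling(num$cooldown_duration_s / num$dt_cooldown_s) + 4L
  tr <- matrix(NA_real_, nsteps_max, 7)
  colnames(tr) <- c("t_s", "power_W", "max_tissue_T", "max_shell_T",
                    "applied_V", "current_A", "picard_iters")
  tr_phase <- character(nsteps_max)
  irow <- 0L
  aud <- list(E_in = 0, dH = 0, robin_out = 0, sink_out = 0,
              dirichlet_out = 0, return_out = 0)

  seg_i <- 1L
  while (seg_i <= length(segments)) {
    seg <- segments[[seg_i]]
    dt <- seg$dt_s
    Q <- seg$irrigation_ml_min
    h_irr <- irrigation_h(cal, Q)
    cmult <- cloud_multiplier(cal, Q)
    h_jun <- cal$junction_h_frac * h_irr
    rob_diag_full <- h_irr * ctx$W_irr + h_jun * ctx$W_jun +
      h_endo * ctx$W_endo + cal$h_substrate * ctx$W_sub
    rob_rhs_full <- (h_irr * ctx$W_irr + h_jun * ctx$W_jun) *
      cfg$cooling$saline_T_C +
      (h_endo * ctx$W_endo + cal$h_substrate * ctx$W_sub) * baseT
    rob_diag <- rob_diag_full[free]
    rob_rhs <- rob_rhs_full[free]
    nsteps <- max(1L, round(seg$duration_s / dt))
    powered <- seg$power_W > 0

    for (step in seq_len(nsteps)) {
      # --- electric solve + power control
      if (powered) {
        Te <- elem_T(mesh, T)
        sigma_e <- matv$sigma_ref * (1 + matv$sigma_slope * (Te - matv$T_ref))
        sigma_e[ctx$cloud_e] <- sigma_e[ctx$cloud_e] * cmult
        kv <- fem_stiff_values(ctx$prob_elec, sigma_e[ctx$elec_elems])
        gpl <- cal$plate_conductance
        dadd_e <- if (gpl > 0) (gpl * ctx$W_plate)[ctx$prob_elec$free] else NULL
        x <- fem_solve(ctx$prob_elec, kv, dadd_e,
                       numeric(ctx$prob_elec$nfree))
        V <- fem_expand(ctx$prob_elec, x)
        g2 <- fem_grad2(mesh, ctx$elec_elems, V)
        raw <- sum(sigma_e[ctx$elec_elems] * g2 * 2 * pi *
                   mesh$rbar[ctx$elec_elems] * mesh$area[ctx$elec_elems]) +
          if (gpl > 0) sum(gpl * ctx$W_plate * V^2) else 0
        sc <- power_control_scale(raw, seg$power_W)
        q_e <- numeric(nrow(mesh$tri))
        q_e[ctx$elec_elems] <- sigma_e[ctx$elec_elems] * g2 * sc^2
        Fq <- as.vector(Smat %*% q_e)
        applied_V <- sc
        current_A <- seg$power_W / sc
      } else {
        Fq <- numeric(n)
        applied_V <- 0
        current_A <- 0
      }

      # --- implicit thermal step with Picard coefficient iteration
      Tstar <- T
      iters <- 0L
      repeat {
        iters <- iters + 1L
        Te <- elem_T(mesh, Tstar)
        k_e <- matv$k_ref * (1 + matv$k_slope * (Te - matv$T_ref))
        k_e[ctx$is_blood_e] <- k_e[ctx$is_blood_e] * keff_mult
        rhoc_e <- matv$rho * (matv$c_ref + matv$c_slope * (Te - matv$T_ref))
        Mdiag <- as.vector(Smat %*% rhoc_e)
        sink_diag_full <- if (sink_w > 0)
          sink_w * as.vector(Smat %*% (rhoc_e * ctx$is_blood_e)) else NULL
        kv_t <- fem_stiff_values(prob, k_e)
        dadd <- Mdiag[free] / dt + rob_diag
        rhs <- Mdiag[free] / dt * T[free] + Fq[free] + rob_rhs
        if (!is.null(sink_diag_full)) {
          dadd <- dadd + sink_diag_full[free]
          rhs <- rhs + sink_diag_full[free] * baseT
        }
        Tn_free <- fem_solve(prob, kv_t, dadd, rhs)
        Tn <- fem_expand(prob, Tn_free, fill = baseT)
        dTi <- max(abs(Tn - Tstar))
        Tstar <- Tn
        if (dTi <= num$picard_tol * max(1, max(abs(Tn))) ||
            iters >= num$max_picard_iters) break
      }
      if (dTi > 10 * num$picard_tol * max(1, max(abs(Tn))))
        stop(sprintf("Picard iteration did not converge (step t = %.3f s, residual %.2g C)",
                     t + dt, dTi), call. = FALSE)

      if (audit) {
        aud$dH <- aud$dH + sum(Mdiag * (Tn - T))
        if (powered) aud$E_in <- aud$E_in + seg$power_W * dt
        aud$robin_out <- aud$robin_out +
          dt * sum(rob_diag_full * Tn - rob_rhs_full)
        if (!is.null(sink_diag_full))
          aud$sink_out <- aud$sink_out +
            dt * sum(sink_diag_full * (Tn - baseT))
        aud$dirichlet_out <- aud$dirichlet_out +
          dt * sum(kv_t[prob$sel_rf] * Tn[prob$j_rf])
        # Joule power deposited at temperature-clamped far-field nodes
        # (the dispersive-return ring): an immediate loss in the books
        aud$return_out <- aud$return_out + dt * sum(Fq[prob$isfix])
      }

      T <- Tn
      Tmax <- pmax(Tmax, T)
      t <- t + dt
      if (powered) delivered <- delivered + seg$power_W * dt

      maxTt <- max(T[ctx$tissue_nodes])
      maxTs <- max(T[ctx$shell_nodes])
      irow <- irow + 1L
      tr[irow, ] <- c(t, if (powered) seg$power_W else 0, maxTt, maxTs,
                      applied_V, current_A, iters)
      tr_phase[irow] <- seg$phase

      # --- complication monitors (active while power is on)
      if (powered && is.null(event)) {
        ev <- check_complications(
          list(T = T, t = t, mesh = mesh), th,
          shell_nodes = ctx$shell_nodes, tissue_nodes = ctx$tissue_nodes)
        if (!is.null(ev)) {
          event <- ev
          power_off_Tmax <- Tmax
          # abandon the rest of the schedule; cool down
          segments <- c(segments[seq_len(seg_i)],
                        list(schedule_segment(num$cooldown_duration_s, 0, Q,
                                              "cooldown", num$dt_cooldown_s)))
          seg_i <- seg_i  # current segment ends now
          break
        }
      }
      # --- early exit once nothing can extend the lesion any more
      if (!powered && seg$phase == "cooldown" &&
          max(T[ctx$tissue_nodes]) < iso) break
    }
    if (powered && is.null(power_off_Tmax) &&
        (seg_i == length(segments) ||
         !any(vapply(segments[-seq_len(seg_i)], function(s) s$power_W > 0,
                     logical(1))))) {
      power_off_Tmax <- Tmax
    }
    if (!is.null(event) && seg$phase != "cooldown") {
      seg_i <- length(segments)  # jump to appended cooldown
    } else {
      seg_i <- seg_i + 1L
    }
  }

  list(T = T, Tmax = Tmax, t = t, event = event,
       delivered_energy_J = delivered,
       power_off_Tmax = power_off_Tmax %||% Tmax,
       traces = {
         df <- as.data.frame(tr[seq_len(irow), , drop = FALSE])
         df$phase <- tr_phase[seq_len(irow)]
         df
       },
       audit = if (audit) aud else NULL)
}

#' Run a single virtual RF application
#'
#' Orchestrates one power-controlled application: per time step the
#' potential is re-solved on the current conductivity field, rescaled to
#' the protocol power, the bioheat equation is advanced implicitly, the
#' running maximum temperature field is updated and the complication
#' monitors (steam pop: tissue >= 97 C; charring: blood shell >= 80 C)
#' are evaluated. On a threshold crossing the application ends (power to
#' zero) but the simulation continues through the cool-down so the
#' partial lesion is still measured. Lesion metrics are extracted from
#' the cumulative maximum-temperature field at the end of the cool-down
#' (capturing thermal latency); the field at power-off is also measured
#' and reported.
#'
#' @param config an [simulation_config()].
#' @param calibration an [cooling_calibration()]; defaults to the shipped
#'   stage-1 fit.
#' @param context optional precomputed run context (mesh + assembled
#'   problem structure) from a previous run with identical geometry,
#'   materials and numerics; reuse makes parameter sweeps much cheaper.
#' @param audit accumulate the global energy-balance audit.
#' @return An object of class `abl_result`: `outcome` (`"safe"`,
#'   `"pop"`, `"charring"`), `event` (an `abl_event` or `NULL`),
#'   `event_time_s`, `lesion` (an `abl_lesion`), `lesion_at_power_off`,
#'   `delivered_energy_J`, `traces` (per-step time series), `audit`,
#'   `manifest`.
#' @export
run_application <- function(config, calibration = default_cooling(),
                            context = NULL, audit = FALSE) {
  ctx <- context %||% build_run_context(config, calibration)
  # rebind run-time knobs: a cached context carries only geometry-,
  # material- and numerics-dependent precomputation
  ctx$config <- config
  ctx$calibration <- calibration
  num <- config$numerics
  p <- config$protocol
  Q <- config$cooling$irrigation_ml_min
  segments <- list(
    schedule_segment(p$duration_s, p$power_W, Q, "heating", num$dt_heating_s),
    schedule_segment(num$cooldown_duration_s, 0, Q, "cooldown",
                     num$dt_cooldown_s))
  st <- run_schedule(ctx, segments, audit = audit)
  finish_result(ctx, st, completed = is.null(st$event))
}

finish_result <- function(ctx, st, completed) {
  cfg <- ctx$config
  iso <- cfg$thresholds$lesion_isotherm_C
  lesion <- extract_lesion(st$Tmax, ctx$mesh, iso = iso)
  lesion_po <- extract_lesion(st$power_off_Tmax, ctx$mesh, iso = iso)
  outcome <- classify_outcome(if (is.null(st$event)) list() else list(st$event),
                              completed = completed)
  structure(list(outcome = outcome, event = st$event,
                 event_time_s = if (!is.null(st$event)) st$event$time_s else NA_real_,
                 lesion = lesion, lesion_at_power_off = lesion_po,
                 delivered_energy_J = st$delivered_energy_J,
                 traces = st$traces, audit = st$audit,
                 T_final = st$T, Tmax_final = st$Tmax,
                 manifest = run_manifest(ctx)),
            class = "abl_result")
}

run_manifest <- function(ctx) {
  list(config = ctx$config, calibration = ctx$calibration,
       insertion_depth_mm = ctx$geom$insertion_depth_mm,
       contact_area_mm2 = ctx$geom$contact_area_mm2,
       mesh_nodes = nrow(ctx$mesh$nodes), mesh_elements = nrow(ctx$mesh$tri),
       package_version = as.character(utils::packageVersion("rfablate")))
}

#' @export
print.abl_result <- function(x, ...) {
  cat(sprintf("<abl_result> outcome: %s%s\n", x$outcome,
              if (!is.na(x$event_time_s))
                sprintf(" (at %.2f s)", x$event_time_s) else ""))
  cat(sprintf("  lesion: D %.2f mm, W %.2f mm, DW %.2f mm, V %.1f mm^3\n",
              x$lesion$depth_D_mm, x$lesion$width_W_mm,
              x$lesion$depth_at_width_DW_mm, x$lesion$volume_mm3))
  cat(sprintf("  delivered energy: %.0f J\n", x$delivered_energy_J))
  invisible(x)
}

#' Run a two-application sequence
#'
#' Runs a first application, keeps the thermal state alive through an
#' inter-application interval (power off, irrigation at 2 ml/min, the
#' protocol rate restored 1 s before re-energizing), then delivers a
#' second identical application with monitors active, followed by the
#' cool-down. The combined lesion is taken from the cumulative
#' maximum-temperature field, so the second application automatically
#' sees the altered thermal/electrical conductivity of the pre-heated
#' tissue. Refuses if the first application is not safe.
#'
#' @param config an [simulation_config()].
#' @param interval_s time between end of the first and start of the
#'   second application, s.
#' @param calibration an [cooling_calibration()].
#' @param context optional precomputed context (see [run_application()]).
#' @param first optional precomputed single-application `abl_result` for
#'   the same configuration (reused as the reference lesion).
#' @param inter_irrigation_ml_min irrigation rate between applications.
#' @return List with `first` (single-application result), `combined`
#'   (sequence result), `volume_increase_pct`, `second_outcome`.
#' @export
run_sequence <- function(config, interval_s, calibration = default_cooling(),
                         context = NULL, first = NULL,
                         inter_irrigation_ml_min = 2) {
  stopifnot(interval_s > 0)
  ctx <- context %||% build_run_context(config, calibration)
  ctx$config <- config
  ctx$calibration <- calibration
  if (is.null(first)) first <- run_application(config, calibration, context = ctx)
  if (first$outcome != "safe")
    stop("first application is not safe (", first$outcome,
         "); refusing a second application", call. = FALSE)
  num <- config$numerics
  p <- config$protocol
  Q <- config$cooling$irrigation_ml_min
  pre_s <- min(1, interval_s)
  segments <- list(
    schedule_segment(p$duration_s, p$power_W, Q, "heating", num$dt_heating_s))
  if (interval_s > pre_s) {
    segments <- c(segments, list(
      schedule_segment(interval_s - pre_s, 0, inter_irrigation_ml_min,
                       "inter_application", num$dt_heating_s)))
  }
  segments <- c(segments, list(
    schedule_segment(pre_s, 0, Q, "inter_application", num$dt_heating_s),
    schedule_segment(p$duration_s, p$power_W, Q, "heating", num$dt_heating_s),
    schedule_segment(num$cooldown_duration_s, 0, Q, "cooldown",
                     num$dt_cooldown_s)))
  st <- run_schedule(ctx, segments, audit = FALSE)
  combined <- finish_result(ctx, st, completed = is.null(st$event))
  V1 <- first$lesion$volume_mm3
  dV <- if (V1 > 0) 100 * (combined$lesion$volume_mm3 - V1) / V1 else NA_real_
  list(first = first, combined = combined, volume_increase_pct = dV,
       second_outcome = combined$outcome)
}
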