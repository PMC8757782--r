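#' Reduced cooling calibration
#'
#' Parameters of the reduced convective models that replace the fluid
#' dynamics of the blood/saline compartment:
#' \itemize{
#'   \item saline irrigation as a convective (Robin) film over the
#'     blood-exposed electrode surface, coefficient
#'     \eqn{h_{irr}(Q) = a Q^b} (W/(m^2 K), Q in ml/min), with the band
#'     next to the metal/shaft junction left uncooled (the coplanar distal
#'     pores do not flush it);
#'   \item blood-flow enhanced transport as an effective-conductivity
#'     multiplier \eqn{m(v) = 1 + c v^d} on the blood region (1 at
#'     stagnation);
#'   \item a volumetric sink relaxing blood towards the baseline
#'     temperature at rate \eqn{w(v) = a_s v^{b_s}} (1/s), zero in
#'     stagnant blood;
#'   \item an endocardial-surface film \eqn{h_{endo}(v) = a_e v^{b_e}}
#'     (W/(m^2 K)) modeling blood washing of the tissue surface.
#' }
#'
#' @param h_irr numeric `c(a, b)` of the irrigation film power law.
#' @param keff numeric `c(c, d)` of the conductivity multiplier.
#' @param h_endo numeric `c(a, b)` of the endocardial film.
#' @param blood_sink numeric `c(a, b)` of the blood relaxation rate.
#' @param sigma_cloud numeric `c(a, b, radius_mm)`: the irrigation jets
#'   keep a saline-rich pool around the tip; blood within `radius_mm` of
#'   the electrode surface carries `1 + a Q^b` times the blood electrical
#'   conductivity (Q in ml/min), effectively enlarging the
#'   current-emitting surface; the shunt strengthens with irrigation
#'   rate and vanishes at Q = 0.
#' @param plate_conductance electrical surface conductance (S/m^2) of
#'   the contact between the tissue's far face and the grounded return
#'   plate of the reference rig (the tissue holder is an imperfect
#'   conductor): a Robin condition in the potential problem. 0 leaves
#'   only the remote bath return; large values approach a grounded
#'   plate. Controls how much current crosses the wall axially and hence
#'   the thin-wall (atrial) heating excess.
#' @param h_substrate convective film at the far (epicardial/substrate)
#'   face of the tissue wall, W/(m^2 K), relaxing towards the baseline
#'   temperature: the in-vitro reference setup rests the tissue on a
#'   holder in a thermostated bath, neither a perfect insulator nor a
#'   perfect heat sink.
#' @param cooled_fraction fraction of the blood-exposed metal surface
#'   (measured axially from the tip) flushed directly by the irrigation
#'   film; the remaining band up to the metal/shaft junction is not in
#'   the jets' path.
#' @param junction_h_frac fraction of the irrigation film coefficient
#'   received indirectly (by entrainment) at the uncooled junction band
#'   and the adjacent shaft surface.
#' @param shell_mm thickness of the blood shell around the blood-exposed
#'   electrode surface and shaft junction on which charring is monitored.
#' @param provenance free-text record of how the values were obtained.
#' @return An object of class `abl_cooling`.
#' @export
cooling_calibration <- function(h_irr, keff, h_endo, blood_sink,
                                sigma_cloud = c(0, 0.25, 8),
                                plate_conductance = 0,
                                h_substrate = 300,
                                cooled_fraction = 0.75,
                                junction_h_frac = 0.2, shell_mm = 0.3,
                                provenance = "unspecified") {
  chk <- function(x, nm, n = 2) {
    if (!is.numeric(x) || length(x) != n || any(!is.finite(x)) || any(x < 0))
      stop("cooling_calibration: ", nm, " must be ", n,
           " non-negative finite numbers", call. = FALSE)
  }
  chk(h_irr, "h_irr"); chk(keff, "keff"); chk(h_endo, "h_endo")
  chk(blood_sink, "blood_sink"); chk(sigma_cloud, "sigma_cloud", 3)
  chk(h_substrate, "h_substrate", 1)
  chk(plate_conductance, "plate_conductance", 1)
  if (cooled_fraction <= 0 || cooled_fraction > 1)
    stop("cooled_fraction must lie in (0, 1]", call. = FALSE)
  if (junction_h_frac < 0 || junction_h_frac > 1)
    stop("junction_h_frac must lie in [0, 1]", call. = FALSE)
  if (shell_mm <= 0) stop("shell_mm must be > 0", call. = FALSE)
  structure(list(h_irr = unname(h_irr), keff = unname(keff),
                 h_endo = unname(h_endo), blood_sink = unname(blood_sink),
                 sigma_cloud = unname(sigma_cloud),
                 plate_conductance = unname(plate_conductance),
                 h_substrate = unname(h_substrate),
                 cooled_fraction = cooled_fraction,
                 junction_h_frac = junction_h_frac, shell_mm = shell_mm,
                 provenance = provenance),
            class = "abl_cooling")
}

#' @export
print.abl_cooling <- function(x, ...) {
  cat("<abl_cooling>\n")
  cat(sprintf("  h_irr(Q) = %.4g Q^%.3g W/(m^2 K) | m(v) = 1 + %.4g v^%.3g\n",
              x$h_irr[1], x$h_irr[2], x$keff[1], x$keff[2]))
  cat(sprintf("  h_endo(v) = %.4g v^%.3g | sink w(v) = %.4g v^%.3g 1/s\n",
              x$h_endo[1], x$h_endo[2], x$blood_sink[1], x$blood_sink[2]))
  cat(sprintf("  saline cloud: 1 + %.4g Q^%.3g within %.1f mm | h_substrate %.4g | plate g %.4g\n",
              x$sigma_cloud[1], x$sigma_cloud[2], x$sigma_cloud[3],
              x$h_substrate, x$plate_conductance))
  cat(sprintf("  cooled fraction %.2f, charring shell %.2f mm\n",
              x$cooled_fraction, x$shell_mm))
  cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Irrigation film coefficient
#'
#' @param cal an [cooling_calibration()].
#' @param Q irrigation rate, ml/min.
#' @return Convective coefficient, W/(m^2 K); 0 at Q = 0.
#' @export
irrigation_h <- function(cal, Q) {
  stopifnot(inherits(cal, "abl_cooling"), all(Q >= 0))
  cal$h_irr[1] * Q^cal$h_irr[2]
}

#' Blood effective-conductivity multiplier
#'
#' @param cal an [cooling_calibration()].
#' @param v blood velocity, m/s.
#' @return Dimensionless multiplier; 1 at v = 0 (stagnant blood conducts
#'   only).
#' @export
blood_keff_multiplier <- function(cal, v) {
  stopifnot(inherits(cal, "abl_cooling"), all(v >= 0))
  1 + cal$keff[1] * v^cal$keff[2]
}

#' Endocardial-surface film coefficient
#'
#' @param cal an [cooling_calibration()].
#' @param v blood velocity, m/s.
#' @return Convective coefficient, W/(m^2 K); 0 at v = 0.
#' @export
endocardial_h <- function(cal, v) {
  stopifnot(inherits(cal, "abl_cooling"), all(v >= 0))
  cal$h_endo[1] * v^cal$h_endo[2]
}

#' Saline-cloud conductivity multiplier
#'
#' @param cal an [cooling_calibration()].
#' @param Q irrigation rate, ml/min.
#' @return Multiplier on the blood electrical conductivity inside the
#'   cloud; 1 at Q = 0.
#' @export
cloud_multiplier <- function(cal, Q) {
  stopifnot(inherits(cal, "abl_cooling"), all(Q >= 0))
  1 + cal$sigma_cloud[1] * Q^cal$sigma_cloud[2]
}

#' Blood volumetric relaxation rate
#'
#' @param cal an [cooling_calibration()].
#' @param v blood velocity, m/s.
#' @return Relaxation rate towards baseline blood temperature, 1/s.
#' @export
blood_sink_rate <- function(cal, v) {
  stopifnot(inherits(cal, "abl_cooling"), all(v >= 0))
  cal$blood_sink[1] * v^cal$blood_sink[2]
}

#' Default (stage-1 calibrated) cooling parameters
#'
#' The shipped values were obtained by the stage-1 procedure of
#' [calibrate_cooling()]: a least-squares fit of the free parameters on
#' the two standard 30 W/30 s reference lesions (atrium depth 5.31 mm /
#' width 7.59 mm; ventricle 4.53 mm / 6.49 mm) at the `"coarse"` numerics
#' preset. HPSD protocols are never fitting targets.
#'
#' @return An `abl_cooling`.
#' @export
default_cooling <- function() {
  cooling_calibration(
    h_irr = c(1200, 0.8),
    keff = c(25, 0.8),
    h_endo = c(4000, 0.8),
    blood_sink = c(250, 1.0),
    sigma_cloud = c(1.232, 0.25, 8),
    plate_conductance = 0,
    h_substrate = 20,
    cooled_fraction = 0.75,
    junction_h_frac = 0.25,
    shell_mm = 0.3,
    provenance = paste("stage-1 least-squares fit on the two 30 W/30 s",
                       "reference lesions (atrium and ventricle), coarse",
                       "numerics preset"))
}

#' Calibrate the reduced cooling model against reference lesions
#'
#' Stage-1 calibration: a deterministic least-squares fit of a chosen
#' subset of cooling parameters so that simulated lesion depth and width
#' match the supplied reference lesions. The objective is the sum of
#' squared relative errors in (depth, width) over all references. Free
#' parameters are optimized on a log scale (they are positive) with
#' Nelder-Mead.
#'
#' @param references list of entries `list(config = <abl_config>,
#'   depth_mm = <target>, width_mm = <target>)`.
#' @param start starting [cooling_calibration()]; defaults to the shipped
#'   values.
#' @param free character vector of free parameters among
#'   `"h_irr_a"`, `"keff_c"`, `"h_endo_a"`, `"blood_sink_a"`,
#'   `"sigma_cloud_a"`, `"h_substrate"`.
#' @param maxit maximum objective evaluations for the optimizer.
#' @param reltol optimizer relative convergence tolerance.
#' @param residual_ceiling per-target relative residual above which the
#'   result is flagged (`converged_within_ceiling = FALSE`).
#' @param verbose print objective values as the fit proceeds.
#' @return An `abl_cooling` with attributes `residuals` (per-reference
#'   relative errors), `objective`, `converged_within_ceiling` and
#'   `evaluations`.
#' @export
calibrate_cooling <- function(references, start = default_cooling(),
                              free = "h_substrate",
                              maxit = 60, reltol = 1e-3,
                              residual_ceiling = 0.05, verbose = FALSE) {
  stopifnot(length(references) >= 1)
  for (ref in references) {
    if (!inherits(ref$config, "abl_config") || is.null(ref$depth_mm) ||
        is.null(ref$width_mm))
      stop("each reference needs config, depth_mm, width_mm", call. = FALSE)
  }
  free <- match.arg(free, c("h_irr_a", "keff_c", "h_endo_a", "blood_sink_a",
                            "sigma_cloud_a", "h_substrate"),
                    several.ok = TRUE)
  get_par <- function(cal) {
    vapply(free, function(f) switch(f,
      h_irr_a = cal$h_irr[1], keff_c = cal$keff[1],
      h_endo_a = cal$h_endo[1], blood_sink_a = cal$blood_sink[1],
      sigma_cloud_a = cal$sigma_cloud[1], h_substrate = cal$h_substrate),
      numeric(1))
  }
  set_par <- function(cal, p) {
    for (i in seq_along(free)) {
      v <- p[i]
      switch(free[i],
             h_irr_a = { cal$h_irr[1] <- v },
             keff_c = { cal$keff[1] <- v },
             h_endo_a = { cal$h_endo[1] <- v },
             blood_sink_a = { cal$blood_sink[1] <- v },
             sigma_cloud_a = { cal$sigma_cloud[1] <- v },
             h_substrate = { cal$h_substrate <- v })
    }
    cal
  }
  # contexts are geometry/numerics-bound and reusable across objective
  # evaluations (the free parameters only enter at run time)
  ctxs <- lapply(references, function(ref)
    build_run_context(ref$config, start))
  resids <- function(cal) {
    unlist(lapply(seq_along(references), function(i) {
      ref <- references[[i]]
      res <- run_application(ref$config, calibration = cal,
                             context = ctxs[[i]])
      c(depth = (res$lesion$depth_D_mm - ref$depth_mm) / ref$depth_mm,
        width = (res$lesion$width_W_mm - ref$width_mm) / ref$width_mm)
    }))
  }
  neval <- 0L
  obj <- function(logp) {
    cal <- set_par(start, exp(logp))
    r <- resids(cal)
    neval <<- neval + 1L
    val <- sum(r^2)
    if (verbose) message(sprintf("  calib eval %d: obj = %.5f", neval, val))
    val
  }
  p0 <- log(get_par(start))
  if (length(p0) == 1) {
    opt <- stats::optimize(obj, interval = c(p0 - log(8), p0 + log(8)),
                           tol = max(reltol, 0.02))
    opt <- list(par = opt$minimum, value = opt$objective)
  } else {
    opt <- optim(p0, obj, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = reltol))
  }
  # keep the better of start and optimum (the bracketing search can end
  # on a slope for flat objectives)
  if (obj(p0) <= opt$value) opt <- list(par = p0, value = obj(p0))
  cal <- set_par(start, exp(opt$par))
  cal$provenance <- sprintf(
    "stage-1 least-squares fit of (%s) on %d reference lesion(s)",
    paste(free, collapse = ", "), length(references))
  r <- resids(cal)
  attr(cal, "residuals") <- r
  attr(cal, "objective") <- opt$value
  attr(cal, "evaluations") <- neval
  attr(cal, "converged_within_ceiling") <- all(abs(r) <= residual_ceiling)
  if (!all(abs(r) <= residual_ceiling))
    warning("calibration residual above the documented ceiling (",
            residual_ceiling * 100, "%)", call. = FALSE)
  cal
}
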