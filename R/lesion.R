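#' Complication monitor
#'
#' Checks the current temperature field against the steam-pop (tissue)
#' and charring (blood shell) thresholds. If both are crossed within one
#' step the tie is resolved by the larger threshold overshoot in degrees
#' C, charring winning ties broken in its favor only when its overshoot
#' is strictly larger.
#'
#' @param state list with nodal field `T`, clock `t` (s) and `mesh`.
#' @param thresholds_ a [thresholds()].
#' @param shell_nodes node indices of the charring monitor shell (blood
#'   nodes at/near the blood-exposed electrode surface and shaft
#'   junction).
#' @param tissue_nodes node indices of the tissue region.
#' @return An `abl_event` (kind, time, location, peak temperature) or
#'   `NULL` if no threshold is crossed.
#' @export
check_complications <- function(state, thresholds_, shell_nodes,
                                tissue_nodes) {
  stopifnot(inherits(thresholds_, "abl_thresholds"),
            length(shell_nodes) > 0, length(tissue_nodes) > 0)
  T <- state$T
  it <- tissue_nodes[which.max(T[tissue_nodes])]
  ib <- shell_nodes[which.max(T[shell_nodes])]
  over_pop <- T[it] - thresholds_$pop_tissue_T_C
  over_char <- T[ib] - thresholds_$charring_blood_T_C
  if (over_pop < 0 && over_char < 0) return(NULL)
  charring <- over_char >= 0 && (over_pop < 0 || over_char > over_pop)
  node <- if (charring) ib else it
  structure(list(kind = if (charring) "charring" else "pop",
                 time_s = state$t,
                 location_mm = 1e3 * state$mesh$nodes[node, ],
                 peak_T_C = T[node]),
            class = "abl_event")
}

#' @export
print.abl_event <- function(x, ...) {
  cat(sprintf("<abl_event> %s at %.2f s, T = %.1f C, (r, z) = (%.2f, %.2f) mm\n",
              x$kind, x$time_s, x$peak_T_C, x$location_mm[1], x$location_mm[2]))
  invisible(x)
}

#' Classify the application outcome
#'
#' Safe if and only if the application completed with no complication;
#' otherwise the complication kind.
#'
#' @param events list of `abl_event`s (at most one; the first complication
#'   ends the application, precluding the other).
#' @param completed did the application run to its full duration?
#' @return `"safe"`, `"pop"` or `"charring"`.
#' @export
classify_outcome <- function(events, completed) {
  if (length(events) > 1)
    stop("at most one complication event can occur per application",
         call. = FALSE)
  if (length(events) == 0) {
    if (!completed)
      stop("an application without events must have completed", call. = FALSE)
    return("safe")
  }
  events[[1]]$kind
}

#' Extract lesion metrics from a maximum-temperature field
#'
#' Identifies the lesion as the region of the tissue where the nodal
#' field reaches the isotherm, by linear interpolation along triangle
#' edges (no smoothing). Reported metrics, all relative to the undeformed
#' endocardial surface datum `z = 0`:
#' \describe{
#'   \item{depth_D_mm}{maximum depth below the datum;}
#'   \item{width_W_mm}{maximum diameter, twice the maximum radial extent;}
#'   \item{depth_at_width_DW_mm}{depth of the maximum-diameter location;}
#'   \item{volume_mm3}{axisymmetric volume `int 2 pi r dA` of the lesion
#'     cross-section.}
#' }
#' A lesion whose element set is not edge-connected is still measured
#' (global extrema and integral) and flagged via `n_components`.
#'
#' @param T_max nodal field, degrees C (cumulative maximum temperature).
#' @param mesh an `abl_mesh`.
#' @param iso lesion isotherm, degrees C.
#' @param datum_z_mm datum plane, mm (0 = undeformed endocardium).
#' @return An object of class `abl_lesion`.
#' @export
extract_lesion <- function(T_max, mesh, iso = 50, datum_z_mm = 0) {
  stopifnot(inherits(mesh, "abl_mesh"), length(T_max) == nrow(mesh$nodes))
  tis <- which(mesh$region == REG_TISSUE)
  tri <- mesh$tri[tis, , drop = FALSE]
  v1 <- T_max[tri[, 1]]; v2 <- T_max[tri[, 2]]; v3 <- T_max[tri[, 3]]
  cand <- which(pmax(v1, v2, v3) >= iso)
  empty <- structure(list(depth_D_mm = 0, width_W_mm = 0,
                          depth_at_width_DW_mm = 0, volume_mm3 = 0,
                          cross_section_mm2 = 0, n_components = 0L),
                     class = "abl_lesion")
  if (!length(cand)) return(empty)
  datum <- datum_z_mm * 1e-3
  vol <- 0; area2d <- 0
  minz <- Inf; maxr <- -Inf; z_at_maxr <- NA_real_
  for (e in cand) {
    id <- tri[e, ]
    px <- mesh$nodes[id, 1]; py <- mesh$nodes[id, 2]
    vv <- T_max[id]
    poly <- clip_triangle(px, py, vv, iso)
    if (is.null(poly)) next
    x <- poly[, 1]; y <- poly[, 2]
    xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
    cr <- x * yn - xn * y
    A <- sum(cr) / 2
    Sx <- sum((x + xn) * cr) / 6  # int x dA (signed)
    vol <- vol + 2 * pi * abs(Sx)
    area2d <- area2d + abs(A)
    minz <- min(minz, min(y))
    mr <- max(x)
    if (mr > maxr) {
      maxr <- mr
      z_at_maxr <- min(y[x >= mr - 1e-15])
    }
  }
  if (!is.finite(maxr)) return(empty)
  # connectivity flag over candidate elements sharing nodes
  comp <- count_components(tri[cand, , drop = FALSE])
  structure(list(depth_D_mm = max(0, 1e3 * (datum - minz)),
                 width_W_mm = 2e3 * maxr,
                 depth_at_width_DW_mm = max(0, 1e3 * (datum - z_at_maxr)),
                 volume_mm3 = 1e9 * vol,
                 cross_section_mm2 = 1e6 * area2d,
                 n_components = comp),
            class = "abl_lesion")
}

#' @export
print.abl_lesion <- function(x, ...) {
  cat(sprintf("<abl_lesion> D %.2f mm | W %.2f mm | DW %.2f mm | V %.1f mm^3%s\n",
              x$depth_D_mm, x$width_W_mm, x$depth_at_width_DW_mm,
              x$volume_mm3,
              if (x$n_components > 1) sprintf(" [%d components]", x$n_components)
              else ""))
  invisible(x)
}

# Clip a triangle against the half-plane {value >= iso}; returns the
# polygon vertex matrix (columns r, z) or NULL.
clip_triangle <- function(px, py, vv, iso) {
  if (all(vv >= iso)) return(cbind(px, py))
  keep <- vv >= iso
  if (!any(keep)) return(NULL)
  xs <- numeric(0); ys <- numeric(0)
  for (i in 1:3) {
    j <- if (i == 3) 1L else i + 1L
    if (keep[i]) { xs <- c(xs, px[i]); ys <- c(ys, py[i]) }
    if (xor(keep[i], keep[j])) {
      s <- (iso - vv[i]) / (vv[j] - vv[i])
      xs <- c(xs, px[i] + s * (px[j] - px[i]))
      ys <- c(ys, py[i] + s * (py[j] - py[i]))
    }
  }
  cbind(xs, ys)
}

# Number of node-connected components among a set of triangles.
count_components <- function(tri) {
  if (nrow(tri) == 0) return(0L)
  nodes <- sort(unique(as.integer(tri)))
  idx <- match(as.vector(tri), nodes)
  dim(idx) <- dim(tri)
  parent <- seq_along(nodes)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  for (e in seq_len(nrow(idx))) {
    r1 <- find(idx[e, 1])
    r2 <- find(idx[e, 2]); if (r2 != r1) parent[r2] <- r1
    r3 <- find(idx[e, 3]); r1 <- find(idx[e, 1])
    if (r3 != r1) parent[r3] <- r1
  }
  length(unique(vapply(seq_along(nodes), find, integer(1))))
}

#' Export the lesion isocontour as a polyline table
#'
#' Computes the iso-temperature segments (linear edge interpolation) of a
#' nodal field restricted to the tissue region and writes them as a
#' delimited text file with columns `segment, r_mm, z_mm`.
#'
#' @param T_max nodal field, degrees C.
#' @param mesh an `abl_mesh`.
#' @param path output path.
#' @param iso isotherm, degrees C.
#' @return The polyline data frame, invisibly.
#' @export
export_lesion_contour <- function(T_max, mesh, path, iso = 50) {
  tis <- which(mesh$region == REG_TISSUE)
  tri <- mesh$tri[tis, , drop = FALSE]
  segs <- list()
  for (e in seq_len(nrow(tri))) {
    id <- tri[e, ]
    vv <- T_max[id]
    if (max(vv) < iso || min(vv) >= iso) next
    px <- mesh$nodes[id, 1]; py <- mesh$nodes[id, 2]
    pts <- NULL
    for (i in 1:3) {
      j <- if (i == 3) 1L else i + 1L
      if (xor(vv[i] >= iso, vv[j] >= iso)) {
        s <- (iso - vv[i]) / (vv[j] - vv[i])
        pts <- rbind(pts, c(px[i] + s * (px[j] - px[i]),
                            py[i] + s * (py[j] - py[i])))
      }
    }
    if (!is.null(pts) && nrow(pts) == 2) segs[[length(segs) + 1L]] <- pts
  }
  if (!length(segs)) {
    df <- data.frame(segment = integer(0), r_mm = numeric(0),
                     z_mm = numeric(0))
  } else {
    df <- do.call(rbind, lapply(seq_along(segs), function(i) {
      data.frame(segment = i, r_mm = 1e3 * segs[[i]][, 1],
                 z_mm = 1e3 * segs[[i]][, 2])
    }))
  }
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(df)
}
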