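# Axisymmetric P1 finite-element core.
#
# All meshes live in the (r, z) half-plane in meters. Integrals carry the
# axisymmetric measure 2*pi*r, approximated per element with the centroid
# radius (one-point quadrature, exact enough for P1 grading).

# Build the derived element data used by every assembly: signed areas,
# centroid radii, shape-function gradient coefficients, the 9 geometric
# stiffness factors per element and a scatter matrix for lumped
# mass/load accumulation.
finalize_mesh <- function(nodes, tri, region, h_min = NA_real_,
                          h_max = NA_real_, geom = NULL,
                          compute_facets = TRUE) {
  stopifnot(ncol(nodes) == 2, ncol(tri) == 3)
  m <- nrow(tri)
  r1 <- nodes[tri[, 1], 1]; z1 <- nodes[tri[, 1], 2]
  r2 <- nodes[tri[, 2], 1]; z2 <- nodes[tri[, 2], 2]
  r3 <- nodes[tri[, 3], 1]; z3 <- nodes[tri[, 3], 2]
  det2 <- (r2 - r1) * (z3 - z1) - (r3 - r1) * (z2 - z1)
  flip <- det2 < 0
  if (any(flip)) {  # enforce positive orientation
    tmp <- tri[flip, 2]; tri[flip, 2] <- tri[flip, 3]; tri[flip, 3] <- tmp
    r2 <- nodes[tri[, 2], 1]; z2 <- nodes[tri[, 2], 2]
    r3 <- nodes[tri[, 3], 1]; z3 <- nodes[tri[, 3], 2]
    det2 <- (r2 - r1) * (z3 - z1) - (r3 - r1) * (z2 - z1)
  }
  area <- det2 / 2
  if (any(area <= 0)) stop("degenerate mesh elements", call. = FALSE)
  rbar <- (r1 + r2 + r3) / 3
  # grad(phi_i) = (b_i, c_i) / (2A)
  b1 <- z2 - z3; b2 <- z3 - z1; b3 <- z1 - z2
  c1 <- r3 - r2; c2 <- r1 - r3; c3 <- r2 - r1
  gb <- cbind(b1, b2, b3)
  gc <- cbind(c1, c2, c3)
  # stiffness factor for pair (i, j): 2*pi*rbar*(b_i b_j + c_i c_j)/(4A)
  fac <- 2 * pi * rbar / (4 * area)
  pairs <- cbind(c(1, 2, 3, 1, 2, 3, 1, 2, 3), c(1, 1, 1, 2, 2, 2, 3, 3, 3))
  Gfac <- matrix(0, m, 9)
  II <- matrix(0L, m, 9); JJ <- matrix(0L, m, 9)
  for (p in seq_len(9)) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    Gfac[, p] <- fac * (gb[, i] * gb[, j] + gc[, i] * gc[, j])
    II[, p] <- tri[, i]; JJ[, p] <- tri[, j]
  }
  wlump <- 2 * pi * rbar * area / 3  # per-node lumped weight (x material rho*c)
  n <- nrow(nodes)
  Smat <- Matrix::sparseMatrix(i = as.integer(tri), j = rep(seq_len(m), 3),
                               x = rep(wlump, 3), dims = c(n, m))
  mesh <- structure(list(nodes = nodes, tri = tri, region = as.integer(region),
                         area = area, rbar = rbar, gb = gb, gc = gc,
                         Gfac = Gfac, II = II, JJ = JJ, wlump = wlump,
                         Smat = Smat, h_min = h_min, h_max = h_max,
                         geom = geom, facets = NULL),
                    class = "abl_mesh")
  if (compute_facets) mesh$facets <- mesh_facets(mesh)
  mesh
}

# Boundary and inter-region interface facets with tags.
mesh_facets <- function(mesh) {
  tri <- mesh$tri
  m <- nrow(tri)
  ed <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  el <- rep(seq_len(m), 3)
  key_lo <- pmin(ed[, 1], ed[, 2])
  key_hi <- pmax(ed[, 1], ed[, 2])
  n <- nrow(mesh$nodes)
  key <- (key_lo - 1) * n + key_hi
  o <- order(key)
  key_s <- key[o]; el_s <- el[o]
  dup_next <- c(key_s[-1] == key_s[-length(key_s)], FALSE)
  dup_prev <- c(FALSE, dup_next[-length(dup_next)])
  single <- !dup_next & !dup_prev
  first <- dup_next
  # boundary facets (one adjacent element)
  bidx <- o[single]
  # interface facets (two adjacent elements of different region)
  f1 <- o[first]; f2 <- o[which(first) + 1]
  reg1 <- mesh$region[el_s[first]]
  reg2 <- mesh$region[c(el_s[-1], 0L)[first]]
  diffreg <- reg1 != reg2
  iidx <- f1[diffreg]
  ireg1 <- pmin(reg1[diffreg], reg2[diffreg])
  ireg2 <- pmax(reg1[diffreg], reg2[diffreg])

  nd <- mesh$nodes
  tol <- 1e-12
  rmax <- max(nd[, 1]); zmin <- min(nd[, 2]); zmax <- max(nd[, 2])
  tag_boundary <- function(idx) {
    a <- ed[idx, 1]; b <- ed[idx, 2]
    ra <- nd[a, 1]; rb <- nd[b, 1]; za <- nd[a, 2]; zb <- nd[b, 2]
    tag <- integer(length(idx))
    tag[abs(za - zmin) < tol & abs(zb - zmin) < tol] <- TAG_BOTTOM
    tag[abs(za - zmax) < tol & abs(zb - zmax) < tol] <- TAG_TOP
    tag[abs(ra - rmax) < tol & abs(rb - rmax) < tol] <- TAG_OUTER
    tag[ra < tol & rb < tol] <- TAG_AXIS
    tag
  }
  btag <- tag_boundary(bidx)
  itag <- integer(length(iidx))
  itag[ireg1 == REG_TISSUE & ireg2 == REG_ELECTRODE] <- TAG_ELECTRODE_TISSUE
  itag[ireg1 == REG_BLOOD & ireg2 == REG_ELECTRODE] <- TAG_ELECTRODE_BLOOD
  itag[ireg1 == REG_BLOOD & ireg2 == REG_SHAFT] <- TAG_SHAFT_BLOOD
  itag[ireg1 == REG_TISSUE & ireg2 == REG_BLOOD] <- TAG_ENDOCARDIUM

  idx <- c(bidx, iidx)
  tag <- c(btag, itag)
  keep <- tag > 0L
  idx <- idx[keep]; tag <- tag[keep]
  a <- ed[idx, 1]; b <- ed[idx, 2]
  len <- sqrt((nd[a, 1] - nd[b, 1])^2 + (nd[a, 2] - nd[b, 2])^2)
  rf <- (nd[a, 1] + nd[b, 1]) / 2
  zf <- (nd[a, 2] + nd[b, 2]) / 2
  list(n1 = a, n2 = b, tag = tag, length = len, rmid = rf, zmid = zf)
}

#' @export
print.abl_mesh <- function(x, ...) {
  cat(sprintf("<abl_mesh> %d nodes, %d triangles\n", nrow(x$nodes), nrow(x$tri)))
  tb <- table(factor(REGION_NAMES[x$region], levels = REGION_NAMES))
  cat("  elements:", paste(sprintf("%s %d", names(tb), tb), collapse = ", "), "\n")
  cat(sprintf("  extent: r [0, %.1f] mm, z [%.1f, %.1f] mm\n",
              1e3 * max(x$nodes[, 1]), 1e3 * min(x$nodes[, 2]),
              1e3 * max(x$nodes[, 2])))
  invisible(x)
}

#' Export a mesh in Gmsh MSH 2.2 interchange format
#'
#' Writes nodes and tagged triangles (region tag as the physical tag) so a
#' run can be inspected in standard mesh viewers.
#'
#' @param mesh an `abl_mesh`.
#' @param path output file path.
#' @param field optional nodal field written as a `$NodeData` block.
#' @param field_name label of the nodal field.
#' @return `path`, invisibly.
#' @export
write_mesh_msh <- function(mesh, path, field = NULL, field_name = "T") {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); m <- nrow(mesh$tri)
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$Nodes",
               as.character(n)), con)
  writeLines(sprintf("%d %.9g %.9g 0", seq_len(n), mesh$nodes[, 1],
                     mesh$nodes[, 2]), con)
  writeLines(c("$EndNodes", "$Elements", as.character(m)), con)
  writeLines(sprintf("%d 2 2 %d %d %d %d %d", seq_len(m), mesh$region,
                     mesh$region, mesh$tri[, 1], mesh$tri[, 2], mesh$tri[, 3]),
             con)
  writeLines("$EndElements", con)
  if (!is.null(field)) {
    writeLines(c("$NodeData", "1", sprintf('"%s"', field_name), "1", "0.0",
                 "3", "0", "1", as.character(n)), con)
    writeLines(sprintf("%d %.9g", seq_len(n), field), con)
    writeLines("$EndNodeData", con)
  }
  invisible(path)
}

# --- linear system machinery -------------------------------------------

# Precompute the Dirichlet-eliminated triplet layout for a subproblem:
# elements `elems`, fixed nodes `fixed` with values `fixed_val`.
fem_problem <- function(mesh, elems, fixed, fixed_val) {
  n <- nrow(mesh$nodes)
  isfix <- logical(n); isfix[fixed] <- TRUE
  valfix <- numeric(n); valfix[fixed] <- fixed_val
  # nodes actually touched by the subdomain
  used <- sort(unique(as.integer(mesh$tri[elems, ])))
  free <- used[!isfix[used]]
  nfree <- length(free)
  fmap <- integer(n); fmap[free] <- seq_len(nfree)
  ii <- as.integer(mesh$II[elems, ]); jj <- as.integer(mesh$JJ[elems, ])
  ff <- !isfix[ii] & !isfix[jj]
  fc <- !isfix[ii] & isfix[jj]
  list(mesh = mesh, elems = elems, free = free, nfree = nfree, fmap = fmap,
       isfix = isfix, valfix = valfix,
       sel_ff = which(ff), i_ff = fmap[ii[ff]], j_ff = fmap[jj[ff]],
       sel_fc = which(fc), i_fc = fmap[ii[fc]], v_fc = valfix[jj[fc]],
       cache = new.env(parent = emptyenv()))
}

# Stiffness values for the subproblem, one per triplet (length 9*|elems|),
# given the per-element diffusion coefficient on `elems`.
fem_stiff_values <- function(prob, coef_e) {
  as.vector(prob$mesh$Gfac[prob$elems, , drop = FALSE] * coef_e)
}

# Solve (K + diag(dadd))_ff x = b_free - K_fc v_fix, reusing the symbolic
# Cholesky factorization across calls with identical sparsity.
fem_solve <- function(prob, kvals, dadd, rhs_free) {
  A <- Matrix::sparseMatrix(i = prob$i_ff, j = prob$j_ff,
                            x = kvals[prob$sel_ff],
                            dims = c(prob$nfree, prob$nfree))
  if (!is.null(dadd)) A <- A + Matrix::Diagonal(prob$nfree, dadd)
  A <- Matrix::forceSymmetric(A, uplo = "U")
  if (length(prob$sel_fc)) {
    corr <- kvals[prob$sel_fc] * prob$v_fc
    rhs_free <- rhs_free - as.vector(Matrix::sparseMatrix(
      i = prob$i_fc, j = rep(1L, length(corr)), x = corr,
      dims = c(prob$nfree, 1)))
  }
  ch <- prob$cache$chol
  if (is.null(ch)) {
    ch <- Matrix::Cholesky(A, LDL = FALSE, super = TRUE)
  } else {
    ch <- Matrix::update(ch, A)
  }
  prob$cache$chol <- ch
  x <- as.vector(Matrix::solve(ch, rhs_free))
  x
}

# Scatter a free-node solution back to a full nodal vector (fixed values
# filled in; untouched nodes take `fill`).
fem_expand <- function(prob, xfree, fill = 0) {
  n <- nrow(prob$mesh$nodes)
  out <- rep(fill, n)
  out[prob$free] <- xfree
  out[prob$isfix] <- prob$valfix[prob$isfix]
  out
}

# Elementwise squared gradient of a nodal field on a subset of elements.
fem_grad2 <- function(mesh, elems, u) {
  tri <- mesh$tri[elems, , drop = FALSE]
  u1 <- u[tri[, 1]]; u2 <- u[tri[, 2]]; u3 <- u[tri[, 3]]
  gb <- mesh$gb[elems, , drop = FALSE]; gc <- mesh$gc[elems, , drop = FALSE]
  twoA <- 2 * mesh$area[elems]
  dr <- (u1 * gb[, 1] + u2 * gb[, 2] + u3 * gb[, 3]) / twoA
  dz <- (u1 * gc[, 1] + u2 * gc[, 2] + u3 * gc[, 3]) / twoA
  dr * dr + dz * dz
}
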