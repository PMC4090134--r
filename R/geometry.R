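# Deterministic geometry generators: straight and variable-thickness tubes,
# the idealized curved axisymmetric aneurysm profile with optional
# intraluminal thrombus, plane-strain rings, and seeded synthetic
# "patient-like" bumpy axisymmetric profiles.
#
# Meshes use 9-node Lagrange quadrilaterals (corners 1-4 counter-clockwise,
# mid-sides 5-8, center 9). Coordinates are (r, z) for axisymmetric
# formulations and (x, y) for plane strain. Lumen boundary edges are stored
# as ordered node triples (start, mid, end) with the solid domain on the
# left of the direction of travel, so that the left normal points into the
# solid.

#' Idealized curved axisymmetric aneurysm profile
#'
#' Axisymmetric outer-wall profile with cylindrical ends and a smooth
#' fusiform bulge at mid-height, built from a flat-topped super-Gaussian
#' bump: `B(Z) = Rn + (Rmax - Rn) exp(-((Z - H/2)/w)^4)`. The wall has
#' uniform thickness; when a lumen is included, the lumen radius follows a
#' narrower bump of smaller amplitude so that it stays inside the wall
#' everywhere, with the gap between lumen and inner wall filled by
#' intraluminal thrombus.
#'
#' @param height vessel height H (mm), default 130.
#' @param max_diameter maximum outer diameter (mm), default 50, reached at
#'   mid-height.
#' @param wall_thickness uniform wall thickness (mm), default 1.5.
#' @param neck_outer_diameter outer diameter of the cylindrical ends (mm).
#' @param bulge_width width parameter `w` of the outer-wall bump (mm).
#' @param lumen_bulge amplitude of the lumen-radius bump (mm); with the
#'   default geometry the thrombus is thickest (~10 mm) at mid-height and
#'   vanishes toward the ends.
#' @param lumen_width width parameter of the lumen bump (mm); must not
#'   exceed `bulge_width` so the lumen stays inside the wall.
#' @param with_lumen include a lumen/thrombus description.
#' @return an object of class `aaa_profile` with function fields
#'   `outer_radius(Z)` and (optionally) `lumen_radius(Z)`.
#' @examples
#' pr <- aaa_profile()
#' pr$outer_radius(65)  # 25 mm: the 50 mm maximum diameter
#' @export
aaa_profile <- function(height = 130, max_diameter = 50, wall_thickness = 1.5,
                        neck_outer_diameter = 22, bulge_width = 28,
                        lumen_bulge = 4, lumen_width = 24,
                        with_lumen = TRUE) {
  stopifnot(height > 0, wall_thickness > 0,
            max_diameter / 2 > neck_outer_diameter / 2)
  Rn <- neck_outer_diameter / 2
  Rmax <- max_diameter / 2
  h <- wall_thickness
  if (Rn - h <= 0) stop("neck too small for the wall thickness")
  if (with_lumen && lumen_width > bulge_width) {
    stop("lumen_width must not exceed bulge_width (lumen must stay inside the wall)")
  }
  zc <- height / 2
  outer <- function(Z) Rn + (Rmax - Rn) * exp(-((Z - zc) / bulge_width)^4)
  lumen <- if (with_lumen) {
    function(Z) (Rn - h) + lumen_bulge * exp(-((Z - zc) / lumen_width)^4)
  } else NULL
  structure(list(height = height, wall_thickness = h,
                 outer_radius = outer, lumen_radius = lumen,
                 label = "idealized-aaa"),
            class = "aaa_profile")
}

#' @export
print.aaa_profile <- function(x, ...) {
  zz <- seq(0, x$height, length.out = 257)
  cat(sprintf(
    "Axisymmetric profile '%s': height %g mm, wall %g mm, max outer radius %.4g mm%s\n",
    x$label, x$height, x$wall_thickness, max(x$outer_radius(zz)),
    if (is.null(x$lumen_radius)) "" else ", with lumen/thrombus"))
  invisible(x)
}

#' Synthetic patient-like axisymmetric profile
#'
#' Seed-controlled stand-in for an image-derived aneurysm geometry: a
#' 20 mm-radius luminal tube dilated by a sum of smooth Gaussian bumps with
#' randomized centers, widths and amplitudes, and a uniform 1.5 mm wall
#' displaced radially outward. Regeneration with the same seed is
#' bit-identical. This geometry is synthetic; it emulates the asymmetric-
#' in-Z dilation of real aneurysms but not their loss of axisymmetry.
#'
#' @param seed integer seed controlling the bump parameters.
#' @param n_bumps number of Gaussian bumps.
#' @param max_amplitude largest bump amplitude (mm); amplitudes are drawn
#'   in `[0.3, 1] * max_amplitude`. Zero gives a straight tube.
#' @param base_radius inner (lumen) radius of the undilated tube (mm).
#' @param height vessel height (mm).
#' @param wall_thickness uniform wall thickness (mm).
#' @return an `aaa_profile` (no lumen/thrombus description).
#' @export
make_patient_like_profile <- function(seed, n_bumps = 3, max_amplitude = 10,
                                      base_radius = 20, height = 130,
                                      wall_thickness = 1.5) {
  stopifnot(is.numeric(seed), length(seed) == 1, n_bumps >= 0,
            max_amplitude >= 0)
  if (n_bumps > 0 && max_amplitude > 0) {
    # draw bump parameters from the seed without disturbing the caller's
    # RNG stream
    old_seed <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                     envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
    rs <- list(centers = stats::runif(n_bumps, 0.25 * height, 0.75 * height),
               widths = stats::runif(n_bumps, 10, 22),
               amps = stats::runif(n_bumps, 0.3, 1) * max_amplitude)
  } else {
    rs <- list(centers = numeric(0), widths = numeric(0), amps = numeric(0))
  }
  inner <- function(Z) {
    r <- rep(base_radius, length(Z))
    for (k in seq_along(rs$amps)) {
      r <- r + rs$amps[k] * exp(-((Z - rs$centers[k]) / rs$widths[k])^2)
    }
    r
  }
  # steep bumps make structured meshing fail; reject before meshing does
  zz <- seq(0, height, length.out = 1025)
  slope <- max(abs(diff(inner(zz)) / diff(zz)))
  if (slope > 1.5) {
    stop("bump parameters produce a profile too steep to mesh (self-intersecting wall)")
  }
  structure(list(height = height, wall_thickness = wall_thickness,
                 outer_radius = function(Z) inner(Z) + wall_thickness,
                 lumen_radius = NULL,
                 label = sprintf("patient-like-seed%d", as.integer(seed))),
            class = "aaa_profile")
}

#' Wall-thickness modulation
#'
#' Cosine modulation of the wall thickness, applied on the outer surface:
#' `h(s) = h0 + amplitude * cos(2 pi n_waves s)` with `s in [0, 1]` the
#' normalized axial position (longitudinal mode) or `theta/2pi`
#' (circumferential mode).
#'
#' @param mode `"longitudinal"` or `"circumferential"`.
#' @param amplitude modulation amplitude (mm); the resulting thickness must
#'   stay positive.
#' @param n_waves number of full cosine waves over the extent.
#' @return an object of class `thickness_modulation`.
#' @export
thickness_modulation <- function(mode = c("longitudinal", "circumferential"),
                                 amplitude, n_waves = 1) {
  mode <- match.arg(mode)
  stopifnot(is.finite(amplitude), n_waves >= 1)
  structure(list(mode = mode, amplitude = amplitude, n_waves = n_waves),
            class = "thickness_modulation")
}

.mod_thickness <- function(h0, s, modulation) {
  if (is.null(modulation)) return(rep(h0, length(s)))
  h <- h0 + modulation$amplitude * cos(2 * pi * modulation$n_waves * s)
  if (any(h <= 0)) stop("thickness modulation drives the wall thickness to zero")
  h
}

# structured Q9 grid: coord_fun(u, v) -> cbind(x, y) over u,v in [0,1];
# nI elements along u, nJ along v. Returns nodes, elems and the node-id
# grid (rows = u stations, cols = v stations).
.structured_quad9 <- function(coord_fun, nI, nJ, wrap_u = FALSE) {
  mi <- 2L * nI + 1L
  mj <- 2L * nJ + 1L
  us <- seq(0, 1, length.out = mi)
  vs <- seq(0, 1, length.out = mj)
  if (wrap_u) {
    idg <- matrix(0L, mi, mj)
    idg[1:(mi - 1L), ] <- matrix(seq_len((mi - 1L) * mj), mi - 1L, mj)
    idg[mi, ] <- idg[1L, ]
    keep <- 1:(mi - 1L)
  } else {
    idg <- matrix(seq_len(mi * mj), mi, mj)
    keep <- 1:mi
  }
  uu <- rep(us[keep], times = mj)
  vv <- rep(vs, each = length(keep))
  nodes <- coord_fun(uu, vv)
  elems <- matrix(0L, nI * nJ, 9L)
  e <- 0L
  for (ej in seq_len(nJ)) {
    j0 <- 2L * ej - 1L
    for (ei in seq_len(nI)) {
      i0 <- 2L * ei - 1L
      e <- e + 1L
      elems[e, ] <- c(idg[i0, j0], idg[i0 + 2L, j0], idg[i0 + 2L, j0 + 2L],
                      idg[i0, j0 + 2L], idg[i0 + 1L, j0],
                      idg[i0 + 2L, j0 + 1L], idg[i0 + 1L, j0 + 2L],
                      idg[i0, j0 + 1L], idg[i0 + 1L, j0 + 1L])
    }
  }
  list(nodes = nodes, elems = elems, idg = idg)
}

.new_mesh <- function(nodes, elems, region, sets, extra = list()) {
  m <- c(list(nodes = nodes, elems = elems, region = region, sets = sets),
         extra)
  class(m) <- "fe_mesh"
  m
}

#' @export
print.fe_mesh <- function(x, ...) {
  cat(sprintf("FE mesh: %d nodes, %d 9-node quads (%s)\n",
              nrow(x$nodes), nrow(x$elems),
              paste(sprintf("%s: %d", names(table(x$region)),
                            table(x$region)), collapse = ", ")))
  cat(sprintf("  lumen edges: %d; fixed-z nodes: %d; fixed-x nodes: %d\n",
              nrow(x$sets$lumen_edges), length(x$sets$fix_z),
              length(x$sets$fix_x)))
  invisible(x)
}

# lumen edge triples along a node-id grid column i=1, ordered descending j
# (solid at larger i lies to the left of the direction of travel)
.edges_desc_j <- function(idg, nJ) {
  t(vapply(seq_len(nJ), function(ej) {
    j0 <- 2L * ej - 1L
    c(idg[1L, j0 + 2L], idg[1L, j0 + 1L], idg[1L, j0])
  }, integer(3)))
}

#' Structured axisymmetric tube mesh
#'
#' Quadratic-quad mesh of the annular wall `A <= r <= B`, `0 <= z <= length`,
#' with the lumen (inner) boundary tagged for pressure application and both
#' end faces constrained longitudinally.
#'
#' @param geom a [tube_geometry()].
#' @param n_thickness elements through the wall (default 6).
#' @param n_axial elements along the axis.
#' @param length axial extent (mm); defaults to four wall thicknesses (the
#'   solution of the constrained tube is z-independent).
#' @param modulation optional longitudinal [thickness_modulation()].
#' @return an `fe_mesh` with region `"wall"`.
#' @export
make_tube_mesh <- function(geom, n_thickness = 6, n_axial = 4,
                           length = NULL, modulation = NULL) {
  stopifnot(inherits(geom, "tube_geometry"), n_thickness >= 1, n_axial >= 1)
  if (!is.null(modulation) && modulation$mode != "longitudinal") {
    stop("tube meshes support longitudinal thickness modulation only; use make_ring_mesh")
  }
  A <- geom$A; h0 <- geom$B - geom$A
  if (is.null(length)) length <- 4 * h0
  cf <- function(u, v) {
    h <- .mod_thickness(h0, v, modulation)
    cbind(A + u * h, v * length)
  }
  g <- .structured_quad9(cf, n_thickness, n_axial)
  mj <- 2L * n_axial + 1L
  sets <- list(
    lumen_edges = .edges_desc_j(g$idg, n_axial),
    fix_z = c(g$idg[, 1L], g$idg[, mj]),
    fix_x = integer(0),
    outer_nodes = g$idg[2L * n_thickness + 1L, ])
  .new_mesh(g$nodes, g$elems, rep("wall", nrow(g$elems)), sets,
            extra = list(wall_grid = g$idg))
}

#' Mesh the curved axisymmetric aneurysm, optionally with thrombus
#'
#' Structured mesh of the wall (and, when requested, the intraluminal
#' thrombus) of an [aaa_profile()]. The thrombus region is meshed where its
#' thickness exceeds `thrombus_min_thickness`, conforming node-for-node
#' with the wall along the shared interface. Wall end faces are constrained
#' longitudinally; thrombus end faces are constrained in the longitudinal
#' direction only. The pressurized lumen boundary is the thrombus inner
#' surface where thrombus is present and the wall inner surface elsewhere.
#'
#' @param profile an [aaa_profile()].
#' @param with_thrombus mesh the thrombus region (requires a lumen).
#' @param n_wall elements through the wall thickness (default 3).
#' @param n_axial elements along the vessel axis.
#' @param n_thrombus elements through the thrombus thickness (default 10).
#' @param thrombus_min_thickness smallest thrombus thickness meshed (mm).
#' @return an `fe_mesh` with regions `"wall"` (and `"thrombus"`), plus
#'   node-id grids `wall_grid` / `thrombus_grid` for profile extraction.
#' @export
make_aaa_mesh <- function(profile, with_thrombus = FALSE, n_wall = 3,
                          n_axial = 40, n_thrombus = 10,
                          thrombus_min_thickness = 0.3) {
  stopifnot(inherits(profile, "aaa_profile"), n_wall >= 1, n_axial >= 2)
  H <- profile$height; h <- profile$wall_thickness
  outer <- profile$outer_radius
  inner <- function(Z) outer(Z) - h
  cf <- function(u, v) {
    Z <- v * H
    cbind(inner(Z) + u * h, Z)
  }
  g <- .structured_quad9(cf, n_wall, n_axial)
  mi <- 2L * n_wall + 1L
  mj <- 2L * n_axial + 1L
  region <- rep("wall", nrow(g$elems))
  sets <- list(lumen_edges = .edges_desc_j(g$idg, n_axial),
               fix_z = c(g$idg[, 1L], g$idg[, mj]),
               fix_x = integer(0),
               outer_nodes = g$idg[mi, ])
  extra <- list(wall_grid = g$idg, profile = profile)

  if (!with_thrombus) {
    return(.new_mesh(g$nodes, g$elems, region, sets, extra))
  }
  if (is.null(profile$lumen_radius)) {
    stop("profile has no lumen description: cannot mesh a thrombus")
  }
  lum <- profile$lumen_radius
  thick <- function(Z) inner(Z) - lum(Z)
  zb <- seq(0, H, length.out = n_axial + 1)
  zmid <- seq(0, H, length.out = 8 * n_axial + 1)
  if (min(thick(zmid)) < -1e-9) stop("lumen radius exceeds the inner wall radius")
  keep <- vapply(seq_len(n_axial), function(e) {
    zz <- seq(zb[e], zb[e + 1], length.out = 9)
    min(thick(zz)) >= thrombus_min_thickness
  }, logical(1))
  if (!any(keep)) stop("thrombus thinner than the meshing cutoff everywhere")
  rng <- range(which(keep))
  if (!all(keep[rng[1]:rng[2]])) stop("thrombus region is not contiguous")
  e1 <- rng[1]; e2 <- rng[2]
  nTe <- e2 - e1 + 1L                      # axial thrombus elements
  jlo <- 2L * e1 - 1L                      # first shared axial station
  Zt <- function(v) (zb[e1] + v * (zb[e2 + 1] - zb[e1]))
  # thrombus grid: u radial (lumen -> wall inner), v axial over [zb_e1, zb_e2+1]
  mti <- 2L * n_thrombus + 1L
  mtj <- 2L * nTe + 1L
  us <- seq(0, 1, length.out = mti)
  vs <- seq(0, 1, length.out = mtj)
  n0 <- nrow(g$nodes)
  idg_t <- matrix(0L, mti, mtj)
  new_nodes <- matrix(0, (mti - 1L) * mtj, 2L)
  cnt <- 0L
  for (j in seq_len(mtj)) {
    Z <- Zt(vs[j])
    for (i in seq_len(mti)) {
      if (i == mti) {
        idg_t[i, j] <- g$idg[1L, jlo + j - 1L]  # conforming interface
      } else {
        cnt <- cnt + 1L
        idg_t[i, j] <- n0 + cnt
        new_nodes[cnt, ] <- c(lum(Z) + us[i] * thick(Z), Z)
      }
    }
  }
  nodes <- rbind(g$nodes, new_nodes[seq_len(cnt), , drop = FALSE])
  elems_t <- matrix(0L, n_thrombus * nTe, 9L)
  e <- 0L
  for (ej in seq_len(nTe)) {
    j0 <- 2L * ej - 1L
    for (ei in seq_len(n_thrombus)) {
      i0 <- 2L * ei - 1L
      e <- e + 1L
      elems_t[e, ] <- c(idg_t[i0, j0], idg_t[i0 + 2L, j0],
                        idg_t[i0 + 2L, j0 + 2L], idg_t[i0, j0 + 2L],
                        idg_t[i0 + 1L, j0], idg_t[i0 + 2L, j0 + 1L],
                        idg_t[i0 + 1L, j0 + 2L], idg_t[i0, j0 + 1L],
                        idg_t[i0 + 1L, j0 + 1L])
    }
  }
  elems <- rbind(g$elems, elems_t)
  region <- c(region, rep("thrombus", nrow(elems_t)))
  # lumen: wall inner face outside the thrombus extent, thrombus inner within
  wall_edges <- .edges_desc_j(g$idg, n_axial)
  lum_edges <- rbind(wall_edges[-(e1:e2), , drop = FALSE],
                     .edges_desc_j(idg_t, nTe))
  thr_ends <- c(idg_t[, 1L], idg_t[, mtj])
  sets$lumen_edges <- lum_edges
  sets$fix_z <- unique(c(sets$fix_z, thr_ends))
  extra$thrombus_grid <- idg_t
  .new_mesh(nodes, elems, region, sets, extra)
}

#' Plane-strain ring (annulus) mesh
#'
#' Full-circle annular mesh in Cartesian coordinates, for plane-strain
#' analyses with circumferentially varying wall thickness. Rigid-body
#' motion is removed by constraining the normal-to-axis displacement at the
#' four symmetry stations (y at theta = 0 and pi, x at theta = pi/2 and
#' 3 pi/2); `n_theta` must be a multiple of 4.
#'
#' @param a inner radius (mm).
#' @param h0 nominal wall thickness (mm).
#' @param n_thickness elements through the wall.
#' @param n_theta elements around the circumference (multiple of 4).
#' @param modulation optional circumferential [thickness_modulation()].
#' @return an `fe_mesh` with region `"wall"`.
#' @export
make_ring_mesh <- function(a, h0, n_thickness = 3, n_theta = 16,
                           modulation = NULL) {
  stopifnot(a > 0, h0 > 0)
  if (n_theta %% 4 != 0) stop("n_theta must be a multiple of 4")
  if (!is.null(modulation) && modulation$mode != "circumferential") {
    stop("ring meshes support circumferential thickness modulation only")
  }
  cf <- function(u, v) {
    th <- -2 * pi * u                     # clockwise: solid left of travel
    h <- .mod_thickness(h0, u, modulation)
    r <- a + v * h
    cbind(r * cos(th), r * sin(th))
  }
  g <- .structured_quad9(cf, n_theta, n_thickness, wrap_u = TRUE)
  # lumen edges: v = 1 row... inner boundary is v = 0 (j = 1); travel along u
  edges <- t(vapply(seq_len(n_theta), function(ei) {
    i0 <- 2L * ei - 1L
    c(g$idg[i0, 1L], g$idg[i0 + 1L, 1L], g$idg[i0 + 2L, 1L])
  }, integer(3)))
  quarter <- n_theta / 4L
  fix_y <- c(g$idg[1L, ], g$idg[2L * (2L * quarter) + 1L, ])       # theta 0, pi
  fix_x <- c(g$idg[2L * quarter + 1L, ], g$idg[2L * (3L * quarter) + 1L, ])
  sets <- list(lumen_edges = edges,
               fix_z = unique(fix_y),     # y is the second coordinate
               fix_x = unique(fix_x),
               outer_nodes = g$idg[, 2L * n_thickness + 1L])
  .new_mesh(g$nodes, g$elems, rep("wall", nrow(g$elems)), sets,
            extra = list(ring_grid = g$idg))
}

#' Check element Jacobians
#'
#' Minimum Jacobian determinant of the isoparametric map over all 3x3
#' Gauss points of all elements; positive for a valid (non-inverted) mesh.
#'
#' @param mesh an `fe_mesh`.
#' @return smallest Jacobian determinant (mm^2).
#' @export
min_jacobian <- function(mesh) {
  gp <- .gauss9()
  dets <- vapply(seq_len(nrow(mesh$elems)), function(e) {
    xe <- mesh$nodes[mesh$elems[e, ], , drop = FALSE]
    min(vapply(seq_len(9), function(g) {
      J <- crossprod(gp$dN[[g]], xe)      # 2x2: dX/dxi
      J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
    }, numeric(1)))
  }, numeric(1))
  min(dets)
}

#' Total cross-sectional area of a mesh
#'
#' Sum of element areas by 3x3 Gauss quadrature of the isoparametric
#' Jacobian (plane measure; no axisymmetric weight).
#'
#' @param mesh an `fe_mesh`.
#' @return area (mm^2).
#' @export
mesh_area <- function(mesh) {
  gp <- .gauss9()
  sum(vapply(seq_len(nrow(mesh$elems)), function(e) {
    xe <- mesh$nodes[mesh$elems[e, ], , drop = FALSE]
    sum(vapply(seq_len(9), function(g) {
      J <- crossprod(gp$dN[[g]], xe)
      gp$w[g] * (J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1])
    }, numeric(1)))
  }, numeric(1)))
}
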