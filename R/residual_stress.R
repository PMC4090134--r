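# Opening-angle residual-stress model (semi-analytic, plane strain,
# incompressible).
#
# A radially cut unloaded ring springs open to a sector with opening angle
# phi; conversely, closing a stress-free open sector of sweep 2(pi - phi)
# into a full ring of fixed geometry (radii a0 < r < b0) generates
# self-equilibrated circumferential residual stress. With the angle-mapping
# factor k = pi/(pi - phi) the exact incompressible plane-strain kinematics
# of the closing map are
#   r^2 = a0^2 + (R^2 - A_open^2)/k,  lam_theta = k r / R,  lam_r = R/(k r),
# which reduces the residual problem to a single root-find for the open
# inner radius A_open such that the closed ring is traction-free on both
# surfaces. Loading the closed ring composes the same map with inflation.

#' Opening-angle configuration
#'
#' @param b0 closed unloaded outer radius (mm).
#' @param thickness wall thickness (mm); `a0 = b0 - thickness`. Supply
#'   either `thickness` or `a0`.
#' @param a0 closed unloaded inner radius (mm).
#' @param phi opening angle in degrees, `>= 0` and `< 180`. `phi = 0`
#'   means no residual stress (`k = 1`).
#' @return an object of class `residual_config` with the angle-mapping
#'   factor `k = pi/(pi - phi)`.
#' @export
residual_config <- function(b0, thickness = NULL, a0 = NULL, phi = 0) {
  if (is.null(a0)) {
    if (is.null(thickness)) stop("supply either a0 or thickness")
    a0 <- b0 - thickness
  }
  if (!(a0 > 0 && b0 > a0)) stop("residual config requires 0 < a0 < b0")
  if (!is.finite(phi) || phi < 0 || phi >= 180) {
    stop("phi must be an angle in [0, 180) degrees")
  }
  phi_rad <- phi * pi / 180
  structure(list(a0 = a0, b0 = b0, phi = phi, k = pi / (pi - phi_rad)),
            class = "residual_config")
}

# sigma_tt - sigma_rr at closed/loaded radius r, inner radius a_in, for the
# open->current map with factors k and open inner radius Ao
.res_dstress <- function(r, a_in, Ao, k, mat) {
  R2 <- Ao^2 + k * (r^2 - a_in^2)
  lt2 <- k^2 * r^2 / R2
  lr2 <- 1 / lt2
  2 * strain_energy_deriv(mat, lt2 + lr2 + 1) * (lt2 - lr2)
}

.res_profile <- function(a_in, b_out, Ao, k, mat, p, n_nodes, model) {
  r <- seq(a_in, b_out, length.out = n_nodes)
  srr <- -p + .cumgauss(function(s) .res_dstress(s, a_in, Ao, k, mat) / s, r)
  stt <- srr + .res_dstress(r, a_in, Ao, k, mat)
  R2 <- Ao^2 + k * (r^2 - a_in^2)
  lr2 <- R2 / (k^2 * r^2)
  szz <- srr + 2 * strain_energy_deriv(mat, k^2 * r^2 / R2 + lr2 + 1) * (1 - lr2)
  .tube_profile_df(r, srr, stt, szz, model, p, a_in, b_out, mat$label)
}

#' Solve for the residual-stress state of a closed unloaded ring
#'
#' Finds the stress-free open-sector geometry whose closure yields the
#' prescribed closed unloaded ring, and the self-equilibrated residual
#' circumferential stress in that ring. The one free parameter (open-sector
#' inner radius) is fixed by the traction-free condition on the closed
#' outer surface; the open outer radius follows from area preservation.
#'
#' @param cfg a [residual_config()].
#' @param mat a [hyperelastic_material()].
#' @param n_nodes number of radial sample nodes.
#' @return an object of class `residual_state`: list with `config`, `mat`,
#'   `open_A`, `open_B` (open-sector radii, mm) and `residual_profile`
#'   (a `tube_profile` on `[a0, b0]` at `p = 0`).
#' @examples
#' st <- solve_residual_state(residual_config(30, 1.5, phi = 45),
#'                            builtin_materials("RV"))
#' st$residual_profile$sigma_tt[1]  # compressive at the inner surface
#' @export
solve_residual_state <- function(cfg, mat, n_nodes = 201) {
  stopifnot(inherits(cfg, "residual_config"),
            inherits(mat, "hyperelastic_material"))
  a0 <- cfg$a0; b0 <- cfg$b0; k <- cfg$k
  if (cfg$phi == 0) {
    r <- seq(a0, b0, length.out = n_nodes)
    z <- numeric(n_nodes)
    prof <- .tube_profile_df(r, z, z, z, "residual", 0, a0, b0, mat$label)
    return(structure(list(config = cfg, mat = mat, open_A = a0, open_B = b0,
                          residual_profile = prof),
                     class = "residual_state"))
  }
  resid <- function(Ao) {
    stats::integrate(function(r) .res_dstress(r, a0, Ao, k, mat) / r,
                     a0, b0, rel.tol = 1e-12, abs.tol = 1e-14)$value
  }
  # Ao small -> circumferential stretch > 1 everywhere -> positive residual;
  # Ao large -> compressed -> negative. Bracket around sqrt(k)*a0.
  lo <- a0 * 0.9
  hi <- a0 * k * 1.5
  f_lo <- resid(lo); f_hi <- resid(hi)
  tries <- 0
  while (f_lo * f_hi > 0 && tries < 40) {
    lo <- lo * 0.95; hi <- hi * 1.1
    f_lo <- resid(lo); f_hi <- resid(hi)
    tries <- tries + 1
  }
  if (f_lo * f_hi > 0) {
    stop(sprintf(paste0("open-sector root not bracketed (residual %.3e / %.3e):",
                        " opening angle too extreme for this material"),
                 f_lo, f_hi))
  }
  Ao <- stats::uniroot(resid, c(lo, hi), tol = 1e-12)$root
  Bo <- sqrt(Ao^2 + k * (b0^2 - a0^2))
  prof <- .res_profile(a0, b0, Ao, k, mat, 0, n_nodes, "residual")
  structure(list(config = cfg, mat = mat, open_A = Ao, open_B = Bo,
                 residual_profile = prof),
            class = "residual_state")
}

#' @export
print.residual_state <- function(x, ...) {
  cat(sprintf(
    "Residual-stress state: phi=%g deg (k=%.4f), closed radii %.4g/%.4g mm, open %.4g/%.4g mm\n",
    x$config$phi, x$config$k, x$config$a0, x$config$b0, x$open_A, x$open_B))
  cat(sprintf("  residual sigma_tt inner/outer: %.4g / %.4g N/mm^2\n",
              x$residual_profile$sigma_tt[1],
              x$residual_profile$sigma_tt[nrow(x$residual_profile)]))
  invisible(x)
}

#' Load a residually stressed ring with internal pressure
#'
#' Composes the open-to-closed map with the inflation map (area preserving,
#' plane strain) and root-finds the loaded inner radius so that
#' `sigma_rr = -p` on the lumen and `0` on the outer surface.
#'
#' @param state a converged [solve_residual_state()] result.
#' @param p internal pressure (N/mm^2), `> 0` (use the plain tube solver
#'   for the unloaded state).
#' @param n_nodes number of radial sample nodes.
#' @return a `tube_profile` on the loaded radii.
#' @export
load_with_residual <- function(state, p, n_nodes = 201) {
  stopifnot(inherits(state, "residual_state"))
  if (!is.finite(p) || p < 0) stop("p must be finite and non-negative")
  cfg <- state$config; mat <- state$mat
  a0 <- cfg$a0; b0 <- cfg$b0; k <- cfg$k; Ao <- state$open_A
  if (p == 0) return(state$residual_profile)
  resid <- function(aL) {
    bL <- sqrt(aL^2 + b0^2 - a0^2)
    -p + stats::integrate(function(r) .res_dstress(r, aL, Ao, k, mat) / r,
                          aL, bL, rel.tol = 1e-12, abs.tol = 1e-14)$value
  }
  lo <- a0 * 0.8; hi <- a0 * 1.6
  f_lo <- resid(lo); f_hi <- resid(hi)
  tries <- 0
  while (f_lo * f_hi > 0 && tries < 40) {
    lo <- lo * 0.95; hi <- hi * 1.15
    f_lo <- resid(lo); f_hi <- resid(hi)
    tries <- tries + 1
  }
  if (f_lo * f_hi > 0) {
    stop("loaded inner radius not bracketed: pressure outside physical range")
  }
  aL <- stats::uniroot(resid, c(lo, hi), tol = 1e-12)$root
  bL <- sqrt(aL^2 + b0^2 - a0^2)
  .res_profile(aL, bL, Ao, k, mat, p, n_nodes, "residual-loaded")
}

#' Find the opening angle that uniformizes the loaded wall stress
#'
#' Sweeps the opening angle and minimizes the through-wall non-uniformity
#' (max minus min) of the loaded circumferential stress. A coarse grid
#' sweep brackets the minimum, refined with a golden-section search; if the
#' grid is not unimodal the grid minimum is returned with a warning flag.
#'
#' @param cfg a [residual_config()]; its `phi` is ignored (the angle is the
#'   search variable); closed radii are taken from it.
#' @param mat a [hyperelastic_material()].
#' @param p internal pressure (N/mm^2), strictly positive.
#' @param phi_max upper end of the searched angle range (degrees).
#' @param n_grid number of grid angles for the coarse sweep.
#' @param n_nodes radial nodes per profile evaluation.
#' @return list with `phi_opt` (degrees), `nonuniformity` (N/mm^2,
#'   max-min loaded sigma_tt at the optimum), `unimodal` flag and the
#'   sweep `grid` data frame.
#' @export
find_uniformizing_angle <- function(cfg, mat, p, phi_max = 120,
                                    n_grid = 13, n_nodes = 101) {
  stopifnot(inherits(cfg, "residual_config"))
  if (!is.finite(p) || p <= 0) {
    stop("p must be strictly positive: there is no load to uniformize")
  }
  nonunif <- function(phi) {
    c2 <- residual_config(cfg$b0, a0 = cfg$a0, phi = phi)
    st <- solve_residual_state(c2, mat, n_nodes = n_nodes)
    prof <- load_with_residual(st, p, n_nodes = n_nodes)
    max(prof$sigma_tt) - min(prof$sigma_tt)
  }
  phis <- seq(0, phi_max, length.out = n_grid)
  vals <- vapply(phis, nonunif, numeric(1))
  i <- which.min(vals)
  sgn <- diff(vals)
  unimodal <- sum(diff(sign(sgn)) != 0) <= 1
  if (!unimodal) {
    warning("non-unimodal non-uniformity sweep; returning grid minimum")
    return(list(phi_opt = phis[i], nonuniformity = vals[i],
                unimodal = FALSE,
                grid = data.frame(phi = phis, nonuniformity = vals)))
  }
  lo <- phis[max(1, i - 1)]; hi <- phis[min(n_grid, i + 1)]
  opt <- stats::optimize(nonunif, c(lo, hi), tol = 1e-3)
  list(phi_opt = opt$minimum, nonuniformity = opt$objective,
       unimodal = TRUE, grid = data.frame(phi = phis, nonuniformity = vals))
}
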