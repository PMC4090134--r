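# Closed-form / root-finding solutions for a pressurized, longitudinally
# constrained thick-wall circular tube.
#
# Nonlinear branch: incompressible hyperelastic wall, plane strain
# (lam_z = 1). With deformed radius r and undeformed radius R related by
# area preservation r^2 - a^2 = R^2 - A^2, the stretches are
# lam_theta = r/R, lam_r = R/r and the radial equilibrium ODE
#   d sigma_rr / dr = (sigma_tt - sigma_rr)/r,
#   sigma_tt - sigma_rr = 2 W'(I_B) (lam_theta^2 - lam_r^2)
# is integrated from sigma_rr(a) = -p; the deformed outer radius b is the
# root of sigma_rr(b) = 0.
#
# Linear branch: classical Lame plane-strain solution on the unchanged
# geometry (a = A, b = B); stresses depend on p only, not on E.

#' Unloaded tube geometry
#'
#' @param A unloaded inner radius (mm), `0 < A < B`.
#' @param B unloaded outer radius (mm).
#' @return an object of class `tube_geometry`.
#' @export
tube_geometry <- function(A, B) {
  stopifnot(is.finite(A), is.finite(B))
  if (!(A > 0 && B > A)) stop("tube geometry requires 0 < A < B")
  structure(list(A = A, B = B), class = "tube_geometry")
}

# circumferential-minus-radial stress at deformed radius r for inner radius a
# (unloaded inner radius A); vectorized over r.
.tube_dstress <- function(r, a, A, mat) {
  R2 <- r^2 - a^2 + A^2
  lt2 <- r^2 / R2
  lr2 <- R2 / r^2
  2 * strain_energy_deriv(mat, lt2 + lr2 + 1) * (lt2 - lr2)
}

# sigma_rr(b; a) - 0, integrating equilibrium from sigma_rr(a) = -p
.tube_outer_traction <- function(b, A, B, mat, p) {
  a <- sqrt(b^2 - B^2 + A^2)
  -p + stats::integrate(function(r) .tube_dstress(r, a, A, mat) / r,
                        a, b, rel.tol = 1e-12, abs.tol = 1e-14)$value
}

# cumulative integral of f over the ordered nodes r by 5-point
# Gauss-Legendre on each subinterval; returns values at the nodes
.cumgauss <- function(f, r) {
  gl <- pracma::gaussLegendre(5, 0, 1)
  dr <- diff(r)
  inc <- numeric(length(dr))
  for (k in seq_along(gl$x)) {
    s <- r[-length(r)] + gl$x[k] * dr
    inc <- inc + gl$w[k] * f(s)
  }
  c(0, cumsum(inc * dr))
}

.tube_profile_df <- function(r, srr, stt, szz, model, p, a, b, material = "") {
  out <- data.frame(
    r_mm = r,
    r_norm = (r - a) / (b - a),
    sigma_rr = srr, sigma_tt = stt, sigma_zz = szz,
    sigma_eff = effective_stress(srr, stt, szz))
  structure(out, class = c("tube_profile", "data.frame"),
            p = p, a = a, b = b, model = model, material = material)
}

#' Inflate an incompressible hyperelastic thick-wall tube
#'
#' Solves the plane-strain inflation of a longitudinally constrained tube
#' with incompressible hyperelastic wall. The deformed outer radius `b` is
#' found by bracketed root-finding on the outer traction-free condition,
#' with the inner radius tied to `b` by cross-sectional area preservation
#' (`b^2 - a^2 = B^2 - A^2`); the radial stress is then obtained by
#' integrating the equilibrium ODE from `sigma_rr(a) = -p`, and the axial
#' stress follows from the hydrostatic pressure
#' (`sigma_zz = sigma_rr + 2 W' (1 - lam_r^2)`).
#'
#' @param geom a [tube_geometry()] (unloaded radii).
#' @param mat a [hyperelastic_material()].
#' @param p internal pressure (N/mm^2), `>= 0`.
#' @param n_nodes number of evenly spaced radial sample nodes (default 201).
#' @return a list with elements `deformed` (list `a`, `b`, `p`) and
#'   `profile` (a `tube_profile` data frame with columns `r_mm`, `r_norm`,
#'   `sigma_rr`, `sigma_tt`, `sigma_zz`, `sigma_eff`).
#' @examples
#' sol <- solve_nonlinear_tube(tube_geometry(14.8, 16.1),
#'                             builtin_materials("RV"), 0.016)
#' sol$deformed$a  # ~16.3 mm
#' @export
solve_nonlinear_tube <- function(geom, mat, p, n_nodes = 201) {
  stopifnot(inherits(geom, "tube_geometry"),
            inherits(mat, "hyperelastic_material"))
  if (!is.finite(p) || p < 0) stop("p must be finite and non-negative")
  A <- geom$A; B <- geom$B
  if (p == 0) {
    r <- seq(A, B, length.out = n_nodes)
    z <- numeric(n_nodes)
    return(list(deformed = list(a = A, b = B, p = 0),
                profile = .tube_profile_df(r, z, z, z, "nonlinear", 0, A, B,
                                           mat$label)))
  }
  # bracket for b: traction residual is -p at b = B and grows with b
  hi <- B * (1 + p * B / (mat$alpha * (B - A)) + 0.05)
  f_lo <- .tube_outer_traction(B, A, B, mat, p)
  f_hi <- .tube_outer_traction(hi, A, B, mat, p)
  tries <- 0
  while (f_hi < 0 && tries < 60) {
    hi <- hi * 1.25
    f_hi <- .tube_outer_traction(hi, A, B, mat, p)
    tries <- tries + 1
  }
  if (f_lo * f_hi > 0) {
    stop(sprintf(paste0("could not bracket the deformed outer radius: ",
                        "residual %.3e at b=%.4g and %.3e at b=%.4g ",
                        "(pressure may be outside the physical range)"),
                 f_lo, B, f_hi, hi))
  }
  b <- stats::uniroot(.tube_outer_traction, c(B, hi), A = A, B = B,
                      mat = mat, p = p, tol = 1e-12)$root
  a <- sqrt(b^2 - B^2 + A^2)
  r <- seq(a, b, length.out = n_nodes)
  srr <- -p + .cumgauss(function(s) .tube_dstress(s, a, A, mat) / s, r)
  dst <- .tube_dstress(r, a, A, mat)
  stt <- srr + dst
  R2 <- r^2 - a^2 + A^2
  lr2 <- R2 / r^2
  szz <- srr + 2 * strain_energy_deriv(mat, r^2 / R2 + lr2 + 1) * (1 - lr2)
  list(deformed = list(a = a, b = b, p = p),
       profile = .tube_profile_df(r, srr, stt, szz, "nonlinear", p, a, b,
                                  mat$label))
}

#' Lame solution for a linear-elastic thick-wall tube
#'
#' Plane-strain small-displacement solution on the (unchanged) deformed
#' geometry: `sigma_rr = k1 - k2/r^2`, `sigma_tt = k1 + k2/r^2` with the
#' constants fixed by `sigma_rr(a) = -p`, `sigma_rr(b) = 0`, and
#' `sigma_zz = nu (sigma_rr + sigma_tt)` from the zero axial strain
#' constraint. The stresses are independent of the Young's modulus.
#'
#' @param geom_deformed a [tube_geometry()] interpreted as the imaged
#'   (deformed) geometry, which the linear model leaves unchanged.
#' @param p internal pressure (N/mm^2), `>= 0`.
#' @param nu Poisson ratio used for the axial stress (default 0.4999).
#' @param n_nodes number of radial sample nodes.
#' @return a `tube_profile` data frame (see [solve_nonlinear_tube()]).
#' @export
solve_linear_tube <- function(geom_deformed, p, nu = 0.4999, n_nodes = 201) {
  stopifnot(inherits(geom_deformed, "tube_geometry"))
  if (!is.finite(p) || p < 0) stop("p must be finite and non-negative")
  a <- geom_deformed$A; b <- geom_deformed$B
  r <- seq(a, b, length.out = n_nodes)
  k1 <- p * a^2 / (b^2 - a^2)
  k2 <- k1 * b^2
  srr <- k1 - k2 / r^2
  stt <- k1 + k2 / r^2
  szz <- nu * (srr + stt)
  .tube_profile_df(r, srr, stt, szz, "linear", p, a, b, "linear")
}

#' Radial displacement field of the linear tube model
#'
#' Plane-strain Lame displacement `u_r(r) = (1+nu)/E [(1-2nu) k1 r + k2/r]`
#' with the traction constants of [solve_linear_tube()]; scales as `1/E`.
#'
#' @param geom a [tube_geometry()] (deformed = initial geometry).
#' @param mat a [linear_material()].
#' @param p internal pressure (N/mm^2).
#' @param n_nodes number of radial sample nodes.
#' @return data frame with columns `r_mm` and `u_r` (mm).
#' @examples
#' u <- linear_tube_displacement(tube_geometry(14.8, 16.1),
#'                               linear_material(8.4e9), 0.016)
#' max(abs(u$u_r))  # negligible at high E
#' @export
linear_tube_displacement <- function(geom, mat, p, n_nodes = 201) {
  stopifnot(inherits(geom, "tube_geometry"), inherits(mat, "linear_material"))
  a <- geom$A; b <- geom$B
  r <- seq(a, b, length.out = n_nodes)
  k1 <- p * a^2 / (b^2 - a^2)
  k2 <- k1 * b^2
  u <- (1 + mat$nu) / mat$E * ((1 - 2 * mat$nu) * k1 * r + k2 / r)
  data.frame(r_mm = r, u_r = u)
}

#' Effective (von Mises) stress in cylindrical components
#'
#' `sigma_eff^2 = ((s_rr-s_tt)^2 + (s_tt-s_zz)^2 + (s_zz-s_rr)^2)/2
#' + 3 (t_rt^2 + t_tz^2 + t_zr^2)`. Vectorized; shear components default
#' to zero for axisymmetric tube states.
#'
#' @param sigma_rr,sigma_tt,sigma_zz normal stress components (N/mm^2).
#' @param tau_rt,tau_tz,tau_zr shear components (N/mm^2), default 0.
#' @return effective stress (N/mm^2).
#' @export
effective_stress <- function(sigma_rr, sigma_tt, sigma_zz,
                             tau_rt = 0, tau_tz = 0, tau_zr = 0) {
  stopifnot(all(is.finite(sigma_rr)), all(is.finite(sigma_tt)),
            all(is.finite(sigma_zz)))
  sqrt(0.5 * ((sigma_rr - sigma_tt)^2 + (sigma_tt - sigma_zz)^2 +
              (sigma_zz - sigma_rr)^2) +
       3 * (tau_rt^2 + tau_tz^2 + tau_zr^2))
}

#' Global force-balance (equilibrium) integral of a tube profile
#'
#' For a tube in equilibrium the circumferential stress integrated through
#' the wall balances the pressure on the lumen:
#' `integral of sigma_tt dr over [a, b] = p * a`. The function returns both
#' sides; their relative gap is a solver-quality diagnostic.
#'
#' @param profile a `tube_profile` from one of the tube solvers.
#' @return list with `integral` (N/mm), `p_times_a` (N/mm) and
#'   `relative_gap`.
#' @export
equilibrium_integral <- function(profile) {
  stopifnot(inherits(profile, "tube_profile"))
  if (nrow(profile) < 2) stop("profile must contain at least 2 radial nodes")
  intg <- pracma::trapz(profile$r_mm, profile$sigma_tt)
  pa <- attr(profile, "p") * attr(profile, "a")
  list(integral = intg, p_times_a = pa,
       relative_gap = if (pa != 0) abs(intg - pa) / abs(pa) else abs(intg))
}

#' @export
print.tube_profile <- function(x, ...) {
  cat(sprintf(
    "Tube stress profile (%s model%s): a=%.4g mm, b=%.4g mm, p=%.4g N/mm^2, %d nodes\n",
    attr(x, "model"),
    if (nzchar(attr(x, "material"))) paste0(", ", attr(x, "material")) else "",
    attr(x, "a"), attr(x, "b"), attr(x, "p"), nrow(x)))
  cat(sprintf("  sigma_tt: %.4g .. %.4g N/mm^2; max sigma_eff %.4g N/mm^2\n",
              min(x$sigma_tt), max(x$sigma_tt), max(x$sigma_eff)))
  invisible(x)
}

#' Export a tube stress profile as CSV
#'
#' Writes columns `r_mm, r_norm, sigma_rr, sigma_tt, sigma_zz, sigma_eff`.
#'
#' @param profile a `tube_profile`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_profile_csv <- function(profile, file) {
  stopifnot(inherits(profile, "tube_profile"))
  utils::write.csv(as.data.frame(profile), file, row.names = FALSE)
  invisible(file)
}
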