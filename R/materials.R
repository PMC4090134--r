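# Constitutive models for the aneurysm wall and intraluminal thrombus.
#
# Wall tissue: isotropic, incompressible hyperelastic with a polynomial
# strain-energy density in the first invariant of the left Cauchy-Green
# tensor B (I_B = tr B):
#
#   W(I_B) = alpha (I_B - 3) + beta (I_B - 3)^2 + gamma (I_B - 3)^3
#          + zeta (I_B - 3)^4 + eta (I_B - 3)^5
#
# The two-term (Raghavan-Vorp) and three-term (Polzer et al. samples) fits
# used throughout the AAA literature are special cases with the higher
# coefficients zero. Thrombus: incompressible with energy in the second
# invariant II_B, W_ILT = D1 (II_B - 3) + D2 (II_B - 3)^2.

#' Hyperelastic wall material
#'
#' Builds an isotropic incompressible hyperelastic material with polynomial
#' strain-energy density `W(I_B) = alpha(I_B-3) + beta(I_B-3)^2 +
#' gamma(I_B-3)^3 + zeta(I_B-3)^4 + eta(I_B-3)^5`. Coefficients are in
#' N/mm^2. The undeformed state (`I_B = 3`) stores no energy.
#'
#' @param alpha,beta,gamma,zeta,eta polynomial coefficients (N/mm^2);
#'   `alpha` must be non-negative, all must be finite.
#' @param label optional short name used in printouts and profile metadata.
#' @return an object of class `hyperelastic_material`.
#' @examples
#' rv <- hyperelastic_material(0.174, 1.881, label = "RV")
#' strain_energy(rv, 4)  # alpha + beta = 2.055 N/mm^2
#' @export
hyperelastic_material <- function(alpha, beta = 0, gamma = 0, zeta = 0,
                                  eta = 0, label = "") {
  co <- c(alpha = alpha, beta = beta, gamma = gamma, zeta = zeta, eta = eta)
  if (!all(is.finite(co))) stop("material coefficients must be finite")
  if (alpha < 0) stop("alpha must be non-negative")
  structure(c(as.list(co), list(label = label)),
            class = "hyperelastic_material")
}

#' Linear elastic wall material
#'
#' @param E Young's modulus (N/mm^2), positive. In the linear-equilibrium
#'   model the computed stresses are independent of `E`; a large value (the
#'   default elsewhere is 8.4e9 N/mm^2) keeps displacements negligible.
#' @param nu Poisson ratio in `[0, 0.5)`; near-incompressible default 0.4999.
#' @return an object of class `linear_material`.
#' @export
linear_material <- function(E, nu = 0.4999) {
  stopifnot(is.finite(E), is.finite(nu))
  if (E <= 0) stop("E must be positive")
  if (nu < 0 || nu >= 0.5) stop("nu must lie in [0, 0.5)")
  structure(list(E = E, nu = nu), class = "linear_material")
}

#' Intraluminal thrombus material
#'
#' Incompressible isotropic thrombus model with energy density
#' `W = D1 (II_B - 3) + D2 (II_B - 3)^2`, where `II_B` is the second
#' invariant of the left Cauchy-Green tensor.
#'
#' @param D1,D2 coefficients (N/mm^2); `D1 > 0`, `D2 >= 0`.
#' @param label optional short name.
#' @return an object of class `thrombus_material`.
#' @export
thrombus_material <- function(D1, D2 = 0, label = "") {
  stopifnot(is.finite(D1), is.finite(D2))
  if (D1 <= 0) stop("D1 must be positive")
  if (D2 < 0) stop("D2 must be non-negative")
  structure(list(D1 = D1, D2 = D2, label = label),
            class = "thrombus_material")
}

#' @export
print.hyperelastic_material <- function(x, ...) {
  cat(sprintf(
    "Hyperelastic wall material%s: alpha=%g beta=%g gamma=%g zeta=%g eta=%g N/mm^2\n",
    if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
    x$alpha, x$beta, x$gamma, x$zeta, x$eta))
  invisible(x)
}

#' @export
print.linear_material <- function(x, ...) {
  cat(sprintf("Linear material: E=%g N/mm^2, nu=%g\n", x$E, x$nu))
  invisible(x)
}

#' @export
print.thrombus_material <- function(x, ...) {
  cat(sprintf("Thrombus material%s: D1=%g D2=%g N/mm^2\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              x$D1, x$D2))
  invisible(x)
}

#' Built-in material catalog
#'
#' Returns the material coefficient sets used throughout the package:
#' the Raghavan-Vorp population-average wall (`RV`), two patient-sample
#' wall fits (`P1`, `P2`), weak/stiff wall variants used in the
#' wall-to-thrombus stiffness-ratio experiments (`wall-weak`,
#' `wall-stiff`), the population-average thrombus (`ILT`, D1 = 0.026
#' N/mm^2) with its stiff and weak variants, and the default high-modulus
#' linear wall (`linear-wall`).
#'
#' @param name optional single material name; when supplied the named
#'   material is returned instead of the full catalog. Unknown names are an
#'   error.
#' @return a named list of material objects, or a single material.
#' @examples
#' builtin_materials("RV")
#' names(builtin_materials())
#' @export
builtin_materials <- function(name = NULL) {
  cat_ <- list(
    "RV"          = hyperelastic_material(0.174, 1.881, label = "RV"),
    "P1"          = hyperelastic_material(0.0145, 0, 2.259, label = "P1"),
    "P2"          = hyperelastic_material(0.022, 1.461, 1.0, label = "P2"),
    "wall-weak"   = hyperelastic_material(0.144, 1.152, label = "wall-weak"),
    "wall-stiff"  = hyperelastic_material(0.204, 2.61, label = "wall-stiff"),
    "ILT"         = thrombus_material(0.026, 0.0286, label = "ILT"),
    "ILT-stiff"   = thrombus_material(0.036, 0.0356, label = "ILT-stiff"),
    "ILT-weak"    = thrombus_material(0.0199, 0.0216, label = "ILT-weak"),
    "linear-wall" = linear_material(8.4e9, 0.4999)
  )
  if (is.null(name)) return(cat_)
  if (!name %in% names(cat_)) {
    stop(sprintf("unknown material '%s'; available: %s", name,
                 paste(names(cat_), collapse = ", ")))
  }
  cat_[[name]]
}

#' Strain-energy density
#'
#' Evaluates the stored energy per unit volume for a wall or thrombus
#' material at the given deformation invariant(s).
#'
#' @param mat a material object.
#' @param ... invariants passed to the method: `IB` (first invariant of B)
#'   for hyperelastic walls, `IIB` (second invariant) for thrombus.
#' @return energy density in N/mm^2 (vectorized over the invariant).
#' @export
strain_energy <- function(mat, ...) UseMethod("strain_energy")

#' @rdname strain_energy
#' @param IB first invariant of the left Cauchy-Green tensor; must be
#'   `>= 3 - 1e-9` (the physical range for incompressible states).
#' @export
strain_energy.hyperelastic_material <- function(mat, IB, ...) {
  if (!all(is.finite(IB))) stop("IB must be finite")
  if (any(IB < 3 - 1e-9)) stop("IB below the physical range (IB >= 3)")
  x <- IB - 3
  mat$alpha * x + mat$beta * x^2 + mat$gamma * x^3 +
    mat$zeta * x^4 + mat$eta * x^5
}

#' @rdname strain_energy
#' @param IIB second invariant of the left Cauchy-Green tensor (thrombus).
#' @export
strain_energy.thrombus_material <- function(mat, IIB, ...) {
  if (!all(is.finite(IIB))) stop("IIB must be finite")
  if (any(IIB < 3 - 1e-9)) stop("IIB below the physical range (IIB >= 3)")
  x <- IIB - 3
  mat$D1 * x + mat$D2 * x^2
}

#' Derivative of the strain-energy density
#'
#' Analytic derivative of [strain_energy()] with respect to its invariant
#' argument (dW/dI_B for walls, dW/dII_B for thrombus).
#'
#' @inheritParams strain_energy
#' @return derivative in N/mm^2 (vectorized).
#' @export
strain_energy_deriv <- function(mat, ...) UseMethod("strain_energy_deriv")

#' @rdname strain_energy_deriv
#' @param IB first invariant, `>= 3 - 1e-9`.
#' @export
strain_energy_deriv.hyperelastic_material <- function(mat, IB, ...) {
  if (!all(is.finite(IB))) stop("IB must be finite")
  if (any(IB < 3 - 1e-9)) stop("IB below the physical range (IB >= 3)")
  x <- IB - 3
  mat$alpha + 2 * mat$beta * x + 3 * mat$gamma * x^2 +
    4 * mat$zeta * x^3 + 5 * mat$eta * x^4
}

#' @rdname strain_energy_deriv
#' @param IIB second invariant (thrombus).
#' @export
strain_energy_deriv.thrombus_material <- function(mat, IIB, ...) {
  if (!all(is.finite(IIB))) stop("IIB must be finite")
  x <- IIB - 3
  mat$D1 + 2 * mat$D2 * x
}

#' Principal stretch state
#'
#' Records the three principal stretches of an incompressible deformation
#' together with the hydrostatic pressure `H` supplied by a boundary-value
#' solver. The incompressibility constraint
#' `lam_r * lam_theta * lam_z = 1` is enforced at construction.
#'
#' @param lam_r,lam_theta,lam_z principal stretches (radial,
#'   circumferential, longitudinal); all positive.
#' @param H hydrostatic pressure (N/mm^2) or `NULL` when not yet known.
#' @param tol tolerance on the incompressibility product.
#' @return an object of class `stretch_state`.
#' @export
stretch_state <- function(lam_r, lam_theta, lam_z = 1, H = NULL,
                          tol = 1e-8) {
  stopifnot(lam_r > 0, lam_theta > 0, lam_z > 0)
  if (abs(lam_r * lam_theta * lam_z - 1) > tol) {
    stop("stretches violate incompressibility (lam_r*lam_theta*lam_z != 1)")
  }
  structure(list(lam_r = lam_r, lam_theta = lam_theta, lam_z = lam_z, H = H),
            class = "stretch_state")
}

#' Principal Cauchy stresses of an incompressible hyperelastic state
#'
#' For an incompressible material with energy `W(I_B)` the principal Cauchy
#' stresses are `sigma_ii = -H + 2 (dW/dI_B) lam_ii^2`. The hydrostatic
#' pressure `H` is not determined by the constitutive law and must be
#' supplied (by the boundary-value solver) in the stretch state.
#'
#' @param mat a `hyperelastic_material`.
#' @param state a [stretch_state()] with `H` set.
#' @return named numeric vector `c(sigma_rr, sigma_tt, sigma_zz)` (N/mm^2).
#' @examples
#' rv <- builtin_materials("RV")
#' s <- stretch_state(1 / 1.2, 1.2, 1, H = 0)
#' cauchy_stress(rv, s)
#' @export
cauchy_stress <- function(mat, state) {
  stopifnot(inherits(mat, "hyperelastic_material"),
            inherits(state, "stretch_state"))
  if (is.null(state$H)) {
    stop("hydrostatic pressure H must be supplied by the boundary-value solver")
  }
  IB <- state$lam_r^2 + state$lam_theta^2 + state$lam_z^2
  dW <- strain_energy_deriv(mat, IB)
  c(sigma_rr = -state$H + 2 * dW * state$lam_r^2,
    sigma_tt = -state$H + 2 * dW * state$lam_theta^2,
    sigma_zz = -state$H + 2 * dW * state$lam_z^2)
}

#' Write a material catalog to a plain-text key-value file
#'
#' One block per material: a `[name]` header followed by `key = value`
#' lines (`alpha..eta`, or `E, nu`, or `D1, D2`). The format round-trips
#' through [read_materials()].
#'
#' @param mats named list of material objects.
#' @param file path to write.
#' @return `file`, invisibly.
#' @export
write_materials <- function(mats, file) {
  stopifnot(is.list(mats), !is.null(names(mats)))
  lines <- character(0)
  for (nm in names(mats)) {
    m <- mats[[nm]]
    lines <- c(lines, sprintf("[%s]", nm))
    if (inherits(m, "hyperelastic_material")) {
      lines <- c(lines, "type = hyperelastic",
                 sprintf("%s = %.17g", c("alpha", "beta", "gamma", "zeta", "eta"),
                         unlist(m[c("alpha", "beta", "gamma", "zeta", "eta")])))
    } else if (inherits(m, "linear_material")) {
      lines <- c(lines, "type = linear",
                 sprintf("E = %.17g", m$E), sprintf("nu = %.17g", m$nu))
    } else if (inherits(m, "thrombus_material")) {
      lines <- c(lines, "type = thrombus",
                 sprintf("D1 = %.17g", m$D1), sprintf("D2 = %.17g", m$D2))
    } else stop("unknown material class")
    lines <- c(lines, "")
  }
  writeLines(lines, file)
  invisible(file)
}

#' Read a material catalog written by [write_materials()]
#'
#' @param file path to a key-value material file.
#' @return named list of material objects.
#' @export
read_materials <- function(file) {
  lines <- trimws(readLines(file))
  lines <- lines[nzchar(lines)]
  heads <- grep("^\\[.*\\]$", lines)
  if (!length(heads)) stop("no material blocks found in ", file)
  out <- list()
  bounds <- c(heads, length(lines) + 1L)
  for (i in seq_along(heads)) {
    nm <- sub("^\\[(.*)\\]$", "\\1", lines[heads[i]])
    block <- lines[(heads[i] + 1L):(bounds[i + 1L] - 1L)]
    kv <- strsplit(block, "\\s*=\\s*")
    keys <- vapply(kv, `[`, "", 1L)
    vals <- vapply(kv, `[`, "", 2L)
    typ <- vals[keys == "type"]
    num <- function(k) as.numeric(vals[keys == k][1L])
    out[[nm]] <- switch(typ,
      hyperelastic = hyperelastic_material(num("alpha"), num("beta"),
                                           num("gamma"), num("zeta"),
                                           num("eta"), label = nm),
      linear = linear_material(num("E"), num("nu")),
      thrombus = thrombus_material(num("D1"), num("D2"), label = nm),
      stop("unknown material type '", typ, "'"))
  }
  out
}
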