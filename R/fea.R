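# Compact continuum finite-element core: axisymmetric / plane-strain
# 9-node Lagrange quadrilaterals with the mixed displacement/pressure
# ("9/3") treatment -- continuous biquadratic displacements, a
# discontinuous linear pressure field (1, xi, eta) per element, condensed
# at the element level. Handles the linear small-displacement model and
# incremental-load full-Newton solves for incompressible hyperelastic
# wall/thrombus domains with follower pressure on the lumen.
#
# Kinematic conventions: coordinates (x, y) are (r, z) in axisymmetric
# runs. The deformation gradient is carried as an in-plane 2x2 block plus
# the out-of-plane stretch (hoop stretch x_r/X_R in axisymmetric runs, 1 in
# plane strain). Internal forces are integrated over the reference volume
# with the Kirchhoff stress and spatial gradients; the consistent tangent
# uses a numerically differentiated material block (d tau / d F by central
# differences) plus the exact geometric and pressure-coupling terms, so the
# same machinery serves first- and second-invariant energy densities.

# 1D quadratic Lagrange basis at nodes {-1, 0, 1}
.lag1 <- function(x) cbind(x * (x - 1) / 2, 1 - x^2, x * (x + 1) / 2)
.dlag1 <- function(x) cbind(x - 0.5, -2 * x, x + 0.5)

.Q9_XI <- cbind(c(-1, 1, 1, -1, 0, 1, 0, -1, 0),
                c(-1, -1, 1, 1, -1, 0, 1, 0, 0))

.q9_shape <- function(xi, eta) {
  lx <- .lag1(xi); ly <- .lag1(eta)
  dlx <- .dlag1(xi); dly <- .dlag1(eta)
  ix <- c(1, 3, 3, 1, 2, 3, 2, 1, 2)   # 1D index along xi per local node
  iy <- c(1, 1, 3, 3, 1, 2, 3, 2, 2)
  N <- lx[ix] * ly[iy]
  dN <- cbind(dlx[ix] * ly[iy], lx[ix] * dly[iy])
  list(N = N, dN = dN)
}

# 3x3 Gauss rule with shape values; cached in the package namespace
.gauss9 <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    g1 <- c(-sqrt(3 / 5), 0, sqrt(3 / 5))
    w1 <- c(5, 8, 5) / 9
    pts <- expand.grid(xi = g1, eta = g1)
    w <- as.numeric(outer(w1, w1))       # xi fastest, matching expand.grid
    N <- vector("list", 9); dN <- vector("list", 9)
    for (g in 1:9) {
      s <- .q9_shape(pts$xi[g], pts$eta[g])
      N[[g]] <- s$N; dN[[g]] <- s$dN
    }
    Nmat <- do.call(rbind, N)            # 9 gp x 9 nodes
    cache <<- list(xi = as.matrix(pts), w = w, N = N, dN = dN,
                   Nmat = Nmat, extrap = solve(Nmat))
    cache
  }
})

# 3-point Gauss rule on a quadratic edge
.gauss_edge <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    s <- c(-sqrt(3 / 5), 0, sqrt(3 / 5))
    cache <<- list(N = .lag1(s), dN = .dlag1(s), w = c(5, 8, 5) / 9)
    cache
  }
})

#' Finite-element solver settings
#'
#' @param energy_tolerance convergence ratio for out-of-balance energy in
#'   the Newton iterations (default 0.001).
#' @param max_iterations maximum Newton iterations per load step (default 15).
#' @param n_load_steps number of incremental load steps (default 15).
#' @param formulation `"axisymmetric"` or `"plane_strain"`.
#' @param pressure_config apply the lumen pressure on the `"deformed"`
#'   (follower load, default) or `"undeformed"` configuration in
#'   hyperelastic solves.
#' @param kappa_factor ratio of the volumetric penalty modulus to the
#'   small-strain shear modulus in hyperelastic solves (near-
#'   incompressibility; default 1e4).
#' @return an object of class `solve_settings`.
#' @export
solve_settings <- function(energy_tolerance = 0.001, max_iterations = 15,
                           n_load_steps = 15,
                           formulation = c("axisymmetric", "plane_strain"),
                           pressure_config = c("deformed", "undeformed"),
                           kappa_factor = 1e4) {
  stopifnot(energy_tolerance > 0, max_iterations >= 1, n_load_steps >= 1)
  structure(list(energy_tolerance = energy_tolerance,
                 max_iterations = as.integer(max_iterations),
                 n_load_steps = as.integer(n_load_steps),
                 formulation = match.arg(formulation),
                 pressure_config = match.arg(pressure_config),
                 kappa_factor = kappa_factor),
            class = "solve_settings")
}

# per-element reference-configuration quantities
.fe_precompute <- function(mesh, axisym) {
  gp <- .gauss9()
  ne <- nrow(mesh$elems)
  pre <- vector("list", ne)
  for (e in seq_len(ne)) {
    conn <- mesh$elems[e, ]
    Xe <- mesh$nodes[conn, , drop = FALSE]
    dNdX <- vector("list", 9); wdet <- numeric(9); Xr <- numeric(9)
    for (g in 1:9) {
      J <- crossprod(gp$dN[[g]], Xe)     # 2x2, J[k,l] = dX_l/dxi_k
      dJ <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
      if (dJ <= 0) stop(sprintf("inverted element %d (detJ=%.3e)", e, dJ))
      # dN/dX = dN/dxi %*% inv(t(J)) since t(J) = dX/dxi
      Jti <- matrix(c(J[2, 2], -J[1, 2], -J[2, 1], J[1, 1]), 2) / dJ
      dNdX[[g]] <- gp$dN[[g]] %*% Jti    # 9x2
      Xr[g] <- sum(gp$N[[g]] * Xe[, 1])
      wdet[g] <- gp$w[g] * dJ * if (axisym) Xr[g] else 1
    }
    pre[[e]] <- list(conn = conn, Xe = Xe, dNdX = dNdX, wdet = wdet, Xr = Xr)
  }
  pre
}

# follower-load stiffness: d f_ext / d x on the current lumen edges
# (unsymmetric 6x6 blocks per edge), returned as sparse triplets
.pressure_load_K <- function(mesh, nodes, p, axisym) {
  ge <- .gauss_edge()
  ed <- mesh$sets$lumen_edges
  ti <- tj <- tv <- list()
  for (k in seq_len(nrow(ed))) {
    en <- ed[k, ]
    xe <- nodes[en, , drop = FALSE]
    Ke <- matrix(0, 6, 6)                # dofs (x1,y1,x2,y2,x3,y3)
    ix <- seq(1, 6, by = 2); iy <- ix + 1L
    for (g in 1:3) {
      N <- ge$N[g, ]; dN <- ge$dN[g, ]; w <- ge$w[g]
      t_ <- as.numeric(dN %*% xe)
      xr <- if (axisym) sum(N * xe[, 1]) else 1
      # f_x = p w N_i (-t_y) xr ; f_y = p w N_i t_x xr
      Ke[ix, iy] <- Ke[ix, iy] + (p * w * xr) * outer(N, -dN)
      Ke[iy, ix] <- Ke[iy, ix] + (p * w * xr) * outer(N, dN)
      if (axisym) {
        Ke[ix, ix] <- Ke[ix, ix] + (p * w * (-t_[2])) * outer(N, N)
        Ke[iy, ix] <- Ke[iy, ix] + (p * w * t_[1]) * outer(N, N)
      }
    }
    dofs <- as.integer(rbind(2L * en - 1L, 2L * en))
    ti[[k]] <- rep(dofs, times = 6)
    tj[[k]] <- rep(dofs, each = 6)
    tv[[k]] <- as.numeric(Ke)
  }
  list(i = unlist(ti), j = unlist(tj), v = unlist(tv))
}

# lumen pressure nodal forces; nodes = configuration to integrate on
.pressure_force <- function(mesh, nodes, p, axisym) {
  ge <- .gauss_edge()
  f <- numeric(2L * nrow(nodes))
  ed <- mesh$sets$lumen_edges
  for (k in seq_len(nrow(ed))) {
    en <- ed[k, ]
    xe <- nodes[en, , drop = FALSE]      # 3x2
    for (g in 1:3) {
      t_ <- as.numeric(ge$dN[g, ] %*% xe)
      nL <- c(-t_[2], t_[1])             # left normal (into the solid)
      xr <- if (axisym) sum(ge$N[g, ] * xe[, 1]) else 1
      fg <- p * ge$w[g] * xr * nL
      ix <- 2L * en - 1L
      f[ix] <- f[ix] + ge$N[g, ] * fg[1]
      f[ix + 1L] <- f[ix + 1L] + ge$N[g, ] * fg[2]
    }
  }
  f
}

.fixed_dofs <- function(mesh) {
  sort(unique(c(2L * mesh$sets$fix_z, 2L * mesh$sets$fix_x - 1L)))
}

# smallest in-plane Jacobian determinant of the deformation over all Gauss
# points; used to guard Newton updates against element inversion
.min_defJ <- function(mesh, pre, u) {
  worst <- Inf
  for (e in seq_along(pre)) {
    pe <- pre[[e]]
    ue <- matrix(u[as.integer(rbind(2L * pe$conn - 1L, 2L * pe$conn))], 2)
    xe <- pe$Xe + t(ue)
    for (g in 1:9) {
      F2 <- crossprod(xe, pe$dNdX[[g]])
      J2 <- F2[1, 1] * F2[2, 2] - F2[1, 2] * F2[2, 1]
      if (J2 < worst) worst <- J2
    }
  }
  worst
}

# shear modulus entering the volumetric penalty
.shear_modulus <- function(mat) {
  if (inherits(mat, "hyperelastic_material")) 2 * mat$alpha
  else if (inherits(mat, "thrombus_material")) 2 * mat$D1
  else mat$E / (2 * (1 + mat$nu))
}

# Kirchhoff stress (t11, t22, t12, toop) for in-plane F2 (2x2), out-of-plane
# stretch Foop and element pressure ptil
.kirchhoff <- function(F2, Foop, ptil, mat) {
  J2 <- F2[1] * F2[4] - F2[2] * F2[3]
  J <- J2 * Foop
  b11 <- F2[1]^2 + F2[3]^2
  b22 <- F2[2]^2 + F2[4]^2
  b12 <- F2[1] * F2[2] + F2[3] * F2[4]
  s <- J^(-2 / 3)
  bb11 <- s * b11; bb22 <- s * b22; bb12 <- s * b12; bboo <- s * Foop^2
  I1 <- bb11 + bb22 + bboo
  if (inherits(mat, "hyperelastic_material")) {
    w1 <- strain_energy_deriv(mat, max(I1, 3))
    t11 <- 2 * w1 * (bb11 - I1 / 3)
    t22 <- 2 * w1 * (bb22 - I1 / 3)
    t12 <- 2 * w1 * bb12
    too <- 2 * w1 * (bboo - I1 / 3)
  } else {                               # thrombus: energy in II_B
    c11 <- bb11^2 + bb12^2; c22 <- bb22^2 + bb12^2
    c12 <- bb12 * (bb11 + bb22); coo <- bboo^2
    I2 <- 0.5 * (I1^2 - (c11 + c22 + coo))
    w2 <- strain_energy_deriv(mat, max(I2, 3))
    a11 <- I1 * bb11 - c11; a22 <- I1 * bb22 - c22
    a12 <- I1 * bb12 - c12; aoo <- I1 * bboo - coo
    tra <- (a11 + a22 + aoo) / 3
    t11 <- 2 * w2 * (a11 - tra); t22 <- 2 * w2 * (a22 - tra)
    t12 <- 2 * w2 * a12;         too <- 2 * w2 * (aoo - tra)
  }
  c(t11 + J * ptil, t22 + J * ptil, t12, too + J * ptil)
}

# d tau / d(F11, F12, F21, F22, Foop) by central differences (4x5)
.dtau_dF <- function(F2, Foop, ptil, mat) {
  A <- matrix(0, 4, 5)
  hs <- 1e-7 * max(1, abs(F2), abs(Foop))
  for (k in 1:4) {
    Fp <- F2; Fm <- F2
    Fp[k] <- Fp[k] + hs; Fm[k] <- Fm[k] - hs
    A[, k] <- (.kirchhoff(Fp, Foop, ptil, mat) -
               .kirchhoff(Fm, Foop, ptil, mat)) / (2 * hs)
  }
  A[, 5] <- (.kirchhoff(F2, Foop + hs, ptil, mat) -
             .kirchhoff(F2, Foop - hs, ptil, mat)) / (2 * hs)
  # stored F2 is column-major (F11, F21, F12, F22): reorder columns to
  # (F11, F12, F21, F22)
  A[, c(1, 3, 2, 4, 5)]
}

# assemble hyperelastic residual and (optionally) tangent.
# u: 2n displacements; cc: ne x 3 element pressure coefficients.
.hyper_assemble <- function(mesh, pre, mats, kappas, u, cc, axisym,
                            want_K = TRUE) {
  gp <- .gauss9()
  ne <- length(pre)
  n <- nrow(mesh$nodes)
  fint <- numeric(2L * n)
  Rc_all <- matrix(0, ne, 3)
  Scond <- if (want_K) vector("list", ne) else NULL
  trip_i <- trip_j <- trip_v <- if (want_K) vector("list", ne) else NULL
  for (e in seq_len(ne)) {
    pe <- pre[[e]]
    mat <- mats[[mesh$region[e]]]
    kap <- kappas[[mesh$region[e]]]
    conn <- pe$conn
    dofs <- as.integer(rbind(2L * conn - 1L, 2L * conn))  # interleaved x,y
    ue <- matrix(u[dofs], 2)             # 2x9 (x; y per node)
    xe <- pe$Xe + t(ue)                  # current coords 9x2
    ce <- cc[e, ]
    Rd <- numeric(18); Rc <- numeric(3)
    if (want_K) {
      Kdd <- matrix(0, 18, 18); Kdc <- matrix(0, 18, 3)
      Kcd <- matrix(0, 3, 18); Kcc <- matrix(0, 3, 3)
    }
    for (g in 1:9) {
      dNdX <- pe$dNdX[[g]]
      F2 <- crossprod(xe, dNdX)          # 2x2 dx/dX
      J2 <- F2[1, 1] * F2[2, 2] - F2[1, 2] * F2[2, 1]
      if (J2 <= 0) stop(sprintf("negative Jacobian in element %d during solve", e))
      xr <- sum(gp$N[[g]] * xe[, 1])
      Foop <- if (axisym) xr / pe$Xr[g] else 1
      J <- J2 * Foop
      Fi <- matrix(c(F2[2, 2], -F2[2, 1], -F2[1, 2], F2[1, 1]), 2) / J2
      gsp <- dNdX %*% Fi                 # 9x2 spatial gradients
      hoop <- if (axisym) gp$N[[g]] / xr else numeric(9)
      P <- c(1, gp$xi[g, 1], gp$xi[g, 2])
      ptil <- sum(P * ce)
      tv <- .kirchhoff(F2, Foop, ptil, mat)
      w <- pe$wdet[g]
      g1 <- gsp[, 1]; g2 <- gsp[, 2]
      # B rows: (11, 22, oop, 12-engineering); columns interleaved (x,y)/node
      Bx <- matrix(0, 4, 18)
      ixx <- seq(1, 18, by = 2); iyy <- ixx + 1L
      Bx[1, ixx] <- g1
      Bx[2, iyy] <- g2
      Bx[3, ixx] <- hoop
      Bx[4, ixx] <- g2; Bx[4, iyy] <- g1
      Rd <- Rd + w * as.numeric(crossprod(Bx, tv[c(1, 2, 4, 3)]))
      Rc <- Rc + w * P * (J - 1 - ptil / kap)
      if (!want_K) next
      A <- .dtau_dF(F2, Foop, ptil, mat) # 4x5, tau rows (11,22,12,oop)
      Gf <- matrix(0, 5, 18)
      Gf[1, ixx] <- g1 * F2[1, 1] + g2 * F2[2, 1]
      Gf[2, ixx] <- g1 * F2[1, 2] + g2 * F2[2, 2]
      Gf[3, iyy] <- g1 * F2[1, 1] + g2 * F2[2, 1]
      Gf[4, iyy] <- g1 * F2[1, 2] + g2 * F2[2, 2]
      Gf[5, ixx] <- hoop * Foop
      AG <- A %*% Gf                     # 4x18, rows (11,22,12,oop)
      Kdd <- Kdd + w * crossprod(Bx, AG[c(1, 2, 4, 3), ])
      # geometric part: K[(n,i),(m,j)] -= w * g_j(n) * (tau %*% g(m))_i
      t2 <- matrix(c(tv[1], tv[3], tv[3], tv[2]), 2)
      q <- t2 %*% t(gsp)                 # 2x9
      for (i in 1:2) for (j in 1:2) {
        rows <- if (i == 1) ixx else iyy
        cols <- if (j == 1) ixx else iyy
        Kdd[rows, cols] <- Kdd[rows, cols] - w * outer(gsp[, j], q[i, ])
      }
      if (axisym) {
        Kdd[ixx, ixx] <- Kdd[ixx, ixx] - w * tv[4] * outer(hoop, hoop)
      }
      divr <- numeric(18)
      divr[ixx] <- g1 + hoop; divr[iyy] <- g2
      Kdc <- Kdc + (w * J) * outer(as.numeric(crossprod(Bx, c(1, 1, 1, 0))), P)
      Kcd <- Kcd + (w * J) * outer(P, divr)
      Kcc <- Kcc - (w / kap) * outer(P, P)
    }
    ix <- 2L * conn - 1L
    fint[dofs] <- fint[dofs] + Rd
    Rc_all[e, ] <- Rc
    if (want_K) {
      Si <- solve(Kcc)
      Ke <- Kdd - Kdc %*% Si %*% Kcd
      Re_corr <- Kdc %*% (Si %*% Rc)
      Scond[[e]] <- list(Si = Si, Kcd = Kcd, Rc = Rc,
                         corr = as.numeric(Re_corr), dofs = dofs)
      trip_i[[e]] <- rep(dofs, times = 18)
      trip_j[[e]] <- rep(dofs, each = 18)
      trip_v[[e]] <- as.numeric(Ke)
    }
  }
  out <- list(fint = fint, Rc = Rc_all)
  if (want_K) {
    out$K <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                                  x = unlist(trip_v),
                                  dims = c(2L * n, 2L * n))
    out$cond <- Scond
  }
  out
}

#' Nonlinear hyperelastic finite-element solve
#'
#' Incremental-load full-Newton solve of the incompressible hyperelastic
#' boundary-value problem on a 9/3 mixed mesh. Pressure follows the
#' deforming lumen surface by default; convergence of each load step is
#' judged by the out-of-balance energy ratio. A diverging step is retried
#' once with half increments before failing.
#'
#' @param mesh an `fe_mesh`.
#' @param mats a single wall material, or a named list mapping regions
#'   (`wall`, `thrombus`) to materials.
#' @param p internal pressure (N/mm^2).
#' @param settings a [solve_settings()].
#' @return an object of class `fe_solution`: displacements, deformed
#'   coordinates, nodal-averaged and raw Gauss-point Cauchy stresses,
#'   effective stress, element pressure coefficients and the Newton
#'   history.
#' @export
solve_hyperelastic_fe <- function(mesh, mats, p,
                                  settings = solve_settings()) {
  stopifnot(inherits(mesh, "fe_mesh"), inherits(settings, "solve_settings"))
  if (!is.list(mats) || inherits(mats, c("hyperelastic_material",
                                         "thrombus_material"))) {
    mats <- list(wall = mats)
  }
  regs <- unique(mesh$region)
  if (!all(regs %in% names(mats))) {
    stop("mats must name a material for every mesh region: ",
         paste(regs, collapse = ", "))
  }
  axisym <- settings$formulation == "axisymmetric"
  pre <- .fe_precompute(mesh, axisym)
  kappas <- lapply(mats, function(m) settings$kappa_factor * .shear_modulus(m))
  n <- nrow(mesh$nodes)
  fixed <- .fixed_dofs(mesh)
  free <- setdiff(seq_len(2L * n), fixed)
  u <- numeric(2L * n)
  cc <- matrix(0, nrow(mesh$elems), 3)
  follower <- settings$pressure_config == "deformed"
  history <- list()

  run_step <- function(p_target, u, cc) {
    for (iter in seq_len(settings$max_iterations)) {
      nodes_now <- mesh$nodes + matrix(u, ncol = 2, byrow = TRUE)
      fext <- .pressure_force(mesh, if (follower) nodes_now else mesh$nodes,
                              p_target, axisym)
      asm <- .hyper_assemble(mesh, pre, mats, kappas, u, cc, axisym)
      R <- asm$fint - fext
      for (e in seq_along(asm$cond)) {   # condensation correction
        cd <- asm$cond[[e]]
        R[cd$dofs] <- R[cd$dofs] - cd$corr
      }
      Rf <- R[free]
      K <- asm$K
      if (follower) {                    # exact follower-load stiffness
        lk <- .pressure_load_K(mesh, nodes_now, p_target, axisym)
        K <- K - Matrix::sparseMatrix(i = lk$i, j = lk$j, x = lk$v,
                                      dims = dim(K))
      }
      du <- numeric(2L * n)
      du[free] <- as.numeric(Matrix::solve(K[free, free], -Rf))
      # damped update: cap unphysically large increments (bending-soft
      # initial tangents of thin shells) and backtrack on near-inversion
      ext <- max(apply(mesh$nodes, 2, function(v) diff(range(v))))
      s <- min(1, 0.2 * ext / max(abs(du)))
      bt <- 0
      while (.min_defJ(mesh, pre, u + s * du) < 0.02 && bt < 30) {
        s <- s / 2; bt <- bt + 1
      }
      if (bt >= 30) stop("Newton update keeps inverting elements")
      en <- abs(sum(s * du[free] * Rf))
      if (iter == 1) en1 <- max(en, .Machine$double.eps)
      u <- u + s * du
      for (e in seq_along(asm$cond)) {   # recover pressure increment
        cd <- asm$cond[[e]]
        cc[e, ] <- cc[e, ] - as.numeric(cd$Si %*%
                     (cd$Rc + cd$Kcd %*% (s * du[cd$dofs])))
      }
      history[[length(history) + 1L]] <<- c(p = p_target, iter = iter,
                                            energy_ratio = en / en1,
                                            res_norm = sqrt(sum(Rf^2)))
      if (en / en1 <= settings$energy_tolerance || en < 1e-30) {
        return(list(u = u, cc = cc, ok = TRUE))
      }
    }
    list(u = u, cc = cc, ok = FALSE)
  }

  steps <- seq_len(settings$n_load_steps) / settings$n_load_steps * p
  k <- 1
  while (k <= length(steps)) {
    st <- run_step(steps[k], u, cc)
    if (!st$ok) {                        # halve this increment once
      p_prev <- if (k == 1) 0 else steps[k - 1]
      half <- (p_prev + steps[k]) / 2
      st1 <- run_step(half, u, cc)
      st2 <- if (st1$ok) run_step(steps[k], st1$u, st1$cc) else st1
      if (!st1$ok || !st2$ok) {
        hist_df <- do.call(rbind, history)
        stop("Newton iterations diverged at p = ", signif(steps[k], 4),
             " N/mm^2 even after step halving; residual history has ",
             nrow(hist_df), " entries")
      }
      st <- st2
    }
    u <- st$u; cc <- st$cc
    k <- k + 1
  }
  .fe_postprocess(mesh, pre, mats, u, cc, axisym, settings,
                  history = do.call(rbind, history), linear = FALSE)
}

# Cauchy stresses at Gauss points -> extrapolated, averaged nodal fields
.fe_postprocess <- function(mesh, pre, mats, u, cc, axisym, settings,
                            history = NULL, linear = FALSE, Dmu = NULL) {
  gp <- .gauss9()
  ne <- nrow(mesh$elems)
  n <- nrow(mesh$nodes)
  acc <- matrix(0, n, 4)
  cnt <- numeric(n)
  regs <- unique(mesh$region)
  acc_r <- lapply(regs, function(r) matrix(0, n, 4))
  cnt_r <- lapply(regs, function(r) numeric(n))
  names(acc_r) <- names(cnt_r) <- regs
  gauss <- vector("list", ne)
  for (e in seq_len(ne)) {
    pe <- pre[[e]]
    mat <- mats[[mesh$region[e]]]
    conn <- pe$conn
    dofs <- as.integer(rbind(2L * conn - 1L, 2L * conn))
    ue <- matrix(u[dofs], 2)
    sig_g <- matrix(0, 9, 4)             # (xx, yy, oop, xy)
    for (g in 1:9) {
      P <- c(1, gp$xi[g, 1], gp$xi[g, 2])
      ptil <- sum(P * cc[e, ])
      if (linear) {
        grad <- ue %*% pe$dNdX[[g]]           # 2x2 du/dX
        hoop <- if (axisym) sum(gp$N[[g]] * ue[1, ]) / pe$Xr[g] else 0
        eps <- c(grad[1, 1], grad[2, 2], hoop, grad[1, 2] + grad[2, 1])
        mu <- Dmu[[mesh$region[e]]]
        tre <- eps[1] + eps[2] + eps[3]
        sig_g[g, ] <- c(2 * mu * (eps[1] - tre / 3) + ptil,
                        2 * mu * (eps[2] - tre / 3) + ptil,
                        2 * mu * (eps[3] - tre / 3) + ptil,
                        mu * eps[4])
      } else {
        xe <- pe$Xe + t(ue)
        F2 <- crossprod(xe, pe$dNdX[[g]])
        J2 <- F2[1, 1] * F2[2, 2] - F2[1, 2] * F2[2, 1]
        Foop <- if (axisym) sum(gp$N[[g]] * xe[, 1]) / pe$Xr[g] else 1
        tv <- .kirchhoff(F2, Foop, ptil, mat)
        sig_g[g, ] <- tv[c(1, 2, 4, 3)] / (J2 * Foop)
      }
    }
    gauss[[e]] <- sig_g
    nod <- gp$extrap %*% sig_g           # 9 nodes x 4
    acc[conn, ] <- acc[conn, ] + nod
    cnt[conn] <- cnt[conn] + 1
    rg <- mesh$region[e]
    acc_r[[rg]][conn, ] <- acc_r[[rg]][conn, ] + nod
    cnt_r[[rg]][conn] <- cnt_r[[rg]][conn] + 1
  }
  stress <- acc / cnt
  colnames(stress) <- c("sigma_xx", "sigma_yy", "sigma_oop", "sigma_xy")
  stress_by_region <- lapply(regs, function(rg) {
    m <- acc_r[[rg]] / cnt_r[[rg]]       # NaN where the region is absent
    colnames(m) <- colnames(stress)
    m
  })
  names(stress_by_region) <- regs
  eff <- effective_stress(stress[, 1], stress[, 2], stress[, 3],
                          tau_rt = stress[, 4])
  structure(list(
    u = matrix(u, ncol = 2, byrow = TRUE),
    nodes_deformed = mesh$nodes + matrix(u, ncol = 2, byrow = TRUE),
    stress_nodal = stress, stress_by_region = stress_by_region,
    sigma_eff = eff,
    stress_gauss = gauss, pressure_coef = cc,
    history = history, settings = settings, mesh = mesh,
    averaged = TRUE), class = "fe_solution")
}

#' @export
print.fe_solution <- function(x, ...) {
  cat(sprintf(
    "FE solution: %d nodes, max |u| = %.4g mm, max effective stress = %.4g N/mm^2\n",
    nrow(x$u), max(abs(x$u)), max(x$sigma_eff)))
  invisible(x)
}

#' Linear small-displacement mixed finite-element solve
#'
#' Single linear solve with the 9/3 mixed displacement/pressure pair for
#' near-incompressible linear elasticity. The lumen pressure is applied on
#' the undeformed configuration and the geometry is not updated, so the
#' computed stresses are independent of the Young's modulus.
#'
#' @param mesh an `fe_mesh`.
#' @param mats a single [linear_material()] or a named list per region.
#' @param p internal pressure (N/mm^2).
#' @param settings a [solve_settings()] (only the formulation is used).
#' @return an `fe_solution`.
#' @export
solve_linear_fe <- function(mesh, mats, p, settings = solve_settings()) {
  stopifnot(inherits(mesh, "fe_mesh"))
  if (inherits(mats, c("linear_material", "hyperelastic_material",
                       "thrombus_material"))) {
    mats <- list(wall = mats)
  }
  regs <- unique(mesh$region)
  if (!all(regs %in% names(mats))) {
    stop("mats must name a material for every mesh region: ",
         paste(regs, collapse = ", "))
  }
  if (!all(vapply(mats, inherits, TRUE, "linear_material"))) {
    stop("the 9/3 mixed linear solver requires linear materials; ",
         "use solve_hyperelastic_fe for hyperelastic regions")
  }
  axisym <- settings$formulation == "axisymmetric"
  gp <- .gauss9()
  pre <- .fe_precompute(mesh, axisym)
  n <- nrow(mesh$nodes)
  ne <- nrow(mesh$elems)
  mus <- lapply(mats, function(m) m$E / (2 * (1 + m$nu)))
  kaps <- lapply(mats, function(m) m$E / (3 * (1 - 2 * m$nu)))
  trip_i <- trip_j <- trip_v <- vector("list", ne)
  cond <- vector("list", ne)
  for (e in seq_len(ne)) {
    pe <- pre[[e]]
    mu <- mus[[mesh$region[e]]]; kap <- kaps[[mesh$region[e]]]
    conn <- pe$conn
    dofs <- as.integer(rbind(2L * conn - 1L, 2L * conn))
    Kdd <- matrix(0, 18, 18); Q <- matrix(0, 18, 3); M <- matrix(0, 3, 3)
    for (g in 1:9) {
      g1 <- pe$dNdX[[g]][, 1]; g2 <- pe$dNdX[[g]][, 2]
      hoop <- if (axisym) gp$N[[g]] / pe$Xr[g] else numeric(9)
      Bx <- matrix(0, 4, 18)
      ixx <- seq(1, 18, by = 2); iyy <- ixx + 1L
      Bx[1, ixx] <- g1; Bx[2, iyy] <- g2; Bx[3, ixx] <- hoop
      Bx[4, ixx] <- g2; Bx[4, iyy] <- g1
      w <- pe$wdet[g]
      # deviatoric moduli in Voigt (11,22,oop,12eng)
      Pd <- diag(c(1, 1, 1, 0.5)) - outer(c(1, 1, 1, 0), c(1, 1, 1, 0)) / 3
      Kdd <- Kdd + (2 * mu * w) * crossprod(Bx, Pd %*% Bx)
      P <- c(1, gp$xi[g, 1], gp$xi[g, 2])
      Q <- Q + w * outer(as.numeric(crossprod(Bx, c(1, 1, 1, 0))), P)
      M <- M + (w / kap) * outer(P, P)
    }
    Mi <- solve(M)
    Ke <- Kdd + Q %*% Mi %*% t(Q)
    cond[[e]] <- list(Mi = Mi, Q = Q, dofs = dofs)
    trip_i[[e]] <- rep(dofs, times = 18)
    trip_j[[e]] <- rep(dofs, each = 18)
    trip_v[[e]] <- as.numeric(Ke)
  }
  K <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                            x = unlist(trip_v), dims = c(2L * n, 2L * n))
  f <- .pressure_force(mesh, mesh$nodes, p, axisym)
  fixed <- .fixed_dofs(mesh)
  free <- setdiff(seq_len(2L * n), fixed)
  u <- numeric(2L * n)
  sol <- tryCatch(Matrix::solve(K[free, free], f[free]),
                  error = function(e) {
                    stop("singular stiffness matrix: the mesh lacks ",
                         "constraints against rigid-body motion (",
                         conditionMessage(e), ")")
                  })
  u[free] <- as.numeric(sol)
  cc <- matrix(0, ne, 3)
  for (e in seq_len(ne)) {
    cd <- cond[[e]]
    cc[e, ] <- as.numeric(cd$Mi %*% crossprod(cd$Q, u[cd$dofs]))
  }
  .fe_postprocess(mesh, pre, mats, u, cc, axisym, settings,
                  linear = TRUE, Dmu = mus)
}

#' Run the reference / conventional / linear model pipeline
#'
#' Reference: hyperelastic solve from the supplied unloaded mesh. Its
#' deformed configuration is then treated as the (wrongly assumed)
#' unloaded, unstressed initial configuration for the conventional
#' hyperelastic solve and for the linear solve. All three stress fields
#' live on the same node set of the shared deformed-configuration wall, so
#' nodal comparisons are direct.
#'
#' @param mesh unloaded reference `fe_mesh`.
#' @param mats_reference material (or per-region list) for the reference
#'   solve.
#' @param p internal pressure (N/mm^2).
#' @param settings a [solve_settings()].
#' @param mats_conventional material (or list) for the conventional solve;
#'   defaults to the Raghavan-Vorp population average (with the mean
#'   thrombus when the mesh has a thrombus region).
#' @param E_linear,nu_linear linear-model wall elasticity.
#' @param mpr_linear wall-to-thrombus Young's modulus ratio for the linear
#'   model; defaults to alpha/D1 of the conventional materials.
#' @return list with `fe_solution`s `reference`, `conventional`, `linear`,
#'   and `mesh_deformed` (the shared initial mesh of the latter two).
#' @export
three_model_run <- function(mesh, mats_reference, p,
                            settings = solve_settings(),
                            mats_conventional = NULL,
                            E_linear = 8.4e9, nu_linear = 0.4999,
                            mpr_linear = NULL) {
  regs <- unique(mesh$region)
  if (is.null(mats_conventional)) {
    mats_conventional <- if ("thrombus" %in% regs) {
      list(wall = builtin_materials("RV"), thrombus = builtin_materials("ILT"))
    } else builtin_materials("RV")
  }
  ref <- solve_hyperelastic_fe(mesh, mats_reference, p, settings)
  mesh_def <- mesh
  mesh_def$nodes <- ref$nodes_deformed
  conv <- solve_hyperelastic_fe(mesh_def, mats_conventional, p, settings)
  lin_mats <- list(wall = linear_material(E_linear, nu_linear))
  if ("thrombus" %in% regs) {
    mc <- if (is.list(mats_conventional) &&
              !inherits(mats_conventional, "hyperelastic_material")) {
      mats_conventional
    } else list(wall = mats_conventional)
    if (is.null(mpr_linear)) {
      mpr_linear <- mc$wall$alpha / mc$thrombus$D1
    }
    lin_mats$thrombus <- linear_material(E_linear / mpr_linear, nu_linear)
  }
  lin <- solve_linear_fe(mesh_def, lin_mats, p, settings)
  list(reference = ref, conventional = conv, linear = lin,
       mesh_deformed = mesh_def)
}

#' Extract a through-wall stress profile from an FE solution
#'
#' Reads the nodal stresses along the radial node line of a structured
#' wall grid closest to the requested axial station and returns them as a
#' `tube_profile` (cylindrical components: `sigma_rr = sigma_xx`,
#' `sigma_zz = sigma_yy`, `sigma_tt = sigma_oop` of the axisymmetric
#' solution).
#'
#' @param solution an `fe_solution` on a mesh with a `wall_grid`.
#' @param z axial station (mm); defaults to the station of largest outer
#'   radius.
#' @param deformed use deformed (TRUE) or reference coordinates for the
#'   radial positions.
#' @return a `tube_profile` data frame.
#' @export
wall_section_profile <- function(solution, z = NULL, deformed = TRUE) {
  mesh <- solution$mesh
  if (is.null(mesh$wall_grid)) stop("mesh has no structured wall grid")
  idg <- mesh$wall_grid
  nodes <- if (deformed) solution$nodes_deformed else mesh$nodes
  outer_ids <- idg[nrow(idg), ]
  j <- if (is.null(z)) {
    which.max(nodes[outer_ids, 1])
  } else {
    which.min(abs(nodes[outer_ids, 2] - z))
  }
  ids <- idg[, j]
  r <- nodes[ids, 1]
  s <- if (!is.null(solution$stress_by_region$wall)) {
    solution$stress_by_region$wall[ids, , drop = FALSE]
  } else {
    solution$stress_nodal[ids, , drop = FALSE]
  }
  .tube_profile_df(r, s[, "sigma_xx"], s[, "sigma_oop"], s[, "sigma_yy"],
                   model = "fe", p = NA_real_, a = min(r), b = max(r))
}
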