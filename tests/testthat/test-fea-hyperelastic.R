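test_that("consistent tangent matches finite differences of the residual", {
  set.seed(4)
  m <- make_tube_mesh(fig4_geom, n_thickness = 1, n_axial = 1)
  mats <- list(wall = rv)
  kap <- list(wall = 1e4 * 2 * rv$alpha)
  pre <- aaastress:::.fe_precompute(m, TRUE)
  n <- nrow(m$nodes)
  u <- 0.05 * rnorm(2 * n)
  cc <- matrix(0.01 * rnorm(3), 1, 3)
  asm <- aaastress:::.hyper_assemble(m, pre, mats, kap, u, cc, TRUE,
                                     want_K = TRUE)
  cd <- asm$cond[[1]]
  dofs <- cd$dofs
  h <- 1e-6
  Kfd <- matrix(0, 18, 18); Cfd <- matrix(0, 3, 18)
  for (jj in 1:18) {
    up <- u; um <- u
    up[dofs[jj]] <- up[dofs[jj]] + h
    um[dofs[jj]] <- um[dofs[jj]] - h
    ap <- aaastress:::.hyper_assemble(m, pre, mats, kap, up, cc, TRUE,
                                      want_K = FALSE)
    am <- aaastress:::.hyper_assemble(m, pre, mats, kap, um, cc, TRUE,
                                      want_K = FALSE)
    Kfd[, jj] <- (ap$fint[dofs] - am$fint[dofs]) / (2 * h)
    Cfd[, jj] <- (ap$Rc[1, ] - am$Rc[1, ]) / (2 * h)
  }
  expect_lt(max(abs(Cfd - cd$Kcd)) / max(abs(Cfd)), 1e-6)
  Kdd <- as.matrix(asm$K)[dofs, dofs] + t(cd$Kcd) %*% cd$Si %*% cd$Kcd
  expect_lt(max(abs(Kfd - Kdd)) / max(abs(Kfd)), 1e-6)
})

test_that("axisymmetric hyperelastic tube matches the closed-form solution", {
  m <- small_tube_mesh()
  s <- solve_hyperelastic_fe(m, rv, p_sys, fast_settings())
  an <- solve_nonlinear_tube(fig4_geom, rv, p_sys)
  a_fe <- min(s$nodes_deformed[, 1])
  expect_lt(abs(a_fe - an$deformed$a) / an$deformed$a, 0.005)
  pr <- wall_section_profile(s, z = mean(m$nodes[, 2]))
  ref <- approx(an$profile$r_norm, an$profile$sigma_tt, pr$r_norm)$y
  expect_lt(max(abs(pr$sigma_tt - ref) / ref), 0.01)
  # global force balance on the deformed wall
  expect_equal(pracma::trapz(pr$r_mm, pr$sigma_tt), p_sys * a_fe,
               tolerance = 0.005)
})

test_that("plane-strain ring matches the tube solution and zero load is the identity", {
  rm <- make_ring_mesh(14.8, 1.3, n_thickness = 2, n_theta = 12)
  s <- solve_hyperelastic_fe(rm, rv, p_sys,
                             fast_settings(formulation = "plane_strain"))
  an <- solve_nonlinear_tube(fig4_geom, rv, p_sys)
  r_in <- min(sqrt(rowSums(s$nodes_deformed^2)))
  expect_lt(abs(r_in - an$deformed$a) / an$deformed$a, 0.005)
  expect_lt(abs(max(s$sigma_eff) - max(an$profile$sigma_eff)) /
            max(an$profile$sigma_eff), 0.02)
  s0 <- solve_hyperelastic_fe(small_tube_mesh(), rv, 0,
                              solve_settings(n_load_steps = 1))
  expect_equal(max(abs(s0$u)), 0)
})

test_that("a thrombus-material tube reproduces its incompressible closed form", {
  # for plane-strain incompressible states II_B = I_B, so a first-invariant
  # wall with alpha = D1, beta = D2 is the analytic twin of the thrombus
  m <- make_tube_mesh(tube_geometry(9, 12), n_thickness = 3, n_axial = 2)
  s <- solve_hyperelastic_fe(m, list(wall = ilt), 0.002, fast_settings())
  twin <- hyperelastic_material(ilt$D1, ilt$D2)
  an <- solve_nonlinear_tube(tube_geometry(9, 12), twin, 0.002)
  expect_lt(abs(min(s$nodes_deformed[, 1]) - an$deformed$a) /
            an$deformed$a, 0.005)
  pr <- wall_section_profile(s, z = mean(m$nodes[, 2]))
  ref <- approx(an$profile$r_norm, an$profile$sigma_tt, pr$r_norm)$y
  expect_lt(max(abs(pr$sigma_tt - ref)) / max(abs(ref)), 0.01)
})

test_that("three-model pipeline shows conventional over-expansion and tiny linear motion", {
  m <- small_tube_mesh()
  tm <- three_model_run(m, rv, p_sys, fast_settings())
  a_ref <- min(tm$reference$nodes_deformed[, 1])
  a_conv <- min(tm$conventional$nodes_deformed[, 1])
  expect_gt(a_conv, a_ref)
  expect_lt(max(abs(tm$linear$u)), 1.3e-9)
  an <- solve_nonlinear_tube(fig4_geom, rv, p_sys)
  pr <- wall_section_profile(tm$reference, z = mean(m$nodes[, 2]))
  ref <- approx(an$profile$r_norm, an$profile$sigma_tt, pr$r_norm)$y
  expect_lt(max(abs(pr$sigma_tt - ref) / ref), 0.01)
})

test_that("pressure on the undeformed configuration expands less than the follower load", {
  m <- small_tube_mesh()
  s_def <- solve_hyperelastic_fe(m, rv, p_sys, fast_settings())
  s_und <- solve_hyperelastic_fe(m, rv, p_sys,
                                 fast_settings(pressure_config = "undeformed"))
  expect_lt(min(s_und$nodes_deformed[, 1]), min(s_def$nodes_deformed[, 1]))
})

test_that("mesh refinement reduces the tube stress error monotonically", {
  an <- solve_nonlinear_tube(fig4_geom, rv, p_sys)
  errs <- vapply(c(1, 2, 4), function(nt) {
    m <- make_tube_mesh(fig4_geom, n_thickness = nt, n_axial = 1)
    s <- solve_hyperelastic_fe(m, rv, p_sys, fast_settings())
    pr <- wall_section_profile(s, z = mean(m$nodes[, 2]))
    ref <- approx(an$profile$r_norm, an$profile$sigma_tt, pr$r_norm)$y
    max(abs(pr$sigma_tt - ref) / ref)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})
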