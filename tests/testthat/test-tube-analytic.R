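test_that("unloaded tube is the identity with zero stress", {
  sol <- solve_nonlinear_tube(fig4_geom, rv, 0)
  expect_equal(sol$deformed$a, 14.8)
  expect_equal(sol$deformed$b, 16.1)
  expect_true(all(sol$profile$sigma_eff == 0))
  lin <- solve_linear_tube(fig4_geom, 0)
  expect_true(all(abs(lin$sigma_tt) == 0))
})

test_that("nonlinear tube satisfies traction boundary conditions and force balance", {
  for (mat in list(rv, p2)) {
    sol <- solve_nonlinear_tube(fig4_geom, mat, p_sys)
    prof <- sol$profile
    expect_lt(abs(prof$sigma_rr[1] + p_sys), 1e-8 * p_sys)
    expect_lt(abs(prof$sigma_rr[nrow(prof)]), 1e-8 * p_sys)
    # area preservation
    expect_equal(sol$deformed$b^2 - sol$deformed$a^2, 16.1^2 - 14.8^2,
                 tolerance = 1e-10)
    ei <- equilibrium_integral(prof)
    expect_lt(ei$relative_gap, 1e-4)
  }
})

test_that("inflation is monotone in pressure for all built-in wall fits", {
  for (mat in list(rv, p1, p2)) {
    a_seq <- vapply(c(0.004, 0.008, 0.016, 0.027), function(p) {
      solve_nonlinear_tube(tube_geometry(14.8, 16.1), mat, p)$deformed$a
    }, numeric(1))
    expect_true(all(diff(a_seq) > 0))
  }
})

test_that("conventional re-solve of the deformed configuration over-expands", {
  ref <- solve_nonlinear_tube(fig4_geom, rv, p_sys)
  conv <- solve_nonlinear_tube(tube_geometry(ref$deformed$a, ref$deformed$b),
                               rv, p_sys)
  expect_gt(conv$deformed$a, ref$deformed$a)
})

test_that("linear tube reproduces an independently derived Lame solution", {
  prof <- solve_linear_tube(fig4_geom, p_sys)
  # independent path: displacement ansatz u = c1 r + c2 / r with constants
  # from the traction conditions written in terms of E, nu
  E <- 1; nu <- 0.4999
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu)); mu <- E / (2 * (1 + nu))
  a <- 14.8; b <- 16.1
  # sigma_rr = (lam + 2 mu) (c1 - c2/r^2) + lam (c1 + c2/r^2)
  M <- rbind(c(2 * (lam + mu), -2 * mu / a^2),
             c(2 * (lam + mu), -2 * mu / b^2))
  cs <- solve(M, c(-p_sys, 0))
  r <- prof$r_mm
  srr <- 2 * (lam + mu) * cs[1] - 2 * mu * cs[2] / r^2
  stt <- 2 * (lam + mu) * cs[1] + 2 * mu * cs[2] / r^2
  expect_equal(prof$sigma_rr, srr, tolerance = 1e-8)
  expect_equal(prof$sigma_tt, stt, tolerance = 1e-8)
  # equilibrium integral equals p a exactly for the Lame field
  ei <- equilibrium_integral(prof)
  expect_equal(ei$integral, p_sys * a, tolerance = 1e-6)
})

test_that("thin-wall limit approaches the membrane estimate for both models", {
  a <- 20; h <- 0.08                      # h/a = 0.004
  lin <- solve_linear_tube(tube_geometry(a, a + h), p_sys)
  expect_equal(mean(lin$sigma_tt), p_sys * a / h, tolerance = 0.02)
  nl <- solve_nonlinear_tube(tube_geometry(a, a + h), rv, p_sys)
  h_def <- nl$deformed$b - nl$deformed$a
  expect_equal(mean(nl$profile$sigma_tt),
               p_sys * nl$deformed$a / h_def, tolerance = 0.02)
})

test_that("linear-model displacements scale as 1/E and are negligible at high E", {
  u <- linear_tube_displacement(fig4_geom, linear_material(8.4e9), p_sys)
  expect_lt(max(abs(u$u_r)), 1.3e-9)
  expect_true(all(linear_tube_displacement(fig4_geom, linear_material(8.4e9),
                                           0)$u_r == 0))
  u1 <- linear_tube_displacement(fig4_geom, linear_material(1e6), p_sys)
  u2 <- linear_tube_displacement(fig4_geom, linear_material(2e6), p_sys)
  expect_equal(u1$u_r, 2 * u2$u_r, tolerance = 1e-12)
})

test_that("effective stress reduces correctly for canonical states", {
  expect_equal(effective_stress(0.3, 0.3, 0.3), 0)
  expect_equal(effective_stress(0, 0.21, 0), 0.21)
  # independent re-evaluation of the full formula for a tube-like state
  s <- c(-0.008, 0.19, 0.09)
  expect_equal(effective_stress(s[1], s[2], s[3]),
               sqrt(0.5 * ((s[1] - s[2])^2 + (s[2] - s[3])^2 +
                           (s[3] - s[1])^2)))
  expect_equal(effective_stress(0, 0, 0, tau_rt = 0.1), sqrt(3) * 0.1)
})

test_that("equilibrium integral rejects degenerate profiles", {
  prof <- solve_linear_tube(fig4_geom, p_sys)
  expect_error(equilibrium_integral(prof[1, ]), "2 radial nodes")
})

test_that("profiles export as CSV with the documented columns", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_profile_csv(solve_linear_tube(fig4_geom, p_sys, n_nodes = 11), f)
  back <- read.csv(f)
  expect_named(back, c("r_mm", "r_norm", "sigma_rr", "sigma_tt",
                       "sigma_zz", "sigma_eff"))
  expect_equal(nrow(back), 11)
  expect_equal(back$r_norm[c(1, 11)], c(0, 1))
})
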