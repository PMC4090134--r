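test_that("built-in catalog carries the published coefficient sets", {
  expect_equal(unlist(rv[c("alpha", "beta", "gamma")]),
               c(alpha = 0.174, beta = 1.881, gamma = 0))
  expect_equal(unlist(p1[c("alpha", "beta", "gamma")]),
               c(alpha = 0.0145, beta = 0, gamma = 2.259))
  expect_equal(unlist(p2[c("alpha", "beta", "gamma")]),
               c(alpha = 0.022, beta = 1.461, gamma = 1.0))
  expect_equal(ilt$D1, 0.026)
  expect_error(builtin_materials("nope"), "unknown material")
})

test_that("strain energy vanishes in the reference state and sums its terms", {
  expect_identical(strain_energy(rv, 3), 0)
  expect_equal(strain_energy(rv, 4), 0.174 + 1.881)
  # independent naive term-by-term evaluation
  naive <- function(mat, IB) {
    co <- unlist(mat[c("alpha", "beta", "gamma", "zeta", "eta")])
    sum(co * (IB - 3)^(1:5))
  }
  for (IB in c(3.1, 3.5, 4.7)) {
    expect_equal(strain_energy(p2, IB), naive(p2, IB), tolerance = 1e-12)
    expect_equal(strain_energy(p1, IB), naive(p1, IB), tolerance = 1e-12)
  }
  m5 <- hyperelastic_material(0.1, 0.2, 0.3, 0.4, 0.5)
  expect_equal(strain_energy(m5, 3.8), naive(m5, 3.8), tolerance = 1e-12)
  expect_error(strain_energy(rv, 3 - 1e-6), "physical range")
  expect_error(strain_energy(rv, NaN), "finite")
})

test_that("analytic energy derivative matches central finite differences", {
  h <- 1e-6
  for (mat in list(rv, p1, p2)) {
    IB <- seq(3 + 1e-3, 6, length.out = 25)
    fd <- (strain_energy(mat, IB + h) - strain_energy(mat, IB - h)) / (2 * h)
    expect_equal(strain_energy_deriv(mat, IB), fd, tolerance = 1e-6)
  }
})

test_that("energy is non-negative and strictly increasing beyond IB = 3", {
  IB <- seq(3, 6, length.out = 200)
  for (mat in list(rv, p1, p2)) {
    w <- strain_energy(mat, IB)
    expect_true(all(w >= 0))
    expect_true(all(diff(w) > 0))
  }
})

test_that("thrombus energy is zero at the undeformed state and quadratic in II_B", {
  expect_identical(strain_energy(ilt, 3), 0)
  expect_equal(strain_energy(ilt, 3.4), 0.026 * 0.4 + 0.0286 * 0.16)
  expect_equal(strain_energy_deriv(ilt, 3.4), 0.026 + 2 * 0.0286 * 0.4)
  expect_error(thrombus_material(0), "D1")
})

test_that("principal Cauchy stresses follow the incompressible constitutive law", {
  # at the undeformed state the hydrostatic pressure 2 W'(3) renders the
  # wall stress-free (H is fixed by the boundary-value problem, not by the
  # constitutive law)
  s0 <- stretch_state(1, 1, 1, H = 2 * strain_energy_deriv(rv, 3))
  expect_equal(unname(cauchy_stress(rv, s0)), c(0, 0, 0))
  # equal in-plane stretches give equal in-plane stresses
  se <- stretch_state(1.1, 1.1, 1 / 1.1^2, H = 0.3)
  st <- cauchy_stress(rv, se)
  expect_equal(st[["sigma_rr"]], st[["sigma_tt"]])
  # stress differences are H-independent and match the finite-difference
  # energy derivative along the constrained stretch path
  lam <- 1.2
  for (H in c(0, 0.5)) {
    s <- cauchy_stress(rv, stretch_state(1 / lam, lam, 1, H = H))
    h <- 1e-6
    path_w <- function(l) strain_energy(rv, l^2 + l^-2 + 1)
    fd <- lam * (path_w(lam + h) - path_w(lam - h)) / (2 * h)
    expect_equal(s[["sigma_tt"]] - s[["sigma_rr"]], fd, tolerance = 1e-7)
  }
  expect_error(cauchy_stress(rv, stretch_state(1 / lam, lam, 1)),
               "hydrostatic pressure")
  expect_error(stretch_state(1.2, 1.2, 1), "incompressibility")
})

test_that("pressure unit conversion matches the clinical reference point", {
  expect_equal(signif(mmHg_to_MPa(120), 2), 0.016)
  expect_equal(MPa_to_mmHg(mmHg_to_MPa(87.3)), 87.3, tolerance = 1e-12)
})

test_that("material catalogs round-trip through the key-value text format", {
  f <- withr::local_tempfile(fileext = ".txt")
  mats <- list(RV = rv, ILT = ilt, lin = linear_material(8.4e9, 0.4999))
  write_materials(mats, f)
  back <- read_materials(f)
  expect_equal(back$RV$alpha, rv$alpha)
  expect_equal(back$RV$beta, rv$beta)
  expect_equal(back$ILT$D2, ilt$D2)
  expect_equal(back$lin$E, 8.4e9)
  expect_s3_class(back$lin, "linear_material")
})
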