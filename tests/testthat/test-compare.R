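test_that("pointwise percent difference behaves as a relative error field", {
  x <- c(1, 2, 3)
  expect_equal(unclass(percent_diff(x, x)), rep(0, 3), ignore_attr = TRUE)
  expect_equal(unclass(percent_diff(1.1 * x, x)), rep(10, 3),
               ignore_attr = TRUE, tolerance = 1e-12)
  masked <- percent_diff(c(1, 2), c(1, 0))
  expect_true(is.na(masked[2]))
  expect_equal(attr(masked, "n_masked"), 1L)
  expect_error(percent_diff(1:3, 1:4), "same nodes")
})

test_that("integrated difference matches closed-form toy profiles", {
  mk <- function(vals) {
    r <- seq(0, 1, length.out = length(vals))
    aaastress:::.tube_profile_df(r, vals * 0, vals, vals * 0, "toy", 0.01, 0, 1)
  }
  a <- mk(rep(2, 11)); b <- mk(rep(1, 11))
  expect_equal(integrated_diff(a, b, field = "sigma_tt"), 100)
  expect_equal(integrated_diff(b, b, field = "sigma_tt"), 0)
  # metric is invariant to a common positive rescaling
  a5 <- mk(rep(10, 11)); b5 <- mk(rep(5, 11))
  expect_equal(integrated_diff(a5, b5, field = "sigma_tt"), 100)
  # signed integrand cancels symmetric over/under-shoots
  osc <- mk(1 + c(rep(0.5, 5), 0, rep(-0.5, 5)))
  expect_lt(abs(integrated_diff(osc, mk(rep(1, 11)), field = "sigma_tt",
                                signed = TRUE)), 1e-10)
  # mismatched grids resample with a warning
  c_ <- mk(rep(2, 7))
  expect_warning(v <- integrated_diff(c_, b, field = "sigma_tt"),
                 "resampling")
  expect_equal(v, 100)
})

test_that("pointwise formula agrees with hand evaluation at spot radii", {
  ref <- solve_nonlinear_tube(fig4_geom, rv, p_sys)
  lin <- solve_linear_tube(tube_geometry(ref$deformed$a, ref$deformed$b),
                           p_sys)
  pd <- percent_diff(lin$sigma_tt, ref$profile$sigma_tt)
  for (i in c(1, 101, 201)) {
    expect_equal(pd[i],
                 100 * (lin$sigma_tt[i] - ref$profile$sigma_tt[i]) /
                   ref$profile$sigma_tt[i])
  }
})

test_that("material/geometry sweep reproduces the expected orderings", {
  sw <- run_sweep(c(0.08, 0.174, 0.35), 1.881,
                  data.frame(B = c(16.1, 25), h0 = c(1.3, 1.3)), p = p_sys)
  expect_true(all(is.finite(sw$integrated_pct)))
  wide <- reshape(sw, idvar = c("alpha_ref", "beta_ref", "B", "h0"),
                  timevar = "model", direction = "wide")
  # linear differences stay below conventional differences in every cell
  expect_true(all(wide$integrated_pct.linear <
                  wide$integrated_pct.conventional))
  # both model differences shrink as the reference wall stiffens
  for (b in unique(wide$B)) {
    sub <- wide[wide$B == b, ]
    sub <- sub[order(sub$alpha_ref), ]
    expect_true(all(diff(sub$integrated_pct.linear) < 0))
    expect_true(all(diff(sub$integrated_pct.conventional) < 0))
  }
  # larger diameter at constant thickness widens the conventional gap and
  # narrows the linear one
  rv_cell <- wide[wide$alpha_ref == 0.174, ]
  expect_gt(rv_cell$integrated_pct.conventional[rv_cell$B == 25],
            rv_cell$integrated_pct.conventional[rv_cell$B == 16.1])
  expect_lt(rv_cell$integrated_pct.linear[rv_cell$B == 25],
            rv_cell$integrated_pct.linear[rv_cell$B == 16.1])
  # maxima: conventional overestimates, linear underestimates
  expect_true(all(wide$max_pct.conventional > 0))
  expect_true(all(wide$max_pct.linear < 0))
  expect_equal(attr(sw, "alpha_band"), c(0.0145, 0.204))
})

test_that("raising the pressure penalizes the conventional model only", {
  cell <- function(p) {
    run_sweep(0.174, 1.881, data.frame(B = 16.1, h0 = 1.3), p = p)
  }
  lo <- cell(0.016); hi <- cell(0.027)
  d_conv <- hi$integrated_pct[hi$model == "conventional"] -
            lo$integrated_pct[lo$model == "conventional"]
  d_lin <- hi$integrated_pct[hi$model == "linear"] -
           lo$integrated_pct[lo$model == "linear"]
  expect_gt(d_conv, 0)
  expect_gt(d_conv, 3 * abs(d_lin))
  # the linear stress field itself simply scales with p
  l1 <- solve_linear_tube(fig4_geom, 0.016)
  l2 <- solve_linear_tube(fig4_geom, 0.027)
  expect_equal(l2$sigma_tt, l1$sigma_tt * 0.027 / 0.016, tolerance = 1e-12)
})

test_that("sweeps are deterministic across repeated runs", {
  a <- run_sweep(c(0.1, 0.2), 1.0, data.frame(B = 16.1, h0 = 1.3))
  b <- run_sweep(c(0.1, 0.2), 1.0, data.frame(B = 16.1, h0 = 1.3))
  expect_identical(a, b)
})

test_that("population-average coefficients give the printed stiffness ratio", {
  expect_equal(round(mpr_value(rv, ilt), 1), 6.7)
  mm4 <- aaastress:::.mpr_materials(4)
  expect_equal(mm4$wall$alpha, 0.144)
  expect_equal(mm4$thrombus$D1, 0.036)
  mm10 <- aaastress:::.mpr_materials(10.25)
  expect_equal(mm10$wall$alpha / mm10$thrombus$D1, 10.25, tolerance = 0.01)
  expect_error(aaastress:::.mpr_materials(5), "no built-in")
})
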