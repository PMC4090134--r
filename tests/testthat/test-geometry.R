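test_that("structured tube meshes have exact boundaries and areas", {
  m <- make_tube_mesh(fig4_geom, n_thickness = 6, n_axial = 20)
  expect_equal(nrow(m$elems), 120)
  expect_gt(min_jacobian(m), 0)
  # cross-section in (r, z) is the rectangle (B - A) x length
  expect_equal(mesh_area(m), (16.1 - 14.8) * 4 * (16.1 - 14.8),
               tolerance = 1e-10)
  r <- m$nodes[, 1]
  lum <- unique(as.vector(m$sets$lumen_edges))
  expect_true(all(r[lum] == 14.8))
  expect_true(all(r[m$sets$outer_nodes] == 16.1))
  expect_error(make_tube_mesh(tube_geometry(1, 2), 0), ">= 1")
})

test_that("ring meshes converge to the annulus area under refinement", {
  errs <- vapply(c(8, 16, 32), function(nt) {
    m <- make_ring_mesh(14.8, 1.3, n_thickness = 2, n_theta = nt)
    abs(mesh_area(m) - pi * (16.1^2 - 14.8^2))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3] / (pi * (16.1^2 - 14.8^2)), 1e-5)
  expect_error(make_ring_mesh(10, 1, n_theta = 6), "multiple of 4")
})

test_that("the idealized aneurysm profile meets its printed dimensions", {
  pr <- aaa_profile()
  expect_equal(pr$outer_radius(65), 25)          # 50 mm maximum diameter
  zz <- seq(0, 130, length.out = 401)
  expect_equal(pr$outer_radius(0), 11, tolerance = 1e-6)   # cylindrical ends
  expect_true(all(pr$lumen_radius(zz) <= pr$outer_radius(zz) - 1.5 + 1e-9))
  m <- make_aaa_mesh(pr, n_wall = 3, n_axial = 20)
  expect_gt(min_jacobian(m), 0)
  # uniform 1.5 mm wall: outer minus inner radius at every axial station
  idg <- m$wall_grid
  thick <- m$nodes[idg[nrow(idg), ], 1] - m$nodes[idg[1, ], 1]
  expect_equal(thick, rep(1.5, ncol(idg)), tolerance = 1e-9)
})

test_that("thrombus meshes conform to the wall and tag the composite lumen", {
  pr <- aaa_profile()
  m <- make_aaa_mesh(pr, with_thrombus = TRUE, n_wall = 2, n_axial = 16,
                     n_thrombus = 3)
  expect_setequal(unique(m$region), c("wall", "thrombus"))
  expect_gt(min_jacobian(m), 0)
  # shared interface: thrombus outer row reuses wall inner-row node ids
  expect_true(all(m$thrombus_grid[nrow(m$thrombus_grid), ] %in%
                  m$wall_grid[1, ]))
  # lumen edge nodes lie on either the wall inner face or the thrombus
  # inner face
  lum <- unique(as.vector(m$sets$lumen_edges))
  onwall <- lum %in% m$wall_grid[1, ]
  onthr <- lum %in% m$thrombus_grid[1, ]
  expect_true(all(onwall | onthr))
  expect_true(any(onthr))
  expect_error(make_aaa_mesh(aaa_profile(with_lumen = FALSE),
                             with_thrombus = TRUE), "no lumen")
})

test_that("patient-like profiles are deterministic and meshable", {
  a <- make_patient_like_profile(11)
  b <- make_patient_like_profile(11)
  zz <- seq(0, 130, length.out = 64)
  expect_identical(a$outer_radius(zz), b$outer_radius(zz))
  expect_false(identical(a$outer_radius(zz),
                         make_patient_like_profile(12)$outer_radius(zz)))
  flat <- make_patient_like_profile(1, max_amplitude = 0)
  expect_equal(flat$outer_radius(zz), rep(21.5, length(zz)))
  for (seed in c(3, 7)) {
    m <- make_aaa_mesh(make_patient_like_profile(seed), n_wall = 2,
                       n_axial = 24)
    expect_gt(min_jacobian(m), 0)
  }
  expect_error(make_patient_like_profile(5, max_amplitude = 60, n_bumps = 6),
               "too steep")
})

test_that("thickness modulation preserves validity and rejects pinch-off", {
  mod <- thickness_modulation("longitudinal", 0.4, n_waves = 2)
  m <- make_tube_mesh(tube_geometry(14.8, 16.1), 3, 12, length = 40,
                      modulation = mod)
  expect_gt(min_jacobian(m), 0)
  expect_error(make_tube_mesh(tube_geometry(14.8, 16.1), 3, 12,
                              modulation = thickness_modulation("longitudinal", 1.5)),
               "thickness")
  mr <- make_ring_mesh(14.8, 1.3, 2, 16,
                       modulation = thickness_modulation("circumferential", 0.4))
  expect_gt(min_jacobian(mr), 0)
  expect_error(make_ring_mesh(14.8, 1.3, 2, 16,
                              modulation = thickness_modulation("longitudinal", 0.1)),
               "circumferential")
})

test_that("meshes and fields round-trip through VTK and .inp files", {
  f <- withr::local_tempfile(fileext = ".vtk")
  m <- make_aaa_mesh(aaa_profile(), with_thrombus = TRUE, n_wall = 2,
                     n_axial = 10, n_thrombus = 2)
  write_vtk(m, f, point_data = list(radius = m$nodes[, 1]))
  back <- read_vtk(f)
  expect_equal(back$nodes, m$nodes, tolerance = 1e-9, ignore_attr = TRUE)
  expect_identical(back$elems, m$elems, ignore_attr = TRUE)
  expect_identical(back$region, m$region)

  fi <- withr::local_tempfile(fileext = ".inp")
  writeLines(c("*NODE", paste(seq_len(9), m$nodes[1:9, 1], m$nodes[1:9, 2],
                              sep = ", "),
               "*ELEMENT, TYPE=CAX9, ELSET=WALL",
               paste(c(1, seq_len(9)), collapse = ", ")), fi)
  mi <- read_inp(fi)
  expect_equal(nrow(mi$nodes), 9)
  expect_identical(mi$region, "wall")
})
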