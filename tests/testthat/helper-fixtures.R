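# shared fixtures: built-in materials and small meshes used across tests

rv <- builtin_materials("RV")
p1 <- builtin_materials("P1")
p2 <- builtin_materials("P2")
ilt <- builtin_materials("ILT")

fig4_geom <- tube_geometry(14.8, 16.1)
p_sys <- 0.016   # systolic, N/mm^2

small_tube_mesh <- function(n_thickness = 4, n_axial = 2) {
  make_tube_mesh(fig4_geom, n_thickness = n_thickness, n_axial = n_axial)
}

fast_settings <- function(...) solve_settings(n_load_steps = 8, ...)

# single unit-square Q9 element with pressure on the right edge pushing in
# -x, left edge fixed in x, bottom edge fixed in y: constant stress state
# sigma_xx = -p, sigma_yy = 0 (plane strain patch)
patch_mesh <- function() {
  xs <- c(0, 0.5, 1)
  nodes <- as.matrix(expand.grid(x = xs, y = xs))[, 1:2]
  idg <- matrix(1:9, 3, 3)               # [i = x station, j = y station]
  elems <- matrix(c(idg[1, 1], idg[3, 1], idg[3, 3], idg[1, 3],
                    idg[2, 1], idg[3, 2], idg[2, 3], idg[1, 2], idg[2, 2]),
                  1, 9)
  # right edge x = 1, travel +y so the left normal (-x) points into the solid
  edges <- matrix(c(idg[3, 1], idg[3, 2], idg[3, 3]), 1, 3)
  aaastress:::.new_mesh(nodes, elems, "wall",
                        sets = list(lumen_edges = edges,
                                    fix_z = idg[, 1],   # bottom: u_y = 0
                                    fix_x = idg[1, ]))  # left: u_x = 0
}
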