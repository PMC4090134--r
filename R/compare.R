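# Stress-difference metrics and comparison pipelines.
#
# Pointwise percent difference: 100 (sigma_i - sigma_i*) / sigma_i*, with
# sigma_i* the reference stress at the same point. Integrated difference:
# the absolute stress gap integrated over the normalized wall thickness,
# normalized to the reference stress integral (in percent). Positive
# pointwise values mean the test model overestimates the reference.

#' Pointwise percent stress difference
#'
#' `100 * (test - ref) / ref` per point. Points where the reference is
#' (numerically) zero are masked to `NA`; their count is attached as the
#' `n_masked` attribute.
#'
#' @param field_test,field_ref numeric vectors on the same nodes.
#' @param zero_tol reference values with magnitude below
#'   `zero_tol * max(abs(field_ref))` are masked.
#' @return percent differences with attribute `n_masked`.
#' @export
percent_diff <- function(field_test, field_ref, zero_tol = 1e-10) {
  if (length(field_test) != length(field_ref)) {
    stop("fields must be defined on the same nodes (length mismatch)")
  }
  mask <- abs(field_ref) <= zero_tol * max(abs(field_ref), .Machine$double.eps)
  out <- 100 * (field_test - field_ref) / field_ref
  out[mask] <- NA_real_
  attr(out, "n_masked") <- sum(mask)
  out
}

#' Integrated normalized stress difference
#'
#' Integrates the stress gap between two through-wall profiles over the
#' normalized thickness and normalizes by the reference stress integral:
#' `100 * int |s - s*| dr' / int s* dr'`. Profiles on different normalized
#' grids are resampled onto the reference grid by linear interpolation
#' (with a warning).
#'
#' @param profile_test,profile_ref `tube_profile` data frames.
#' @param field profile column to compare (default `"sigma_eff"`).
#' @param signed use the signed integrand instead of its absolute value.
#' @return scalar percent difference.
#' @export
integrated_diff <- function(profile_test, profile_ref, field = "sigma_eff",
                            signed = FALSE) {
  stopifnot(field %in% names(profile_test), field %in% names(profile_ref))
  xr <- profile_ref$r_norm
  yt <- profile_test[[field]]
  if (length(profile_test$r_norm) != length(xr) ||
      max(abs(profile_test$r_norm - xr)) > 1e-12) {
    warning("profiles on different normalized-thickness grids; resampling")
    yt <- stats::approx(profile_test$r_norm, yt, xout = xr, rule = 2)$y
  }
  gap <- yt - profile_ref[[field]]
  if (!signed) gap <- abs(gap)
  100 * pracma::trapz(xr, gap) / pracma::trapz(xr, profile_ref[[field]])
}

#' Percent difference of profile maxima
#'
#' Locates the maximum of the chosen stress field independently in the
#' test and reference profiles and returns their percent difference.
#'
#' @inheritParams integrated_diff
#' @return scalar percent difference of the maxima.
#' @export
max_stress_diff <- function(profile_test, profile_ref, field = "sigma_eff") {
  100 * (max(profile_test[[field]]) - max(profile_ref[[field]])) /
    max(profile_ref[[field]])
}

#' Material / geometry sweep of the analytic tube pipeline
#'
#' For every combination of reference-material coefficients and initial
#' geometry: solve the reference hyperelastic tube, re-solve its deformed
#' configuration with the conventional model (fixed population-average
#' material) and the linear model, and record the integrated and
#' maximum-stress percent differences of both against the reference.
#'
#' @param alpha_ref,beta_ref coefficient grids for the reference wall
#'   (N/mm^2); `gamma = 0`.
#' @param geometries data frame with columns `B` (initial outer radius,
#'   mm) and `h0` (initial wall thickness, mm).
#' @param p internal pressure (N/mm^2).
#' @param mat_conventional wall material of the conventional model.
#' @param field stress field compared (default effective stress).
#' @param n_nodes radial nodes per profile.
#' @return long-format data frame with one row per (cell, model) and
#'   columns `alpha_ref`, `beta_ref`, `B`, `h0`, `model`,
#'   `integrated_pct`, `max_pct`, `a_def`, plus an `alpha_band` attribute
#'   marking the physiological range of `alpha_ref` spanned by the
#'   built-in tissue fits.
#' @export
run_sweep <- function(alpha_ref, beta_ref,
                      geometries = data.frame(B = 16.1, h0 = 1.3),
                      p = 0.016,
                      mat_conventional = builtin_materials("RV"),
                      field = "sigma_eff", n_nodes = 201) {
  stopifnot(all(c("B", "h0") %in% names(geometries)))
  rows <- list()
  for (gi in seq_len(nrow(geometries))) {
    B <- geometries$B[gi]; h0 <- geometries$h0[gi]
    geom <- tube_geometry(B - h0, B)
    for (al in alpha_ref) for (be in beta_ref) {
      mat_ref <- hyperelastic_material(al, be,
                                       label = sprintf("a%g-b%g", al, be))
      cell <- tryCatch({
        ref <- solve_nonlinear_tube(geom, mat_ref, p, n_nodes)
        gdef <- tube_geometry(ref$deformed$a, ref$deformed$b)
        conv <- solve_nonlinear_tube(gdef, mat_conventional, p, n_nodes)
        lin <- solve_linear_tube(gdef, p, n_nodes = n_nodes)
        data.frame(
          alpha_ref = al, beta_ref = be, B = B, h0 = h0,
          model = c("linear", "conventional"),
          integrated_pct = c(integrated_diff(lin, ref$profile, field),
                             integrated_diff(conv$profile, ref$profile, field)),
          max_pct = c(max_stress_diff(lin, ref$profile, field),
                      max_stress_diff(conv$profile, ref$profile, field)),
          a_def = c(ref$deformed$a, conv$deformed$a))
      }, error = function(e) {
        data.frame(alpha_ref = al, beta_ref = be, B = B, h0 = h0,
                   model = c("linear", "conventional"),
                   integrated_pct = NA_real_, max_pct = NA_real_,
                   a_def = NA_real_)
      })
      rows[[length(rows) + 1L]] <- cell
    }
  }
  out <- do.call(rbind, rows)
  # physiological alpha band: the range spanned by the built-in tissue fits
  attr(out, "alpha_band") <- c(0.0145, 0.204)
  out
}

#' Wall-to-thrombus material property ratio
#'
#' `MPR = alpha / D1` for nonlinear materials (or the ratio of Young's
#' moduli in the linear model).
#'
#' @param wall a [hyperelastic_material()].
#' @param thrombus a [thrombus_material()].
#' @return scalar ratio.
#' @examples
#' mpr_value(builtin_materials("RV"), builtin_materials("ILT"))  # ~6.7
#' @export
mpr_value <- function(wall, thrombus) {
  stopifnot(inherits(wall, "hyperelastic_material"),
            inherits(thrombus, "thrombus_material"))
  wall$alpha / thrombus$D1
}

# wall/thrombus coefficient pairs for the stiffness-ratio experiments
.mpr_materials <- function(mpr) {
  key <- sprintf("%.2f", mpr)
  switch(key,
    "4.00" = list(wall = builtin_materials("wall-weak"),
                  thrombus = builtin_materials("ILT-stiff")),
    "6.70" = list(wall = builtin_materials("RV"),
                  thrombus = builtin_materials("ILT")),
    "10.25" = list(wall = builtin_materials("wall-stiff"),
                   thrombus = builtin_materials("ILT-weak")),
    stop("no built-in coefficient pair for MPR = ", mpr,
         "; supply materials explicitly via three_model_run"))
}

#' Thrombus stiffness-ratio (MPR) experiment on the curved aneurysm
#'
#' For each requested wall-to-thrombus material property ratio, runs the
#' requested models of the three-model pipeline on the thrombus-bearing
#' curved axisymmetric aneurysm and compares wall effective stresses
#' through the wall at the maximum-diameter section. The linear model uses
#' a wall/thrombus Young's modulus ratio equal to the MPR.
#'
#' @param profile an [aaa_profile()] with lumen; default geometry.
#' @param mpr_values ratios to run (built-in coefficient pairs exist for
#'   4, 6.7 and 10.25).
#' @param p internal pressure (N/mm^2).
#' @param settings a [solve_settings()].
#' @param models subset of `c("reference", "conventional", "linear")`;
#'   the reference is always run.
#' @param n_wall,n_axial,n_thrombus mesh densities (see [make_aaa_mesh()]).
#' @return list with `table` (per MPR and model: max pointwise percent
#'   difference magnitude at the max-diameter section, integrated percent
#'   difference, max wall effective stress) and `profiles` (through-wall
#'   `tube_profile`s per MPR and model).
#' @export
mpr_experiment <- function(profile = aaa_profile(),
                           mpr_values = c(4, 6.7, 10.25), p = 0.016,
                           settings = solve_settings(),
                           models = c("reference", "linear"),
                           n_wall = 3, n_axial = 40, n_thrombus = 10) {
  models <- match.arg(models, c("reference", "conventional", "linear"),
                      several.ok = TRUE)
  mesh <- make_aaa_mesh(profile, with_thrombus = TRUE, n_wall = n_wall,
                        n_axial = n_axial, n_thrombus = n_thrombus)
  rows <- list(); profs <- list()
  for (mpr in mpr_values) {
    mm <- .mpr_materials(mpr)
    ref <- solve_hyperelastic_fe(mesh, mm, p, settings)
    prof_ref <- wall_section_profile(ref)
    z_max <- ref$nodes_deformed[
      mesh$wall_grid[nrow(mesh$wall_grid),
                     which.max(ref$nodes_deformed[
                       mesh$wall_grid[nrow(mesh$wall_grid), ], 1])], 2]
    profs[[sprintf("mpr%.4g_reference", mpr)]] <- prof_ref
    mesh_def <- mesh
    mesh_def$nodes <- ref$nodes_deformed
    for (model in setdiff(models, "reference")) {
      sol <- if (model == "conventional") {
        solve_hyperelastic_fe(mesh_def, mm, p, settings)
      } else {
        lm <- list(wall = linear_material(8.4e9),
                   thrombus = linear_material(8.4e9 / mpr))
        solve_linear_fe(mesh_def, lm, p, settings)
      }
      prof <- wall_section_profile(sol, z = z_max)
      profs[[sprintf("mpr%.4g_%s", mpr, model)]] <- prof
      pd <- percent_diff(
        stats::approx(prof$r_norm, prof$sigma_eff,
                      xout = prof_ref$r_norm, rule = 2)$y,
        prof_ref$sigma_eff)
      rows[[length(rows) + 1L]] <- data.frame(
        mpr = mpr, model = model,
        max_pointwise_pct = max(abs(pd), na.rm = TRUE),
        integrated_pct = suppressWarnings(integrated_diff(prof, prof_ref)),
        max_eff_test = max(prof$sigma_eff),
        max_eff_ref = max(prof_ref$sigma_eff))
    }
  }
  list(table = do.call(rbind, rows), profiles = profs)
}
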