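---
title: "Linear-equilibrium estimation of aneurysm wall stress: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linear-equilibrium estimation of aneurysm wall stress: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aaastress)
```

## The problem

Wall stress in an abdominal aortic aneurysm (AAA) is a candidate predictor
of rupture risk, but computing it from medical images is awkward for two
reasons. First, the imaged geometry is the *loaded* configuration: the
vessel is pressurized when scanned, and its unloaded, unstressed shape is
unknown. Second, aneurysm wall tissue is strongly nonlinear, so
finite-element solves on the imaged geometry require incremental loading
and Newton iterations that may or may not converge.

The conventional work-around — pretending the imaged geometry is unloaded
and inflating it with a hyperelastic wall law — produces an artificial
extra expansion and systematically distorted stresses. This package
implements and compares three modelling strategies on shared geometries:

* **Reference model** — a hypothetical run in which the unloaded
  configuration and the material are assumed known. Its stresses are the
  ground truth for comparisons.
* **Conventional model** — a hyperelastic inflation that (wrongly) treats
  the imaged geometry as unloaded.
* **Linear model** — a linear-elastic, infinitesimal-displacement solve on
  the imaged geometry. Because displacements are negligible, equilibrium
  (and the pressure boundary condition) is satisfied *on the imaged
  geometry itself*, and the resulting stresses are independent of the
  Young's modulus chosen.

The linear model is the package's focus: it is cheap (one linear solve),
robust, and requires no knowledge of the tissue properties.

## Constitutive models

Wall tissue is isotropic, (nearly) incompressible hyperelastic with the
polynomial energy density

$$W(I_B) = \alpha (I_B - 3) + \beta (I_B - 3)^2 + \gamma (I_B - 3)^3
         + \zeta (I_B - 3)^4 + \eta (I_B - 3)^5 ,$$

where $I_B$ is the first invariant of the left Cauchy–Green tensor
$B = F F^T$. The classical two-term population-average fit (`RV`,
$\alpha = 0.174$, $\beta = 1.881$ N/mm²) and two patient-sample fits
(`P1`, `P2`) are built in; the five-term form is the single
implementation, with higher coefficients zero where a fit does not use
them. The Cauchy stress of an incompressible state is
$\sigma = -H I + 2 W'(I_B)\, B$ with the hydrostatic pressure $H$ supplied
by the boundary-value problem (at the undeformed state the stress-free
condition corresponds to $H = 2 W'(3)$, not $H = 0$).

Intraluminal thrombus (ILT) uses an energy in the *second* invariant,
$W_{\mathrm{ILT}} = D_1 (II_B - 3) + D_2 (II_B - 3)^2$. The
population-average $D_1 = 0.026$ N/mm² is built in; the published
population statistics give only a 95% range for $D_2$
(0.0216–0.0356 N/mm²), so the catalog's mean thrombus uses the midpoint
$D_2 = 0.0286$ N/mm². The wall-to-thrombus **material property ratio**
(MPR) is $\alpha / D_1$ (ratio of Young's moduli in the linear model);
the built-in coefficient pairs realize MPR = 4, 6.7 and 10.25.

Units are fixed package-wide: mm, N, N/mm² (MPa). Pressures in mmHg go
through `mmHg_to_MPa()` (1 mmHg = 1.33322e-4 N/mm²); tension is positive
and the lumen boundary condition is $\sigma_{rr} = -p$.

## Closed-form tube solutions

For a longitudinally constrained thick-wall tube under internal pressure
(plane strain, $\lambda_z = 1$), incompressibility ties the deformed and
undeformed radii by area preservation, $r^2 - a^2 = R^2 - A^2$, so
$\lambda_\theta = r/R$ and $\lambda_r = R/r$. The radial equilibrium ODE

$$\frac{d\sigma_{rr}}{dr} = \frac{\sigma_{\theta\theta} - \sigma_{rr}}{r},
\qquad
\sigma_{\theta\theta} - \sigma_{rr} = 2 W'(I_B)\,
(\lambda_\theta^2 - \lambda_r^2)$$

is integrated from $\sigma_{rr}(a) = -p$, and the deformed outer radius is
the root of $\sigma_{rr}(b) = 0$. `solve_nonlinear_tube()` brackets that
root on $[B,\; B(1 + pB/(\alpha(B-A)) + 0.05)]$ (expanding if needed) and
solves it to 1e-12 mm; the stored profile uses 201 evenly spaced radii
with the running integral evaluated by 5-point Gauss panels between
nodes. The axial stress follows from the hydrostatic pressure:
$\sigma_{zz} = \sigma_{rr} + 2 W' (1 - \lambda_r^2)$.

The linear model on the same geometry is the Lamé plane-strain field,
independent of $E$, with $\sigma_{zz} = \nu(\sigma_{rr} +
\sigma_{\theta\theta})$ from the zero axial strain constraint. Every tube
solve can be audited with `equilibrium_integral()`: in equilibrium the
through-wall integral of $\sigma_{\theta\theta}$ equals $p\,a$ exactly,
so the relative gap between the two is a solver-quality diagnostic.

Profiles are reported against the normalized thickness
$r' = (r - a)/(b - a)$, with $r' = 0$ at the lumen.

## Residual stress by the opening angle

A radially cut unloaded artery ring springs open; closing a stress-free
open sector of sweep $2(\pi - \varphi)$ into the full ring generates
self-equilibrated circumferential residual stress. With the mapping
factor $k = \pi / (\pi - \varphi)$ (the classical convention, stated
explicitly because the opening angle is otherwise only defined
pictorially) the exact incompressible plane-strain kinematics of the
closure are

$$r^2 = a_0^2 + \frac{R^2 - A_{\mathrm{open}}^2}{k}, \qquad
\lambda_\theta = \frac{k r}{R}, \qquad \lambda_r = \frac{R}{k r} .$$

This reduces the residual problem to a single root-find: choose
$A_{\mathrm{open}}$ so that the closed ring is traction-free on both
surfaces; the open outer radius follows from area preservation. Compared
with a finite-element sector closure (imposing a closing displacement on
a half sector), these semi-analytic kinematics honor the fixed closed
geometry exactly and make angle sweeps essentially free. Loading the
closed ring composes the same map with inflation and root-finds the
loaded inner radius.

Residual stress is compressive at the inner surface and tensile at the
outer surface, and integrates to zero net circumferential force. Under
load, increasing $\varphi$ first flattens the through-wall stress
gradient and then reverses it; `find_uniformizing_angle()` locates the
angle of flattest loaded stress by a coarse sweep (13 angles by default)
refined with a golden-section search, returning the grid minimum with a
warning flag when the sweep is not unimodal. The operation rejects
$p = 0$, where there is nothing to uniformize.

## The finite-element core

Geometries beyond the straight tube are solved with a compact
displacement/pressure mixed finite-element core:

* **Element**: 9-node Lagrange quadrilateral, 3×3 Gauss quadrature,
  with a discontinuous linear pressure field (1, ξ, η) per element —
  the inf-sup stable "9/3" pair — condensed at the element level.
  Axisymmetric and plane-strain formulations share one code path (the
  out-of-plane stretch is $x_r / X_R$ or 1).
* **Near-incompressibility**: the volumetric penalty modulus is
  `kappa_factor` (default 1e4) times the small-strain shear modulus of
  each region's material ($2\alpha$ for first-invariant walls,
  $2 D_1$ for thrombus); the linear solver takes $\kappa$ from
  $E, \nu$ with $\nu = 0.4999$ by default.
* **Hyperelastic solves**: incremental loading (default 15 steps; up to
  60 are useful for the stiffer sweeps) with full Newton per step and
  convergence judged by the out-of-balance energy ratio (default
  tolerance 0.001, at most 15 iterations per step, one step-halving
  retry). The Kirchhoff-stress material tangent is differentiated
  numerically per Gauss point (central differences on the five carried
  components of $F$), which lets first- and second-invariant energies
  share the assembly; the geometric and pressure-coupling blocks are
  exact, and a finite-difference test in the suite pins the assembled
  tangent to the residual derivative. Newton updates are damped: an
  increment is capped at 20% of the mesh extent and backtracked whenever
  it would drive an element Jacobian near inversion — thin curved walls
  are bending-soft at first and would otherwise overshoot.
* **Pressure loads**: the lumen pressure is a follower load on the
  deforming lumen by default (with its exact load stiffness assembled;
  omitting it stalls Newton on thin shells); `pressure_config =
  "undeformed"` applies it to the initial configuration instead. The
  linear solver always loads the undeformed geometry, consistent with
  its infinitesimal-displacement assumption — this is what makes its
  stresses exactly independent of $E$ (the whole system scales by $E$).
* **Stress recovery**: Cauchy stresses are evaluated at Gauss points,
  extrapolated to nodes through the inverse of the Gauss-point shape
  matrix, and averaged across elements — globally and per material
  region, so that wall profiles at a wall–thrombus interface are not
  contaminated by averaging across the material jump. Raw Gauss values
  are kept alongside.

There is no randomness anywhere in assembly or solving; repeated runs
are bit-identical. The default sparse direct solve handles the largest
meshes used here (a few thousand unknowns) in well under a second.

## Geometry generators

All study geometries are generated programmatically:

* `make_tube_mesh()` — structured annular wall meshes (default 6
  elements through the thickness), optionally with a cosine longitudinal
  thickness modulation; `make_ring_mesh()` provides the plane-strain
  analogue with circumferential modulation.
* `aaa_profile()` + `make_aaa_mesh()` — an idealized curved axisymmetric
  aneurysm: height 130 mm, maximum outer diameter 50 mm at mid-height,
  uniform 1.5 mm wall, cylindrical ends (22 mm outer diameter by
  default). The bulge is a flat-topped super-Gaussian,
  $B(Z) = R_n + (R_{\max} - R_n)\, e^{-((Z - H/2)/28)^4}$, chosen as a
  smooth $C^1$ profile honoring those printed dimensions; the lumen
  follows a narrower, lower bump (amplitude 4 mm, width 24 mm) so the
  intraluminal thrombus fills the bulge — up to ~10 mm thick at
  mid-height, vanishing toward the ends. The thrombus is meshed where it
  is thicker than 0.3 mm (default 10 elements through its thickness, 3
  through the wall), node-conforming with the wall, with its end faces
  constrained longitudinally.
* `make_patient_like_profile()` — a seeded synthetic stand-in for an
  image-derived geometry: a 20 mm-radius luminal tube dilated by 1–6
  random smooth bumps, with a uniform 1.5 mm wall displaced outward.
  Same seed, same profile, bit-for-bit.

What the generators deliberately do **not** emulate: loss of
axisymmetry, local wall-thickness variation of real aneurysms (available
only as the idealized cosine modulation), anisotropy and heterogeneity
of the tissue, neck angulation, or iliac branching. Passing tests on
these geometries therefore demonstrate correctness of the mechanics and
the orderings among the three models — not image-pipeline fidelity.

## Comparison metrics

`percent_diff()` is the pointwise relative difference
$100(\sigma_i - \sigma_i^*)/\sigma_i^*$ against the reference field
(zero-reference points are masked and counted). `integrated_diff()`
integrates the difference over the normalized wall thickness and
normalizes by the reference integral. The integrand uses the *absolute*
difference by default so the metric is a norm; a `signed` flag is
provided because the signed variant lets symmetric over/under-shoots
cancel. `max_stress_diff()` compares profile maxima located
independently in each field.

`run_sweep()` drives the analytic three-model tube pipeline over grids
of reference-material coefficients and initial geometries. The
physiological band of $\alpha$ attached to sweep tables
(0.0145–0.204 N/mm²) is the range spanned by the built-in tissue fits.
`mpr_experiment()` runs the thrombus-bearing curved aneurysm through the
FE pipeline at chosen wall-to-thrombus stiffness ratios.

## Numerical and design choices, in brief

* Root-finds: bracketed `uniroot` everywhere, tolerance 1e-12 (radii in
  mm); integrands via adaptive `integrate` at 1e-12 relative.
* Degenerate inputs: zero pressure short-circuits to the exact identity
  state; opening angle 0 means factor $k = 1$ and zero residual stress;
  profiles with fewer than two nodes, inverted elements, unconstrained
  meshes, and thrombus requests without a lumen are rejected with
  specific errors.
* The deformed inner radius of a conventional tube solve is reported
  from the exact incompressible root-find. Nearly-incompressible FE
  discretizations of the same problem give an outer radius a fraction of
  a percent away from the area-preserving value; agreement should be
  judged on the inner radius.
* Problem sizes: the test suite and the acceptance script use 201-node
  analytic profiles, tube meshes up to 6×20 elements, and a curved
  aneurysm + thrombus mesh of 360 elements (3 wall and 10 thrombus
  elements through the respective thicknesses, 40 axial stations) —
  sizes at which the tube benchmarks sit within 1% of closed forms and
  the matched-ratio experiment is mesh-converged to a few tenths of a
  percent.

## Known limitations

The matched-stiffness-ratio thrombus experiment deserves a caveat. With
the default geometry, the linear model reproduces reference wall
effective stresses at the maximum-diameter section to within about 7%
(the conventional model errs by ~26% on the same setup). The exact
figure is sensitive to how much load the thrombus carries — i.e. to the
lumen profile — and to the gap between the *tangent* stiffness ratio of
wall and thrombus at the operating strain and the coefficient ratio
$\alpha/D_1$ used to match the linear model: a strain-stiffening wall
pulls the instantaneous ratio above the coefficient ratio, so the
matched linear model slightly under-stresses the wall. Thinner or
softer thrombus geometries give smaller differences.

Beyond that: residual stresses are available for circular sections only
(the open-sector construction has no patient-specific analogue); axial
pre-stretch, anisotropy, damage and viscoelasticity are out of scope;
the FE core is 2D (axisymmetric/plane-strain) by design; and the linear
model, by construction, cannot describe deformations over the cardiac
cycle — only equilibrium stresses on a given imaged state.
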