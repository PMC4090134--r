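# aaastress

Wall-stress computation for abdominal aortic aneurysms (AAAs), built
around a **linear-equilibrium** approach and the nonlinear models it is
benchmarked against.

## The problem

An AAA is a pathological dilation of the abdominal aorta; wall stress is
a candidate predictor of rupture risk. Computing it from CT-derived
geometries is hard because (i) the imaged geometry is the *pressurized*
configuration — the unloaded shape is unknown — and (ii) aneurysm wall
tissue is strongly nonlinear, making finite-element solves expensive and
fragile. The common ("conventional") practice of inflating the imaged
geometry as if it were unloaded over-expands the vessel and distorts the
stresses.

The linear-equilibrium alternative solves a linear-elastic,
infinitesimal-displacement problem directly on the imaged geometry with
an arbitrary large Young's modulus: displacements are negligible, the
pressure boundary condition is satisfied on the imaged geometry itself,
and the resulting equilibrium stresses are independent of the modulus
chosen. This package implements that approach together with the
reference and conventional nonlinear models needed to quantify its
accuracy, for researchers in vascular biomechanics.

## What is inside

* **Materials** — isotropic incompressible hyperelastic wall energies
  `W(I_B) = α(I_B−3) + β(I_B−3)² + γ(I_B−3)³ + ζ(I_B−3)⁴ + η(I_B−3)⁵`
  with the published population-average (`RV`) and patient-sample
  (`P1`, `P2`) coefficient sets built in; intraluminal thrombus
  `W = D₁(II_B−3) + D₂(II_B−3)²`; linear elasticity.
* **Analytic tube solvers** — incompressible hyperelastic inflation of a
  thick-wall tube (root-find on the traction-free outer radius plus the
  equilibrium ODE) and the Lamé plane-strain solution; von Mises
  effective stress; the equilibrium integral `∫σ_θθ dr = p·a` as a
  built-in diagnostic.
* **Residual stress** — semi-analytic opening-angle model: residual
  stress in a closed ring, loaded states on top of it, and the angle
  that uniformizes the loaded through-wall stress.
* **FE core** — axisymmetric / plane-strain 9-node quadrilaterals with
  mixed displacement/pressure ("9/3") treatment, full-Newton incremental
  loading, follower pressure, and two-material (wall + thrombus)
  domains.
* **Geometry generators** — tubes, variable-thickness tubes and rings,
  an idealized curved axisymmetric aneurysm (130 mm height, 50 mm max
  diameter, 1.5 mm wall) with optional thrombus, and seeded synthetic
  patient-like profiles. VTK/`.inp` mesh I/O.
* **Comparison workflows** — pointwise and thickness-integrated percent
  stress differences, material/geometry sweeps, and wall-to-thrombus
  stiffness-ratio (MPR) experiments.

## Worked example

Compare the three models on an imaged tube of inner/outer radii
14.8/16.1 mm at systolic pressure:

```r
library(aaastress)

rv   <- builtin_materials("RV")        # population-average wall
geom <- tube_geometry(14.8, 16.1)      # imaged radii, mm
p    <- mmHg_to_MPa(120)               # 0.016 N/mm^2

lin  <- solve_linear_tube(geom, p)     # linear model: geometry unchanged
conv <- solve_nonlinear_tube(geom, rv, p)  # conventional: treats imaged
                                           # geometry as unloaded
lin
#> Tube stress profile (linear model, linear): a=14.8 mm, b=16.1 mm, p=0.016 N/mm^2, 201 nodes
#>   sigma_tt: 0.1745 .. 0.1905 N/mm^2; max sigma_eff 0.1788 N/mm^2
conv$profile
#> Tube stress profile (nonlinear model, RV): a=16.36 mm, b=17.55 mm, p=0.016 N/mm^2, 201 nodes
#>   sigma_tt: 0.198 .. 0.248 N/mm^2; max sigma_eff 0.229 N/mm^2

unlist(equilibrium_integral(lin))[1:2]
#>  integral p_times_a
#> 0.2367799 0.2367799
unlist(equilibrium_integral(conv$profile))[1:2]
#>  integral p_times_a
#> 0.2618007 0.2618006
```

Reading the output: the linear model keeps the imaged geometry
(a = 14.8 mm) and its through-wall stress integral equals `p·a`
(≈ 0.237 N/mm) — equilibrium holds on the imaged configuration. The
conventional model inflates the same geometry to a = 16.36 mm, so its
stress integral (≈ 0.262 N/mm) and peak effective stress
(0.229 vs 0.179 N/mm², +28%) are equilibrium values for the *wrong*,
over-expanded configuration. Against a reference model whose unloaded
state is known, the linear stresses are the closer approximation —
`run_sweep()` quantifies this over material/geometry grids, and
`mpr_experiment()` does the same on the curved aneurysm with thrombus.

The displacements behind the linear model are genuinely negligible:

```r
max(abs(linear_tube_displacement(geom, linear_material(8.4e9), p)$u_r))
#> [1] 2.728671e-10   # mm
```

## Command line

A thin CLI over the same functions is installed with the package:

```sh
Rscript inst/cli/aaastress tube-solve --model linear --A 14.8 --B 16.1 --p 120 --units mmHg
Rscript inst/cli/aaastress residual --material RV --b0 30 --thickness 1.5 --phi-list 0,30,60 --p 0.016
Rscript inst/cli/aaastress make-geom aaa --with-thrombus --out-dir meshes
```
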