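Package: aaastress
Title: Linear-Equilibrium and Nonlinear Wall-Stress Computation for
    Abdominal Aortic Aneurysms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes abdominal aortic aneurysm (AAA) wall stresses with a
    linear-equilibrium approach and benchmarks it against conventional
    nonlinear models. Provides closed-form hyperelastic and Lame thick-wall
    tube solvers, an opening-angle residual-stress solver, a compact mixed
    displacement/pressure finite-element core for axisymmetric and
    plane-strain geometries with optional intraluminal thrombus,
    deterministic geometry generators for idealized and synthetic
    patient-like aneurysm profiles, and stress-difference comparison
    workflows including material/geometry sweeps and wall-to-thrombus
    stiffness-ratio experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
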