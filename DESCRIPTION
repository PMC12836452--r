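Package: sleevesim
Title: Finite-Element Mechanics of Passive Epicardial Sleeves on an Idealized Left Ventricle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quasi-static nonlinear finite-element simulation of an idealized
    spheroidal left ventricle with a Fung-type transversely isotropic passive
    myocardium, Frank-Starling-modulated active contraction, and passive
    epicardial support sleeves.  Includes a structured quadratic-tetrahedral
    mesh generator for the truncated spheroidal wall, infarct and rule-based
    myofiber assignment, generators for continuum and auxetic (rotating
    triangle, negative Poisson ratio) sleeve lattices with barycentric mapping
    onto the epicardium, a pressure-driven cardiac-cycle solver with follower
    loads, and organ-level (EDV/SV/EF), regional fiber-strain, torsion and
    infarct-bulging metrics, together with synthetic pressure and activation
    waveforms and named myocardial-infarction scenarios.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
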