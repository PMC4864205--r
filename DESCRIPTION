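Package: hemolbm
Title: Lattice Boltzmann Simulation of Laminar Blood Flow in Bifurcation
    Aneurysms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-dimensional D3Q19 lattice Boltzmann solver for laminar
    arterial blood flow in bifurcation-aneurysm geometries. Provides four
    interchangeable collision operators (BGK, incompressible BGK, regularized
    BGK, and multiple-relaxation-time), halfway bounce-back walls, parabolic
    velocity inlets and pressure outlets, Shan-Chen pseudopotential multiphase
    forcing, bidirectional physical/lattice unit conversion, parametric
    bifurcation-aneurysm geometry generation and STL voxelization, and
    hemodynamic post-processing: pressure, velocity probes and plane slices,
    wall shear stress from the non-equilibrium stress tensor, and wall shear
    stress distribution statistics.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
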