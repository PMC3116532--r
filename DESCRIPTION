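Package: mdmdfit
Title: Maxwell's-Demon Molecular Dynamics Flexible Fitting of Structures into Density Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Flexible fitting of atomic models into three-dimensional density
    maps by Maxwell's-demon molecular dynamics (MdMD): short stochastic
    simulation "sprints" are accepted only when they raise a global progress
    variable, by default the cross-correlation between a simulated density
    synthesized from the model and a target (e.g. cryo-EM) map. Includes
    Gaussian-kernel density synthesis with exact per-voxel integrals,
    MRC/CCP4 map input/output, coarse-grained elastic-network and hinge
    Monte-Carlo propagators with harmonic tether restraints, and tRNA
    geometry analyses (interarm angle, per-residue fluctuation, trajectory
    docking, contact maps) together with a synthetic pseudo-tRNA benchmark
    generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
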