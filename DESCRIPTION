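Package: hdxcalib
Title: Structure-to-Reactivity Calibration for In-Droplet Hydrogen/Deuterium Exchange
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for relating peptide hydrogen/deuterium exchange (HDX)
    measured by mass spectrometry to conformational ensembles from molecular
    dynamics (MD) simulations.  The package enumerates exchangeable hydrogen
    sites and sequence-dependent intrinsic exchange rates, derives deuterium
    uptake from isotopic envelopes with internal-standard scaling, decomposes
    uptake into side-chain and backbone contributions by nonnegative least
    squares, classifies per-residue open/closed states in MD trajectories from
    amide-hydrogen solvent accessibility and hydrogen bonding, converts state
    populations into protection factors and theoretical backbone exchange
    (digital and combined kinetic models), and fits the calibration
    regressions that relate theory to experiment.  A synthetic-data module
    generates trajectories, isotopic envelopes and amino-acid-standard series
    with construction-known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
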