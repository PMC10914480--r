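Package: idrflex
Title: Conformational Ensemble Analysis of Phosphorylated Disordered Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for conformational ensembles of intrinsically
    disordered protein regions under phosphorylation, built around the
    N-terminal, Linker 1 and Linker 2 regions of the splicing regulators
    PTBP1 and PTBP2. Provides integer net-charge and phosphorylation-density
    models (phosphoserine/phosphothreonine as -2e), a coarse-grained
    charged-chain Monte Carlo sampler with temperature replica exchange and
    Debye-Hueckel screened electrostatics, multi-model PDB ensemble input and
    output, radius-of-gyration and end-to-end-distance observables with
    cross-replica standard errors and a convergence rule, salt-bridge
    fractional occupancy maps on charge-site atoms, and per-residue
    secondary-structure fraction and difference maps from a Kabsch-Sander
    hydrogen-bond assignment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
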