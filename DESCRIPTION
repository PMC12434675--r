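Package: taufield
Title: Analysis of Tau Cross-Beta Filament Degradation Under Oscillating Electric Fields
Version: 0.1.0
Authors@R:
    person("Taufield", "Developers", email = "taufield@example.org", role = c("aut", "cre"))
Description: Tools to quantify the structural degradation of tau amyloid
    filament cores (paired helical filament and straight filament topologies)
    in molecular simulation trajectories: Kabsch-Sander (DSSP) secondary
    structure assignment and beta-strand content time series, three classes of
    C-alpha contact survival (intrapeptide, interpeptide, interprotofilament),
    central-chain-anchored root-mean-square fluctuations, beta-sheet twist
    dihedrals, Shrake-Rupley solvent-accessible surface and protofilament
    interface area, and one/two-phase exponential decay kinetics with
    slow-phase half-lives. Includes a synthetic-data stage: an idealized
    cross-beta decamer builder and a charged elastic-network Brownian-dynamics
    simulator driven by an oscillating external electric field, so the whole
    pipeline is testable without microsecond-scale all-atom trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
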