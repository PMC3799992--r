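Package: bfmsim
Title: Bond-Fluctuation Monte Carlo Simulation of Proteins in an Effective Solvent
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse- and fine-grained lattice Monte Carlo simulation of a
    protein chain in an effective solvent medium. Residues are nodes of a
    bond-fluctuation chain on a cubic lattice; residue-residue couplings come
    from the Miyazawa-Jernigan knowledge-based contact matrix and
    residue-solvent couplings from a hydropathy scale multiplied by a solvent
    strength parameter. Metropolis kinetics with incremental energy updates,
    plus the full observable suite: per-residue energy and mobility profiles,
    radius of gyration, center-of-mass displacement, spherically averaged
    structure factor and effective-dimension (power-law) fits, solvent-strength
    scans, and two- and three-node-per-residue fine-grain representations.
    Ships the 136-residue human histone H3.1 sequence as the reference input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
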