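Package: famedew
Title: Hydration-Shell, Dewetting and Conformational Analysis of Lipidated Elastin-Like Polypeptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-chain trajectory analysis for fatty-acid-modified
    elastin-like polypeptides (FAMEs): first-hydration-shell water counts
    (N_w) and intrachain residue contacts (N_pp) with a periodic-aware
    cell-list neighbor search, a residue-level dewetting-temperature
    hydropathy scale built from restrained annealing series, Ramachandran
    classification of backbone dihedrals, length-normalized temperature
    trend fits with 90 percent confidence intervals, and amphiphile
    composition metrics (hydrophilic mass fraction). Includes synthetic
    coordinate generators that emulate the statistical structure of the
    analysis inputs, so every stage is testable without molecular dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
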