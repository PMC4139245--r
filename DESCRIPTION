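Package: hexshell
Title: Interface, Symmetry and Nanotube Geometry of Bacterial
    Microcompartment Shell-Protein Hexamers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing how hexameric bacterial microcompartment
    (BMC) shell proteins such as PduA tile into sheets and roll into
    nanotubes. Implements a deterministic Shrake-Rupley solvent-accessible
    surface area engine with per-residue burial (delta-ASA) and buried
    interface area accounting, interface hot-spot ranking with dyad
    proximity, cyclic-symmetry axis fitting and symmetry-deviation scoring,
    hexagonal sheet construction and tiling-dimensionality classification,
    ring-stack and multi-start helical nanotube builders with clash and
    contact validation, pore-axis profiling with probe-fit tests,
    geometric hydrogen-bond detection and interface comparison, alignment
    column conservation mapping, and a coarse-grained synthetic hexamer
    generator so the whole pipeline is testable without external
    structures. Includes fixed-column PDB and crystal-cell (CRYST1) input
    and output with lattice-translation expansion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d
Config/testthat/edition: 3
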