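Package: sasar
Title: Solvent Accessible Surface Area of Biomolecular Structures
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes the solvent accessible surface area (SASA) of
    proteins and nucleic acids from PDB coordinates using either the
    Lee & Richards slicing approximation or the Shrake & Rupley
    test-point approximation. Atomic radii are assigned from the ProtOr
    group-radius set with van der Waals element fallback, and custom
    radius and polarity configurations can be supplied.  Results can be
    aggregated by polarity class, chain, residue and residue type,
    queried with a Pymol-style atom selection syntax, recomputed for
    chain groups in isolation, and written back to PDB with per-atom
    areas in the temperature-factor column.  A command-line interface
    mirroring classic SASA tools is included.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
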