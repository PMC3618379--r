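Package: nmrvalid
Title: Validation of NMR Structure Ensembles Against Experimental Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Validates multi-model NMR structure ensembles against their
    experimental data. Quantifies ensemble precision with a circular
    dihedral order parameter, clusters models by pairwise backbone RMSD
    and selects medoid representatives, checks NOE distance restraints
    (with r^-6 sum averaging over ambiguous assignments) and dihedral
    restraints for violations, fits one Saupe alignment tensor per model
    and alignment medium from residual dipolar couplings (reporting Da,
    rhombicity, RMSD, Pearson R and Cornilescu Q), re-references chemical
    shifts per nucleus class and flags Z-score outliers against an
    environment-conditioned reference table, and rolls everything up into
    per-residue red/orange/green scores emitted as a machine-readable
    JSON report. A deterministic synthetic-fixture generator produces toy
    ensembles with known ground truth for testing and demonstration.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
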