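Package: gtmdock
Title: Generative Topographic Mapping of Protein-Ligand Docking Conformational Space
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps the conformational space of protein-ligand docking problems
    with Generative Topographic Mapping (GTM) of site-anchored fuzzy Contact
    Fingerprints (CF) and Hybrid (CF plus circular-fragment) descriptor
    vectors.  Provides key-atom selection from per-atom solvent accessibility,
    fuzzy contact descriptors over direct and long-range distance bands, a
    from-scratch GTM (EM fit, responsibilities, regression and fuzzy-class
    property landscapes with cross-validated Q2 and evolutionary
    hyperparameter selection), docking-specific analyses (run-reproducibility
    index IRI, explorer-based RMSD cross-prediction with Q/R/M/F verdicts,
    native-pose ranking ROC), Boltzmann-weighted averaged-responsibility (AR)
    vectors for virtual-screening ranking, pose-pool bookkeeping (energy
    window, diverse-subset selection, energy convergence criterion, capped
    RMSD, docking score), synthetic fixture generators for the whole
    pipeline, and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    ChemmineR,
    pROC,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
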