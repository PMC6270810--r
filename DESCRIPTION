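Package: comfar
Title: Comparative Molecular Field Analysis (CoMFA) 3D-QSAR Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A self-contained pipeline for grid-based 3D-QSAR modeling in the
    style of Comparative Molecular Field Analysis (CoMFA). Provides molecule
    input/output (SDF V2000, MOL2), iterative partial-charge assignment by
    partial equalization of orbital electronegativity (PEOE), force-field
    energy evaluation with minimization and torsional simulated annealing,
    rigid least-squares scaffold superposition, steric (Lennard-Jones) and
    electrostatic (Coulomb) probe fields on a rectangular lattice, partial
    least squares (PLS) regression with leave-one-out cross-validation and
    component-number scanning, external-validation statistics (PRESS, SD,
    predictive r-squared), StDev*Coeff contour maps with OpenDX export, and a
    synthetic-data generator with known field-to-activity ground truth for
    end-to-end validation. Ships a transcription of a published cannabinoid
    CB1/CB2 aminoalkylindole affinity data set as a worked fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
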