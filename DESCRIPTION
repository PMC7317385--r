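Package: chargekit
Title: Atomic Partial Charge Schemes and Principal Components of Ionicity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes families of atomic partial charges from common electron
    density and wavefunction representations: Mulliken, Loewdin and Bickelhaupt
    populations with minimal-basis projection (MBS-Mulliken, MBS-Bickelhaupt),
    the Hirshfeld stockholder family (Hirshfeld, iterative Hirshfeld, ISA, MBIS),
    grid-based Bader/QTAIM basins and Voronoi deformation densities,
    electrostatic-potential fitted charges with CHELPG-style point selection,
    and the empirical CM5 and electronegativity-equalization (EEQ) models.
    Includes Becke-style molecular quadrature, Slater-type proatom databases,
    readers and writers for XYZ, Gaussian cube, CSV and spreadsheet charge
    tables, deterministic synthetic fixtures with closed-form oracles, and a
    meta-analysis engine that extracts principal components of ionicity from
    per-atom charge tables (blocked correlations, PCA, backward elimination,
    GCD subset selection, regression fits, noise robustness).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    readxl,
    withr,
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
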