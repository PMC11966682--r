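Package: eprmix
Title: Multi-Species Simulation and Decomposition of Field-Swept EPR
    Spectra of Iron-Sulfur Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for resolving coexisting paramagnetic species of
    reduced [4Fe4S] clusters from field-swept electron paramagnetic
    resonance (EPR) spectra. Simulates anisotropic S = 1/2 powder
    patterns with g-strain broadening at arbitrary microwave frequency,
    converts echo-detected absorption spectra to derivative-like
    lineshapes by pseudo-modulation, decomposes composite spectra into
    axial and rhombic components by non-negative least squares with
    optional bounded refinement of g-values (variable projection),
    links species fractions to applied potential (Nernst) and pH
    (Hill/Henderson-Hasselbalch) and fits midpoint potentials and pKa
    values, enumerates and classifies valence isomers of a cubane
    cluster from broken-symmetry spin populations, and generates fully
    reproducible synthetic datasets with known ground truth. Reads and
    writes two-column ASCII spectra and Bruker BES3T (DSC/DTA) files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
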