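Package: saxstruct
Title: Structural Inference from SEC-SAXS Data for Flexible Multi-Domain Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning size-exclusion-chromatography-coupled
    small-angle X-ray scattering (SEC-SAXS) measurements into low-resolution
    structural models of flexible multi-domain proteins. Covers frame
    selection and buffer subtraction for SEC-SAXS series, Guinier analysis,
    regularized indirect Fourier transform to the pair distance distribution
    P(r) with automatic Dmax search, Porod-volume molecular weight
    estimation, ab initio dummy-atom envelope reconstruction by simulated
    annealing with normalized-spatial-discrepancy superposition and
    multi-model averaging, Debye-formula scattering profiles from atomic or
    bead models with chi-square fitting, envelope-restrained flexible
    fitting of C-alpha models, and a backbone dihedral descriptor (protein
    angular value) with PCA and hierarchical clustering for model-ensemble
    comparison. A synthetic-data module generates toy multi-domain
    structures, simulated curves, and SEC-SAXS frame series with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
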