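Package: pymbms
Title: Cell-Wall Phenotyping from Pyrolysis Molecular Beam Mass Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: High-throughput chemometric phenotyping of lignocellulosic
    biomass cell walls from pyrolysis molecular beam mass spectrometry
    (py-MBMS) spectra. Provides spectrum normalization and replicate
    handling, diagnostic-ion estimators for lignin content and the
    syringyl/guaiacyl (S/G) ratio, reduced-ion single-point sugar
    estimates, NIPALS partial least squares (PLS1) calibration of glucose
    and xylose content against reference compositions, principal component
    and per-ion correlation diagnostics, thin-plate-spline correction of
    field microspatial trends, and broad-sense heritability from clonally
    replicated pedigree trials. A synthetic-data module simulates
    compositions, spectra, reference measurements and factorial pedigree
    field trials with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    MASS,
    mgcv,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
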