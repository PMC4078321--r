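Package: thyrodose
Title: Cellular S Values for Radioiodine in Thyroid Follicle Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte Carlo microdosimetry of the radioiodine isotopes I-123, I-125
    and I-131 in species-specific thyroid follicle models (mouse, rat, man).
    Computes cellular S values (mean absorbed dose to follicle-cell nuclei per
    decay) for homogeneous and heterogeneous activity distributions in single-
    and multiple-follicle nested-sphere geometries, using curated non-radiative
    electron emission spectra (Auger/Coster-Kronig, internal conversion, beta)
    and straight-track continuous-slowing-down (CSDA) electron transport in
    unit-density water with a Cole-type range-energy relation. Includes the
    MIRD mean-absorbed-dose formalism for comparison, deterministic quadrature
    oracles, and reproducible experiment pipelines for S-value tables, lumen
    diameter sweeps, concentric-shell source scans and layer-contribution
    decompositions.
License: GPL (>= 3)
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
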