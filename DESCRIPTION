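Package: plaquesim
Title: Patient-Specific Simulation of Atherosclerotic Plaque Progression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A multi-physical continuum model of the atherosclerotic plaque
    microenvironment on a labeled 2D vessel cross-section. Twelve coupled
    reaction-diffusion fields (LDL, ox-LDL, MCP-1, monocytes, macrophages,
    foam cells, smooth muscle cells, ECM, MMP, endothelial cells, VEGF and
    extravascular plasma) are advanced by an explicit Euler finite-difference
    scheme on a masked grid, with wall-shear-stress-modulated endothelial
    influx of LDL and monocytes, chemotaxis and haptotaxis in conservative
    flux form, and zero-flux closure at the external elastic membrane. The
    package provides a calibrate-then-predict workflow that selects initial
    inflammation and microvessel levels against observed necrotic-core growth
    at follow-up, necrotic-core and plaque-burden analytics, a multi-factor
    severity scoring scale with plaque-fate classification, cohort statistics
    (Welch t-tests and Spearman correlations), and a fully synthetic
    four-patient cohort generator for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    png,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
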