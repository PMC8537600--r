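Package: lspcyto
Title: Label-Free Single-Cell Phenotyping from Angular Light-Scattering Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Forward simulation and look-up-table inversion of angular
    light-scattering profiles of single cells modelled as concentric
    two-layer (nucleus and cytosol) spheres, following the Aden-Kerker
    extension of Mie theory.  Recovers four biophysical properties per
    cell (diameter, cytosol and nucleus refractive index, nucleus-to-cell
    diameter ratio), evaluates the viscoelastic microfluidic centreline
    alignment criterion, classifies cells into six blood-borne types with
    a quadratic support-vector machine, and enumerates circulating tumour
    cells per sample.  Includes a synthetic-data generator for
    class-conditional cell populations and an end-to-end pipeline from
    diffraction image or profile to per-sample report.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    e1071,
    class,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    png
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
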