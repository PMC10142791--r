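Package: prokmorph
Title: Morphometry and Morphotype Analysis of Marine Prokaryoplankton
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to reproduce an epifluorescence-microscopy morphometric
    survey of marine prokaryoplankton on fully synthetic data. Generates
    cell populations from per-cruise, per-morphotype length/width
    distributions, renders DAPI-like micrographs with ground truth,
    segments and measures cells (skeleton length, medial-axis width,
    centerline curvature), applies the operational morphotype
    classification rules (cocci, coccobacilli, rods, curved rods, vibrios,
    spirillae, filamentous), derives biovolume, cell carbon content and
    biomass, and computes community statistics (size-class spectra,
    morphological index, Shannon diversity, Kruskal-Wallis contrasts and
    PCA ordination against environmental covariates).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    vegan,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
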