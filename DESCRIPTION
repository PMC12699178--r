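Package: ubmorph
Title: 3D Morphometrics, Statistics and Traction Cytometry for Branching
    Epithelial Tips
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reusable pipeline for quantifying epithelial cell shape in
    three-dimensional images of branching tubular organs such as the
    embryonic kidney ureteric bud.  Reconstructs individual cells from
    membrane-staining probability maps by anisotropy-aware
    marker-controlled watershed, extracts ellipsoid-moment shape
    descriptors (volume, roundness, elongation, ellipticity, principal
    axes), clusters cells and maps selected subgroups back into the
    source volume, embeds feature matrices in two dimensions (PCA, UMAP),
    and runs the accompanying nonparametric stage statistics
    (Kruskal-Wallis with Conover-Iman post hoc, pairwise Levene and
    Mann-Whitney tests, distribution summaries).  Also provides 2D
    nuclear-contour shape descriptors for nuclear-envelope wrinkling,
    Fourier-transform traction cytometry (forward Boussinesq model,
    regularized inversion, RMS traction, doublet intercellular force,
    delamination speed), and a synthetic-tissue generator with known
    ground truth so every stage is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    tiff,
    jsonlite,
    e1071,
    uwot,
    digest
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
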