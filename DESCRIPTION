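Package: fiberDV
Title: Collagen Fiber Density and Directional Variance Mapping for H&E Histology
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Characterizes scar and normal dermis in hematoxylin-and-eosin
    stained histology images. Pixels are clustered in CIE L*a*b* chromaticity
    (a*, b*) with K-means into collagen, foreground (nuclei, glands, hair
    follicles) and background; the collagen mask is convolved with an
    airy-disk kernel to give a local fiber density map; pixel-wise axial fiber
    orientation is estimated by directional line sampling and reduced, through
    doubled-angle vector summation, to a directional variance map
    V = 1 - R/m in [0, 1] (0 = perfectly aligned, 1 = isotropic). Includes a
    synthetic H&E dermis generator with per-pixel ground truth, rotation
    augmentation and dataset-split utilities, ROI metrics (FS, CAS, CDM, DV
    percentages), two-group and multi-group comparisons, and a command-line
    front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    methods,
    png,
    tiff,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
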