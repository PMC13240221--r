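Package: myomorph
Title: Muscle Fiber and Endomysium Histomorphometry with Synthetic Ground Truth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Stereological quantification of muscle fiber cross-sectional area
    and endomysial connective tissue from segmented cross-section images of
    skeletal muscle. Generates ground-truthed synthetic fiber mosaics
    (perturbed-lattice Voronoi tessellations rendered as basement-membrane
    boundary stains or connective-tissue fill stains), segments both staining
    modalities, computes corrected fiber counts, mean fiber area, total
    endomysium area, and mean endomysium thickness, applies myopathological
    classification rules to fiber populations and cohort tables, runs
    normality-gated two-group comparisons and Bland-Altman method agreement,
    and screens protein abundance matrices with valid-value filtering,
    left-shifted imputation, permutation-based FDR ANOVA, and a
    detection-pattern presence/absence screen.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    igraph,
    jsonlite,
    stats,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
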