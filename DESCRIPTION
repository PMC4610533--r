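Package: leukoSeg
Title: White Blood Cell Segmentation in Stained Blood Smears
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Segmentation of white blood cells (leukocytes) in RGB
    micrographs of Wright-stained peripheral-blood and bone-marrow smears.
    The method combines illumination-invariant rg-chromaticity enhancement
    to extract nucleus seeds, mean-shift filtering of the CMYK cyan channel
    with a nucleus-area-anchored adaptive threshold to extract whole-cell
    regions, and a nucleus-marked watershed with an adaptive second
    splitting pass to separate adhesive (overlapping) cells. Includes a
    synthetic smear generator with pixel-exact ground truth and an
    evaluation module based on region matching, over/under-segmentation
    counting and the F-measure.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, EBImage, Rcpp, yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'color.R'
    'eval.R'
    'io.R'
    'leukoSeg-package.R'
    'methods.R'
    'morphology.R'
    'nmwo.R'
    'params.R'
    'pipeline.R'
    'seeds.R'
    'synth.R'
    'wbcRegion.R'
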