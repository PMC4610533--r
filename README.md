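# leukoSeg

Segmentation of white blood cells (leukocytes) in RGB micrographs of
Wright-stained peripheral-blood and bone-marrow smears, for hematology
image-analysis pipelines that need per-cell masks before counting or
classification.

The stain makes the problem a color problem with a geometry problem on
top: nuclei are dark purple, cytoplasm lilac, red cells reddish, the
background pale — but illumination varies between microscopes, leukemic
marrow cells have weak nucleus/cytoplasm contrast, and cells adhere into
clumps. leukoSeg implements a four-phase seed-driven pipeline:

1. **Nucleus seeds.** Illumination cancels in channel ratios: with
   chromaticities r = R/(R+G+B), g = G/(R+G+B), b = 1 − r − g and HSI
   saturation S = 1 − 3·min(R,G,B)/(R+G+B), the enhancement
   I_E = I_s / I_g (byte-normalized S over g) is large exactly on nuclei.
   Otsu's threshold, a scene-independent stain floor S/g > 1, and a
   centroid-connected operation that merges the lobes of segmented
   neutrophil nuclei yield one seed per cell.
2. **Cell regions.** The CMYK cyan channel, smoothed by mean-shift
   filtering in (x, y, intensity) space (flat kernel, bandwidths
   h_s = h_r = 3), and the b/g chromaticity enhancement are each cut by
   an adaptive threshold anchored on the nucleus area: assuming cell
   area = N × nucleus area (N = 3 peripheral, 1.5 marrow), the smallest
   gray level whose cumulative histogram reaches
   S_image − N·S_nucleus separates background from cells. The two masks
   are unioned, denoised and hole-filled.
3. **Adhesion separation.** Components flagged adhesive — by area/
   roundness bounds, by holding several nucleus seeds, or by a merged
   (dumbbell-shaped) nucleus seed — are split by marker-controlled
   watershed flooded from the nucleus groups over the negated distance
   transform, with a second adaptive pass (corrosion of the merged seed,
   local-extremum regions, or region corrosion) for basins the first
   pass could not separate.
4. **Post-processing.** Nuclei inherit cell labels through a logical AND;
   components without a nucleus are removed as impurities; per-cell
   region features (chain-code perimeter, roundness = P²/4πA, …) are
   reported.

A synthetic smear generator (`makeSmear`) with pixel-exact ground truth
and an evaluation module (region matching at IoU, TP/FP/FN with over- and
under-segmentation counts, F-measure) make the whole pipeline testable
without any image download.

## Worked example

```r
library(leukoSeg)

scene  <- makeSmear(imageSize = c(300, 400), nWbc = 4, nRbc = 50,
                    overlapFraction = 0.5, seed = 42)
params <- segmentationParams("peripheral", resizeFactor = 1)
result <- segmentImage(scene, params)
result
#> SegmentationResult: 4 white blood cell(s)
#>   provenance: single=2 split_pass1=2 split_pass2=0
#>   mean area: 2427.8  mean roundness: 1.16

evaluateSegmentation(result, scene)
#> EvalReport: TP=4 FP=0 FN=0 overseg=0 underseg=0
#>   P=100.0% R=100.0% F1=100.0%

head(regionTable(result))
#>   label area perimeter height width roundness       cx        cy
#> 1     1 2632  203.5391     52    64  1.252564 146.6391 137.65540
#> 2     2 2783  206.1249     54    64  1.214892 157.7147 185.02695
#> 3     3 1663  149.5391     46    46  1.070058 341.4546  59.61756
#> 4     4 2633  189.3381     62    54  1.083466 348.7641 263.82567
```

The scene contains two isolated cells and one overlapping pair placed at
`overlapFraction = 0.5`; the provenance line shows the pair was separated
by the first (nucleus-marked) watershed pass. All four cells match their
ground truth at IoU 0.5, giving F1 = 100%.

Real images enter through `readSmear()` (8-bit RGB PNG/TIFF/JPEG) and the
default `resizeFactor = 0.2` working scale; a thin command-line wrapper
with `segment`, `synth` and `eval` subcommands is installed at
`inst/scripts/wbcseg.R`.

## The methods vignette

`vignettes/leukocyte-segmentation.Rmd` documents the model phase by
phase: every parameter with its unit, default and provenance; the
numerical conventions (histogram binning, tie-breaks, winsorisation,
degenerate inputs); what the synthetic generator does and does not
emulate; and the known limitations of shape-based splitting.
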