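#' Parameters of the segmentation pipeline
#'
#' Every tunable of the four-phase leukocyte segmentation method, with the
#' defaults calibrated on Wright-stained smears at the 0.2x working
#' resolution. Area and distance parameters are in working-scale pixels.
#'
#' @slot smearType \code{"peripheral"} or \code{"marrow"}; selects the
#'   cell-to-nucleus area ratio (\code{areaRatio} 3 vs 1.5).
#' @slot minNucleusArea smallest retained nucleus component (default 100 px);
#'   removes platelets and stain debris from the nucleus mask.
#' @slot minCellArea smallest retained whole-cell component (default 350 px).
#' @slot centroidPad padding of the centroid-connection rectangle joining
#'   nucleus lobes (default 5 px).
#' @slot maxCoreGap largest boundary-to-boundary gap between two nucleus
#'   lobes that still belong to one segmented nucleus (default 55 px).
#' @slot coreAreaRange open interval of single-lobe areas, default
#'   \code{c(100, 950)} px; only components in this range take part in lobe
#'   pairing.
#' @slot adhesionMinArea area above which a component counts as an adhesive
#'   cell cluster (default 3500 px, just above the largest single cell).
#' @slot adhesionRoundness roundness (compactness, perimeter^2 / (4 pi area))
#'   beyond which a component counts as adhesive (default 3).
#' @slot adhesionRule \code{"either"} (default) flags a component when the
#'   area or the roundness criterion fires; \code{"both"} requires both.
#' @slot adhesionComparator direction of the roundness comparison,
#'   \code{"greater"} (default) or \code{"less"}.
#' @slot nucleusAdhesionRoundness roundness of a nucleus seed beyond which
#'   the nucleus itself is considered adhesive (merged nuclei of distinct
#'   cells), sending its cell region to the second splitting pass
#'   (default 1.4, between the compactness of a smoothed digitized disk,
#'   about 1.1, and of two overlapping disks, about 1.45 at deep overlap
#'   and 2 analytically at tangency).
#' @slot extremumRadius distance-transform level defining local-extremum
#'   marker regions in the second splitting pass (default 7 px).
#' @slot spatialBandwidth,rangeBandwidth mean-shift bandwidths hs (pixels,
#'   default 3) and hr (intensity units on the 0-255 scale, default 3).
#' @slot msIterations,msTolerance mean-shift iteration cap (default 4) and
#'   intensity convergence tolerance (default 0.5).
#' @slot areaRatio assumed whole-cell to nucleus area ratio N; 3 for
#'   peripheral blood, 1.5 for bone marrow.
#' @slot resizeFactor image down-scaling factor before processing
#'   (default 0.2, matching full-resolution 100x micrographs).
#' @slot iouMatch intersection-over-union above which a predicted cell
#'   counts as a correct segmentation (default 0.5).
#' @slot cmykNaive if \code{TRUE} the cyan channel is the naive
#'   \code{1 - R/255} instead of the key-extraction form.
#' @slot seRadius disk radius of the default structuring element (default 3).
#' @slot ratioClipQuantile quantile at which ratio-enhanced planes are
#'   winsorised before byte rescaling (default 0.995); prevents a handful of
#'   near-zero denominators from crushing the histogram.
#' @slot watershedSurface topographic relief for the marked watershed:
#'   \code{"dist_to_bg"} (negated distance to background, default) or
#'   \code{"dist_to_seed"} (distance to the nearest seed).
#' @seealso \code{\link{segmentationParams}}, \code{\link{segmentImage}}
#' @export
setClass("SegmentationParams", representation(
  smearType = "character",
  minNucleusArea = "numeric",
  minCellArea = "numeric",
  centroidPad = "numeric",
  maxCoreGap = "numeric",
  coreAreaRange = "numeric",
  adhesionMinArea = "numeric",
  adhesionRoundness = "numeric",
  adhesionRule = "character",
  adhesionComparator = "character",
  nucleusAdhesionRoundness = "numeric",
  extremumRadius = "numeric",
  spatialBandwidth = "numeric",
  rangeBandwidth = "numeric",
  msIterations = "numeric",
  msTolerance = "numeric",
  areaRatio = "numeric",
  resizeFactor = "numeric",
  iouMatch = "numeric",
  cmykNaive = "logical",
  seRadius = "numeric",
  ratioClipQuantile = "numeric",
  watershedSurface = "character"
))

setValidity("SegmentationParams", function(object) {
  msgs <- character()
  pos <- c(minNucleusArea = object@minNucleusArea,
           minCellArea = object@minCellArea,
           centroidPad = object@centroidPad,
           maxCoreGap = object@maxCoreGap,
           adhesionMinArea = object@adhesionMinArea,
           nucleusAdhesionRoundness = object@nucleusAdhesionRoundness,
           extremumRadius = object@extremumRadius,
           spatialBandwidth = object@spatialBandwidth,
           rangeBandwidth = object@rangeBandwidth,
           seRadius = object@seRadius)
  if (any(pos <= 0))
    msgs <- c(msgs, paste("must be > 0:",
                          paste(names(pos)[pos <= 0], collapse = ", ")))
  if (length(object@coreAreaRange) != 2 ||
      object@coreAreaRange[1] >= object@coreAreaRange[2])
    msgs <- c(msgs, "coreAreaRange must be an increasing pair")
  if (object@areaRatio <= 1)
    msgs <- c(msgs, "areaRatio must be > 1")
  if (object@resizeFactor <= 0 || object@resizeFactor > 1)
    msgs <- c(msgs, "resizeFactor must be in (0, 1]")
  if (!object@smearType %in% c("peripheral", "marrow"))
    msgs <- c(msgs, "smearType must be 'peripheral' or 'marrow'")
  if (!object@adhesionRule %in% c("either", "both"))
    msgs <- c(msgs, "adhesionRule must be 'either' or 'both'")
  if (!object@adhesionComparator %in% c("greater", "less"))
    msgs <- c(msgs, "adhesionComparator must be 'greater' or 'less'")
  if (!object@watershedSurface %in% c("dist_to_bg", "dist_to_seed"))
    msgs <- c(msgs, "watershedSurface must be 'dist_to_bg' or 'dist_to_seed'")
  if (object@iouMatch <= 0 || object@iouMatch > 1)
    msgs <- c(msgs, "iouMatch must be in (0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Nucleus and whole-cell seed masks
#'
#' Container for the Phase I / Phase II outputs: \code{nucleusRaw} is the
#' thresholded nucleus mask before lobe connection, \code{inside} the nucleus
#' groups after the centroid-connected operation (one component per cell),
#' and \code{outside} the whole-cell (WBC) region mask.
#'
#' @slot inside,outside,nucleusRaw integer 0/1 matrices of identical shape.
#' @export
setClass("SeedSet", representation(
  inside = "matrix", outside = "matrix", nucleusRaw = "matrix"))

setValidity("SeedSet", function(object) {
  ms <- list(object@inside, object@outside, object@nucleusRaw)
  ms <- ms[vapply(ms, function(m) length(m) > 0L, logical(1))]
  if (length(ms) > 1) {
    d <- vapply(ms, dim, integer(2))
    if (any(d[1, ] != d[1, 1]) || any(d[2, ] != d[2, 1]))
      return("populated masks must share one shape")
  }
  for (m in ms)
    if (any(!m %in% c(0, 1))) return("masks must be strictly binary")
  TRUE
})

#' Final segmentation of one smear image
#'
#' @slot wbcLabels integer label matrix of the separated white blood cells
#'   (0 = background, labels consecutive).
#' @slot nucleusLabels integer label matrix of the nuclei, carrying the label
#'   of the cell each nucleus belongs to.
#' @slot props \code{data.frame} of per-cell region features
#'   (label, area, perimeter, height, width, roundness, cx, cy).
#' @slot provenance character vector, per label: \code{"single"} (untouched
#'   component), \code{"split_pass1"} (nucleus-marked watershed) or
#'   \code{"split_pass2"} (adaptive second pass).
#' @slot params the \linkS4class{SegmentationParams} used.
#' @export
setClass("SegmentationResult", representation(
  wbcLabels = "matrix", nucleusLabels = "matrix",
  props = "data.frame", provenance = "character",
  params = "SegmentationParams"))

setValidity("SegmentationResult", function(object) {
  if (!identical(dim(object@wbcLabels), dim(object@nucleusLabels)))
    return("label masks must share one shape")
  k <- max(0L, object@wbcLabels)
  if (k > 0 && !setequal(seq_len(k), setdiff(unique(as.vector(object@wbcLabels)), 0L)))
    return("labels must be consecutive 1..K")
  if (any(object@nucleusLabels != 0 & object@wbcLabels == 0))
    return("nucleus labels must be supported by cell labels")
  TRUE
})

#' Synthetic stained-smear scene with pixel-exact ground truth
#'
#' @slot image integer H x W x 3 array, values 0-255.
#' @slot wbcLabels,nucleusLabels ground-truth integer label matrices.
#' @slot cells \code{data.frame} of per-cell geometry
#'   (cell, cx, cy, radius, nucleusRadius, lobes, cluster).
#' @slot spec list of the generator arguments that produced the scene.
#' @export
setClass("SyntheticSmear", representation(
  image = "array", wbcLabels = "matrix", nucleusLabels = "matrix",
  cells = "data.frame", spec = "list"))

setValidity("SyntheticSmear", function(object) {
  if (length(dim(object@image)) != 3 || dim(object@image)[3] != 3)
    return("image must be H x W x 3")
  if (!identical(dim(object@image)[1:2], dim(object@wbcLabels)))
    return("ground truth must match the image shape")
  if (any(object@nucleusLabels != 0 & object@wbcLabels == 0))
    return("nucleus truth must lie inside cell truth")
  TRUE
})

#' Segmentation quality report
#'
#' Cell-level counting of segmentation outcomes: \code{tp} correct cells,
#' \code{fp} spurious predictions (red cells, debris), \code{fn} missed or
#' broken cells, plus over- and under-segmentation counts and the derived
#' precision, recall and F-measure (fractions in [0, 1]; the show method
#' prints percentages).
#'
#' @slot tp,fp,fn,overseg,underseg non-negative integer counts.
#' @slot precision,recall,f1 fractions in [0, 1].
#' @export
setClass("EvalReport", representation(
  tp = "integer", fp = "integer", fn = "integer",
  overseg = "integer", underseg = "integer",
  precision = "numeric", recall = "numeric", f1 = "numeric"))

setValidity("EvalReport", function(object) {
  cnt <- c(object@tp, object@fp, object@fn, object@overseg, object@underseg)
  if (any(cnt < 0)) return("counts must be non-negative")
  fr <- c(object@precision, object@recall, object@f1)
  if (any(fr < 0 | fr > 1)) return("rates must be in [0, 1]")
  TRUE
})
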