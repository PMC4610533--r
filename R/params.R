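#' Build a parameter set for the segmentation pipeline
#'
#' Returns the default parameters for the chosen smear type, with any field
#' overridden by name. The defaults are calibrated for images at the 0.2x
#' working resolution of 100x oil-immersion micrographs; if your input is
#' already at working scale set \code{resizeFactor = 1}.
#'
#' @param smearType \code{"peripheral"} (cell/nucleus area ratio N = 3) or
#'   \code{"marrow"} (N = 1.5).
#' @param ... named overrides of any \linkS4class{SegmentationParams} slot,
#'   e.g. \code{resizeFactor = 1} or \code{areaRatio = 2}.
#' @return A validated \linkS4class{SegmentationParams} object.
#' @examples
#' p <- segmentationParams("peripheral", resizeFactor = 1)
#' p@areaRatio   # 3
#' @export
segmentationParams <- function(smearType = c("peripheral", "marrow"), ...) {
  smearType <- match.arg(smearType)
  p <- new("SegmentationParams",
    smearType = smearType,
    minNucleusArea = 100,
    minCellArea = 350,
    centroidPad = 5,
    maxCoreGap = 55,
    coreAreaRange = c(100, 950),
    adhesionMinArea = 3500,
    adhesionRoundness = 3.00,
    adhesionRule = "either",
    adhesionComparator = "greater",
    nucleusAdhesionRoundness = 1.4,
    extremumRadius = 7,
    spatialBandwidth = 3,
    rangeBandwidth = 3,
    msIterations = 4,
    msTolerance = 0.5,
    areaRatio = if (smearType == "peripheral") 3 else 1.5,
    resizeFactor = 0.2,
    iouMatch = 0.5,
    cmykNaive = FALSE,
    seRadius = 3,
    ratioClipQuantile = 0.995,
    watershedSurface = "dist_to_bg")
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), slotNames("SegmentationParams"))
    if (length(bad))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    for (nm in names(dots)) slot(p, nm) <- dots[[nm]]
  }
  validObject(p)
  p
}

#' Read and write parameter files
#'
#' Parameters serialize to a flat YAML mapping, one key per slot, so a run
#' can be reproduced from its config file.
#'
#' @param params a \linkS4class{SegmentationParams} object.
#' @param path file path of the YAML config.
#' @return \code{readParams} returns a \linkS4class{SegmentationParams};
#'   \code{writeParams} invisibly returns \code{path}.
#' @export
writeParams <- function(params, path) {
  stopifnot(is(params, "SegmentationParams"))
  vals <- lapply(slotNames("SegmentationParams"), function(nm) slot(params, nm))
  names(vals) <- slotNames("SegmentationParams")
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' @rdname writeParams
#' @export
readParams <- function(path) {
  vals <- yaml::read_yaml(path)
  st <- if (is.null(vals$smearType)) "peripheral" else vals$smearType
  vals$smearType <- NULL
  do.call(segmentationParams, c(list(smearType = st), vals))
}

setMethod("show", "SegmentationParams", function(object) {
  cat("SegmentationParams (", object@smearType, " smear)\n", sep = "")
  cat("  area ratio N:", object@areaRatio,
      " resize:", object@resizeFactor, "\n")
  cat("  denoise areas S1/S2:", object@minNucleusArea, "/",
      object@minCellArea, "\n")
  cat("  lobe pairing: area in (", object@coreAreaRange[1], ",",
      object@coreAreaRange[2], "), gap <", object@maxCoreGap,
      ", pad", object@centroidPad, "\n")
  cat("  adhesion: area >", object@adhesionMinArea, object@adhesionRule,
      "roundness", object@adhesionComparator, object@adhesionRoundness, "\n")
  cat("  mean shift: hs", object@spatialBandwidth, "hr",
      object@rangeBandwidth, "iters", object@msIterations, "\n")
})
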