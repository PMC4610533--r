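#' @include AllClasses.R
NULL

#' Accessors for seed sets, segmentation results and synthetic smears
#'
#' \code{insideSeeds}, \code{outsideSeeds} and \code{nucleusMask} extract the
#' binary masks of a \linkS4class{SeedSet}. \code{wbcLabels} and
#' \code{nucleusLabels} extract the integer label masks of a
#' \linkS4class{SegmentationResult} or the ground-truth labels of a
#' \linkS4class{SyntheticSmear}. \code{regionTable} returns the per-cell
#' morphological feature table and \code{smearImage} the rendered RGB array.
#'
#' @param x the object.
#' @return A matrix (masks, labels), a \code{data.frame} (\code{regionTable},
#'   \code{cellRecords}) or an integer array (\code{smearImage}).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("insideSeeds", function(x) standardGeneric("insideSeeds"))

#' @rdname accessors
#' @export
setGeneric("outsideSeeds", function(x) standardGeneric("outsideSeeds"))

#' @rdname accessors
#' @export
setGeneric("nucleusMask", function(x) standardGeneric("nucleusMask"))

#' @rdname accessors
#' @export
setGeneric("wbcLabels", function(x) standardGeneric("wbcLabels"))

#' @rdname accessors
#' @export
setGeneric("nucleusLabels", function(x) standardGeneric("nucleusLabels"))

#' @rdname accessors
#' @export
setGeneric("regionTable", function(x) standardGeneric("regionTable"))

#' @rdname accessors
#' @export
setGeneric("smearImage", function(x) standardGeneric("smearImage"))

#' @rdname accessors
#' @export
setGeneric("cellRecords", function(x) standardGeneric("cellRecords"))

#' @rdname accessors
#' @export
setGeneric("metrics", function(x) standardGeneric("metrics"))
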