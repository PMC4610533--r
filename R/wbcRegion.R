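#' Mean-shift filtering of an intensity plane
#'
#' Each pixel's estimate moves through the joint (x, y, intensity) space
#' with a flat kernel: the next estimate is the mean of the original
#' samples within Chebyshev spatial distance \code{hs} and intensity
#' distance \code{hr} of the current estimate. Iteration stops after
#' \code{maxIters} rounds (four by default) or when the intensity shift
#' falls below \code{tol}; the output pixel takes the converged intensity.
#' The filter is a contraction of the intensity range and leaves flat
#' regions separated by more than \code{hr} untouched.
#'
#' @param plane numeric matrix on the byte scale.
#' @param hs spatial bandwidth in pixels (window side 2 hs + 1).
#' @param hr intensity (range) bandwidth.
#' @param maxIters iteration cap.
#' @param tol convergence tolerance on the intensity shift.
#' @return numeric matrix of converged intensities.
#' @export
meanShiftFilter <- function(plane, hs = 3, hr = 3, maxIters = 4, tol = 0.5) {
  stopifnot(is.matrix(plane), hs >= 1, hr > 0, maxIters >= 1)
  .cpp_mean_shift(plane, as.integer(hs), hr, as.integer(maxIters), tol)
}

#' Nucleus-area-anchored adaptive threshold
#'
#' The whole-cell area is assumed to be \code{N} times the nucleus area, so
#' the red-cell-plus-background pixel budget is
#' \code{Simage - N * nucleusArea}. The returned threshold is the smallest
#' gray level whose cumulative histogram count (bins 0..Tg of the rounded
#' intensities) reaches that budget; the cell mask is taken strictly above
#' it. If the requested cell area exceeds the image, the threshold degrades
#' to 0 with a warning.
#'
#' @param plane numeric matrix on the byte scale.
#' @param nucleusArea total nucleus (inside-seed) area in pixels.
#' @param N assumed cell-to-nucleus area ratio (3 peripheral, 1.5 marrow).
#' @return scalar threshold in [0, 255].
#' @export
adaptiveThresholdFraction <- function(plane, nucleusArea, N) {
  stopifnot(is.matrix(plane), nucleusArea >= 0, N > 0)
  n <- length(plane)
  target <- n - N * nucleusArea
  if (target < 0) {
    warning("adaptiveThresholdFraction: requested cell area exceeds image")
    return(0)
  }
  target <- min(target, n)
  g <- byteBin(plane)
  cum <- cumsum(tabulate(g + 1L, 256L))
  if (target == 0) return(0)
  which(cum >= target)[1] - 1
}

#' Whole-cell mask from mean-shift clustering of the cyan channel
#'
#' Phase II strategy 1: the CMYK cyan channel (high on nucleus, moderate on
#' cytoplasm, near zero on red cells and background) is byte-scaled,
#' smoothed by \code{\link{meanShiftFilter}} and cut by the adaptive
#' area-anchored threshold.
#'
#' @param image RGB array (0-255).
#' @param nucleusArea total inside-seed area in pixels.
#' @param params \linkS4class{SegmentationParams}.
#' @return binary integer matrix.
#' @export
wbcClusterMask <- function(image, nucleusArea, params = segmentationParams()) {
  cplane <- rgbCyanChannel(image, naive = params@cmykNaive) * 255
  f <- meanShiftFilter(cplane, params@spatialBandwidth, params@rangeBandwidth,
                       params@msIterations, params@msTolerance)
  t3 <- adaptiveThresholdFraction(f, nucleusArea, params@areaRatio)
  (byteBin(f) > t3) * 1L
}

#' Whole-cell mask from b/g chromaticity enhancement
#'
#' Phase II strategy 2: cell pixels have a larger blue-to-green
#' chromaticity ratio than red cells and background. The ratio plane
#' (zero where g = 0) is tail-winsorised, byte-scaled and cut by the
#' adaptive area-anchored threshold.
#'
#' @inheritParams wbcClusterMask
#' @return binary integer matrix.
#' @export
wbcEnhancedMask <- function(image, nucleusArea, params = segmentationParams()) {
  ch <- rgbToChroma(image)
  ien <- ratioEnhance(ch[, , "b"], ch[, , "g"])
  byte <- normalizePlane(clipRatioTail(ien, params@ratioClipQuantile))
  t4 <- adaptiveThresholdFraction(byte, nucleusArea, params@areaRatio)
  (byteBin(byte) > t4) * 1L
}

#' Build the outside seeds (whole-cell regions)
#'
#' Phase II: union (logical OR) of the two strategies, so a cell detected by
#' only one of them is kept; then components below \code{minCellArea} are
#' removed, enclosed holes are filled (a nucleus darker than its
#' cytoplasm can punch a hole in the cyan-channel mask, and the watershed
#' needs the inside seeds fully contained in the outside seeds) and the
#' boundary is repaired by a close-and-open smoothing.
#'
#' @inheritParams wbcClusterMask
#' @return binary integer matrix covering the white blood cells.
#' @export
buildOutsideSeeds <- function(image, nucleusArea, params = segmentationParams()) {
  m1 <- wbcClusterMask(image, nucleusArea, params)
  m2 <- wbcEnhancedMask(image, nucleusArea, params)
  m <- ((m1 + m2) > 0) * 1L
  m <- denoiseSmall(m, params@minCellArea)
  m <- fillHoles(m)
  m <- morphSmooth(m, params@seRadius)
  denoiseSmall(fillHoles(m), params@minCellArea)
}
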