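#' Otsu's threshold on a byte-scaled plane
#'
#' Exhaustive maximization of the between-class variance over a 256-bin
#' histogram of the rounded intensities; ties are broken toward the smallest
#' threshold. Foreground is taken strictly above the returned value.
#' A constant plane is degenerate: the constant itself is returned with a
#' warning, so the downstream mask is empty.
#'
#' @param plane numeric matrix with values in [0, 255].
#' @return scalar threshold in [0, 255].
#' @export
otsuThreshold <- function(plane) {
  stopifnot(is.matrix(plane), length(plane) > 0)
  if (min(plane) == max(plane)) {
    warning("otsuThreshold: constant plane, degenerate threshold")
    return(plane[1])
  }
  g <- byteBin(plane)
  h <- as.numeric(tabulate(g + 1L, 256L))
  n <- length(g)
  lev <- as.numeric(0:255)
  w0 <- cumsum(h)
  m0 <- cumsum(h * lev)
  mT <- m0[256]
  w1 <- n - w0
  # between-class variance for split "class0 = {<= t}" at t = 0..255
  num <- (mT * w0 - m0 * n)^2
  den <- as.numeric(w0) * as.numeric(w1)
  sb <- ifelse(den > 0, num / den, -Inf)
  lev[which.max(sb)]
}

#' Nucleus mask from saturation/green-chromaticity enhancement
#'
#' Phase I core: the normalized HSI saturation is divided by the normalized
#' g chromaticity, which is well above one on nuclei (high saturation, low
#' g) and below one on red cells and background. The upper tail of the
#' ratio is winsorised (\code{ratioClipQuantile}) before byte rescaling so
#' isolated near-zero denominators cannot flatten the histogram, Otsu's
#' threshold keeps the bright side, and the mask is intersected with the
#' floor S/g > 1 on the raw (unnormalized) ratio -- the stain property that
#' distinguishes nuclei, independent of the scene's intensity range --
#' which protects against an Otsu cut that lands below the red-cell mode
#' when nuclei occupy only a tiny image fraction and empties the mask on
#' leukocyte-free fields. The mask boundary is then
#' repaired by a close-and-open smoothing and components smaller than
#' \code{minNucleusArea} are removed.
#'
#' @param image RGB array (0-255).
#' @param params \linkS4class{SegmentationParams}.
#' @return binary integer matrix of nucleus pixels.
#' @export
segmentNucleus <- function(image, params = segmentationParams()) {
  ch <- rgbToChroma(image)
  s <- rgbSaturation(image)
  ig <- normalizePlane(ch[, , "g"])
  is <- normalizePlane(s)
  ie <- ratioEnhance(is, ig)
  ieb <- normalizePlane(clipRatioTail(ie, params@ratioClipQuantile))
  if (max(ieb) == min(ieb)) # achromatic or empty enhancement
    return(matrix(0L, nrow(ieb), ncol(ieb)))
  t <- otsuThreshold(ieb)
  # stain floor on the raw (unnormalized) saturation/green-chromaticity
  # ratio: independent of the scene's min-max range, it is above one only
  # on strongly stained nucleus pixels, so a field without any leukocyte
  # yields an empty mask instead of promoting the red cells
  rawRatio <- ratioEnhance(s, ch[, , "g"])
  mask <- (byteBin(ieb) > t & rawRatio > 1) * 1L
  mask <- morphSmooth(mask, max(1, params@seRadius - 1))
  denoiseSmall(mask, params@minNucleusArea)
}

#' Find nucleus lobe pairs eligible for connection
#'
#' A segmented (multi-lobed) nucleus appears as several components whose
#' individual areas fall strictly inside \code{coreAreaRange} and whose
#' minimum boundary-to-boundary Euclidean distance is below
#' \code{maxCoreGap}. All qualifying unordered pairs are returned, closest
#' first.
#'
#' @param nucleus binary nucleus mask.
#' @param params \linkS4class{SegmentationParams}.
#' @return \code{data.frame} with columns a, b (component labels in the
#'   4-connected labeling of \code{nucleus}) and dist.
#' @export
findMultiCores <- function(nucleus, params = segmentationParams()) {
  lab <- connectedComponents(nucleus, 4)
  empty <- data.frame(a = integer(), b = integer(), dist = numeric())
  k <- max(0L, lab)
  if (k < 2) return(empty)
  areas <- tabulate(lab[lab > 0], k)
  cand <- which(areas > params@coreAreaRange[1] & areas < params@coreAreaRange[2])
  if (length(cand) < 2) return(empty)
  out <- empty
  for (i in seq_along(cand)[-length(cand)]) {
    a <- cand[i]
    # distance from every pixel to component a
    da <- distanceTransform(lab != a)
    for (j in (i + 1):length(cand)) {
      b <- cand[j]
      d <- min(da[lab == b])
      if (d < params@maxCoreGap)
        out <- rbind(out, data.frame(a = a, b = b, dist = d))
    }
  }
  out[order(out$dist, out$a, out$b), , drop = FALSE]
}

#' Connect two nucleus lobes through a padded centroid rectangle
#'
#' The axis-aligned rectangle spanned by the two lobe centroids, padded by
#' \code{centroidPad} on every side and clamped to the image, is filled with
#' foreground, merging the pair into one component.
#'
#' @param nucleus binary nucleus mask.
#' @param pair one row of the \code{\link{findMultiCores}} table (or a list
#'   with elements \code{a} and \code{b}).
#' @param params \linkS4class{SegmentationParams}.
#' @return binary integer matrix with the rectangle merged in.
#' @export
centroidConnect <- function(nucleus, pair, params = segmentationParams()) {
  lab <- connectedComponents(nucleus, 4)
  m <- binMat(nucleus)
  pr <- regionProps(lab)
  ca <- pr[pr$label == pair$a, ]
  cb <- pr[pr$label == pair$b, ]
  if (nrow(ca) == 0 || nrow(cb) == 0) return(m)
  rect <- padRectangle(c(ca$cx, cb$cx), c(ca$cy, cb$cy),
                       params@centroidPad, dim(m))
  m[rect$rows, rect$cols] <- 1L
  m
}

# The padded rectangle arithmetic: x11/x22 (resp. y11/y22) are the ordered
# centroid coordinates; the corners are padded by t2 and clamped to the
# image. 1-based inclusive pixel ranges.
padRectangle <- function(xs, ys, t2, dims) {
  x11 <- min(xs); x22 <- max(xs)
  y11 <- min(ys); y22 <- max(ys)
  a <- min(max(round(x11) - t2, 1), dims[2])
  b <- max(min(round(x22) + t2, dims[2]), 1)
  cc <- min(max(round(y11) - t2, 1), dims[1])
  d <- max(min(round(y22) + t2, dims[1]), 1)
  list(rows = cc:d, cols = a:b)
}

#' Build the inside seeds (nucleus groups)
#'
#' Phase I: segment the nucleus, then repeatedly connect qualifying lobe
#' pairs (closest pair first) until none remains, so a neutrophil with up to
#' five lobes collapses into a single seed component. The pre-connection
#' mask is kept as \code{nucleusRaw}.
#'
#' @param image RGB array (0-255).
#' @param params \linkS4class{SegmentationParams}.
#' @return a \linkS4class{SeedSet} with \code{inside} and \code{nucleusRaw}
#'   populated (\code{outside} is filled by \code{\link{buildOutsideSeeds}}).
#' @export
buildInsideSeeds <- function(image, params = segmentationParams()) {
  raw <- segmentNucleus(image, params)
  m <- raw
  maxIter <- max(1L, max(connectedComponents(m, 4)))
  for (i in seq_len(maxIter)) {
    pairs <- findMultiCores(m, params)
    if (nrow(pairs) == 0) break
    m <- centroidConnect(m, pairs[1, ], params)
  }
  new("SeedSet", inside = m, outside = matrix(0L, 0, 0), nucleusRaw = raw)
}

# round intensities into the 0..255 integer bins used by all histogram
# based thresholds
byteBin <- function(plane) {
  g <- as.integer(round(pmin(pmax(plane, 0), 255)))
  dim(g) <- dim(plane)
  g
}
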